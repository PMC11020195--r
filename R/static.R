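#' Static-variant fitting: Monte-Carlo maximum likelihood
#'
#' With fixed input embeddings Z, the model's log joint probability over
#' p-values P, switches T and association scores F is maximized in the
#' parameter network Phi by stochastic gradient ascent: latents are drawn by
#' Gibbs sweeps of their exact conditionals, the per-gene gradient triple is
#' evaluated at the draw, and the chain rule carries it into Phi.
#'
#' @name static_pheseq
#' @keywords internal
NULL

#' Joint log-probability of p-values and latents given mixture parameters
#'
#' Per gene:
#' \code{T log(alpha) + T (alpha - 1) log(P) + log Beta-normalizer(a, b)
#' + (T + a - 1) log(F) + (b - T) log(1 - F)}, summed over genes.
#'
#' @param P clipped p-values.
#' @param T_switch 0/1 switch states.
#' @param F_score association scores in (0, 1), clipped away from the
#'   boundary.
#' @param params list with per-gene \code{alpha}, \code{a}, \code{b}.
#' @return scalar log joint probability.
#' @export
log_joint_static <- function(P, T_switch, F_score, params) {
  a <- params$a; b <- params$b; alpha <- params$alpha
  terms <- T_switch * log(alpha) + T_switch * (alpha - 1) * log(P) +
    (lgamma(a + b) - lgamma(a) - lgamma(b)) +
    (T_switch + a - 1) * log(F_score) + (b - T_switch) * log1p(-F_score)
  v <- sum(terms)
  if (!is.finite(v)) stop("non-finite joint log-probability", call. = FALSE)
  v
}

#' Draw latent switches and scores by Gibbs sweeps of the exact conditionals
#'
#' Initializes \code{F ~ Beta(a, b)}, then alternates
#' \code{T ~ Bernoulli(posterior_T(P, alpha, F))} and
#' \code{F ~ Beta(a + T, b + 1 - T)} for \code{sweeps} rounds.  Uses R's
#' global RNG stream.
#'
#' @param params per-gene \code{alpha}, \code{a}, \code{b}.
#' @param P clipped p-values.
#' @param sweeps number of Gibbs sweeps (>= 1).
#' @param f_eps clipping margin applied to F.
#' @return list with integer vector \code{T} and numeric vector \code{F}.
#' @export
sample_latents <- function(params, P, sweeps = 2L, f_eps = 1e-6) {
  G <- length(P)
  F_score <- clip_F(stats::rbeta(G, params$a, params$b), f_eps)
  T_switch <- integer(G)
  for (s in seq_len(sweeps)) {
    pT <- posterior_T(P, params$alpha, F_score, f_eps)
    T_switch <- stats::rbinom(G, 1L, pT)
    F_score <- clip_F(stats::rbeta(G, params$a + T_switch,
                                   params$b + 1L - T_switch), f_eps)
  }
  list(T = T_switch, F = F_score)
}

# Mean-value (Rao-Blackwellized) latent state for the objective trace: the
# switch enters at its conditional expectation (the joint is linear in T)
# and F at its conditional mean given that expectation.  This is the
# infinite-replication limit of common-random-number averaging: a smooth,
# deterministic function of the parameters, so successive trace values are
# directly comparable.
trace_latents <- function(params, P, f_eps = 1e-6) {
  F0 <- clip_F(params$a / (params$a + params$b), f_eps)
  pT <- posterior_T(P, params$alpha, F0, f_eps)
  F_score <- clip_F((params$a + pT) / (params$a + params$b + 1), f_eps)
  list(T = pT, F = F_score)
}

#' Per-gene gradient of the joint log-probability at a latent draw
#'
#' The Gamma-ratio expressions of the analytic gradient reduce to digamma
#' differences, which is how they are evaluated here:
#' \code{d_alpha = T (log P + 1/alpha)},
#' \code{d_a = digamma(a+b) - digamma(a) + log F},
#' \code{d_b = digamma(a+b) - digamma(b) + log(1-F)}.
#'
#' @param P clipped p-values.
#' @param latents list with \code{T} and \code{F} from [sample_latents()].
#' @param params per-gene \code{alpha}, \code{a}, \code{b}.
#' @return list of per-gene gradient vectors \code{d_alpha}, \code{d_a},
#'   \code{d_b}.
#' @export
grad_static <- function(P, latents, params) {
  list(
    d_alpha = latents$T * (log(P) + 1 / params$alpha),
    d_a = digamma(params$a + params$b) - digamma(params$a) + log(latents$F),
    d_b = digamma(params$a + params$b) - digamma(params$b) + log1p(-latents$F)
  )
}

#' One gradient-ascent step on the parameter network
#'
#' Assembles the summed chain-rule product of the per-gene gradient triple
#' with the network Jacobian and takes one ascent step of size \code{eta}.
#'
#' @param grads list from [grad_static()].
#' @param Z embedding matrix fed to Phi.
#' @param phi \code{phi_params} object.
#' @param eta step size (>= 0); 0 leaves Phi unchanged.
#' @return list with the updated \code{phi} and the recomputed per-gene
#'   \code{params}.
#' @export
step_phi <- function(grads, Z, phi, eta) {
  params <- phi_forward(Z, phi)
  back <- phi_backward(phi, params, grads$d_alpha, grads$d_a, grads$d_b)
  if (any(!vapply(back$dW, function(w) all(is.finite(w)), logical(1)))) {
    stop("non-finite gradient in the parameter network", call. = FALSE)
  }
  phi$net <- mlp_step(phi$net, back, eta)
  params_new <- phi_forward(Z, phi)
  params_new$cache <- NULL
  list(phi = phi, params = params_new)
}

# Frozen-parameter posterior summaries: burn-in sweeps, then average the
# Rao-Blackwellized switch probability and the sampled score over M sweeps.
posterior_summaries <- function(params, P, M = 50L, burn = 10L, f_eps = 1e-6) {
  G <- length(P)
  F_score <- clip_F(stats::rbeta(G, params$a, params$b), f_eps)
  sum_T <- numeric(G); sum_F <- numeric(G)
  for (s in seq_len(burn + M)) {
    pT <- posterior_T(P, params$alpha, F_score, f_eps)
    T_switch <- stats::rbinom(G, 1L, pT)
    F_score <- clip_F(stats::rbeta(G, params$a + T_switch,
                                   params$b + 1L - T_switch), f_eps)
    if (s > burn) {
      sum_T <- sum_T + pT
      sum_F <- sum_F + F_score
    }
  }
  list(mean_T = sum_T / M, mean_F = sum_F / M)
}

new_pheseq_fit <- function(mode, phi, vae, params, summaries, trace,
                           converged_at, config, dataset) {
  structure(list(
    mode = mode, phi = phi, vae = vae,
    params = params[c("alpha", "a", "b")],
    mean_T = summaries$mean_T, mean_F = summaries$mean_F,
    trace = trace, converged_at = converged_at,
    config = config,
    gene_ids = dataset$gene_ids, p_values = dataset$p_values,
    disease_id = dataset$disease_id
  ), class = "pheseq_fit")
}

#' @export
print.pheseq_fit <- function(x, ...) {
  cat("pheseq fit (", x$mode, "): ", length(x$gene_ids), " genes, ",
      length(x$trace), " iterations",
      if (is.na(x$converged_at)) " (max_iters reached)" else
        paste0(" (converged at ", x$converged_at, ")"), "\n", sep = "")
  cat("  final objective:", format(x$trace[length(x$trace)]), "\n")
  cat("  mean fused posterior:", format(mean(x$mean_T), digits = 4), "\n")
  invisible(x)
}

#' Fit the static variant
#'
#' Gradient-ascent loop: map embeddings through Phi, draw
#' \code{latent_samples} latent states by Gibbs sweeps, average the per-gene
#' gradient triple across the draws, and chain it into Phi with step size
#' \code{learning_rate / G} (the configured rate applies to the
#' per-gene-averaged gradient).  The iteration stops at \code{max_iters} or
#' once the largest absolute change of any per-gene (alpha, a, b) stays
#' below \code{tol} for \code{conv_window} consecutive iterations.  The
#' objective trace is evaluated with common random numbers so successive
#' values are comparable.  Posterior summaries are averaged over
#' \code{summary_sweeps} frozen-parameter Gibbs sweeps.
#'
#' @param dataset an \code{association_dataset} with embeddings attached.
#' @param config a \code{pheseq_config}; \code{mode} is forced to "static".
#' @return a \code{pheseq_fit} object.
#' @export
fit_static <- function(dataset, config = pheseq_config(mode = "static")) {
  if (is.null(dataset$embeddings)) {
    stop("dataset has no embeddings; call attach_embeddings() first",
         call. = FALSE)
  }
  set.seed(config$seed)
  Z <- dataset$embeddings
  P <- dataset$p_values
  G <- length(P)
  phi <- phi_init(ncol(Z), config$hidden_dim, config$f_eps)
  trace <- numeric(0)
  prev_par <- NULL
  stable <- 0L
  converged_at <- NA_integer_
  S <- config$latent_samples
  for (t in seq_len(config$max_iters)) {
    params <- phi_forward(Z, phi)
    d_alpha <- d_a <- d_b <- numeric(G)
    for (s in seq_len(S)) {
      lat <- sample_latents(params, P, config$gibbs_sweeps, config$f_eps)
      g <- grad_static(P, lat, params)
      d_alpha <- d_alpha + g$d_alpha; d_a <- d_a + g$d_a; d_b <- d_b + g$d_b
    }
    back <- phi_backward(phi, params, d_alpha / S, d_a / S, d_b / S)
    phi$net <- mlp_step(phi$net, back, config$learning_rate / G)

    lat_t <- trace_latents(params, P, config$f_eps)
    trace[t] <- log_joint_static(P, lat_t$T, lat_t$F, params)

    par_mat <- cbind(params$alpha, params$a, params$b)
    if (!is.null(prev_par)) {
      delta <- max(abs(par_mat - prev_par))
      stable <- if (delta < config$tol) stable + 1L else 0L
      if (stable >= config$conv_window) { converged_at <- t; break }
    }
    prev_par <- par_mat
  }
  params <- phi_forward(Z, phi)
  params$cache <- NULL
  summ <- posterior_summaries(params, P, config$summary_sweeps,
                              f_eps = config$f_eps)
  new_pheseq_fit("static", phi, NULL, params, summ, trace, converged_at,
                 config, dataset)
}
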