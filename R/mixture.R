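#' Beta-uniform mixture model of association p-values
#'
#' The significance model at the heart of the package: under association
#' (switch \code{T = 1}) a gene's p-value follows \code{Beta(alpha, 1)} with
#' \code{0 < alpha < 1}, concentrating mass near zero; under non-association
#' (\code{T = 0}) it is \code{Uniform(0, 1)}.  These helpers evaluate the
#' component and mixture log-densities, sample from the model, and invert it
#' to the posterior switch probability.
#'
#' @name mixture
#' @keywords internal
NULL

#' Log-density of the significant Beta(alpha, 1) component
#'
#' @param p p-value(s) in (0, 1]; clip upstream with [clip_pvalues()] so that
#'   \code{log(p)} is finite.
#' @param alpha shape parameter in (0, 1); values near 0 concentrate the
#'   density near p = 0.
#' @return \code{log(alpha) + (alpha - 1) * log(p)}, vectorized.
#' @examples
#' beta1_logpdf(0.01, 0.5)  # log(5)
#' @export
beta1_logpdf <- function(p, alpha) {
  if (any(p <= 0)) stop("p must be positive; clip p-values first", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  log(alpha) + (alpha - 1) * log(p)
}

#' Log-density of the two-component beta-uniform mixture
#'
#' Density \code{w * alpha * p^(alpha - 1) + (1 - w) * 1}, evaluated in
#' log-space with max-subtraction so tiny p-values do not overflow.
#'
#' @inheritParams beta1_logpdf
#' @param w marginal probability of the significant component, in [0, 1].
#' @return log mixture density, vectorized over \code{p}.
#' @export
mixture_logpdf <- function(p, alpha, w) {
  if (any(w < 0 | w > 1)) stop("mixture weight w must lie in [0, 1]", call. = FALSE)
  if (any(p <= 0)) stop("p must be positive; clip p-values first", call. = FALSE)
  n <- max(length(p), length(alpha), length(w))
  p <- rep_len(p, n); alpha <- rep_len(alpha, n); w <- rep_len(w, n)
  out <- numeric(n)
  only_beta <- w == 1
  only_unif <- w == 0
  mix <- !only_beta & !only_unif
  if (any(only_beta)) out[only_beta] <- beta1_logpdf(p[only_beta], alpha[only_beta])
  if (any(only_unif)) out[only_unif] <- 0
  if (any(mix)) {
    la <- log(w[mix]) + beta1_logpdf(p[mix], alpha[mix])
    lb <- log1p(-w[mix])  # uniform density is 1
    m <- pmax(la, lb)
    out[mix] <- m + log(exp(la - m) + exp(lb - m))
  }
  out
}

#' Sample p-values from the switch-conditional model
#'
#' \code{T = 0} draws Uniform(0, 1); \code{T = 1} draws Beta(alpha, 1) by
#' inverse CDF, \code{u^(1/alpha)}.  Uses R's global RNG stream, so results
#' are reproducible under \code{set.seed()}.
#'
#' @param T_switch 0/1 vector of switch states.
#' @param alpha shape of the significant component (scalar or per-gene).
#' @return vector of p-values in (0, 1), one per entry of \code{T_switch}.
#' @export
sample_p <- function(T_switch, alpha) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  n <- length(T_switch)
  alpha <- rep_len(alpha, n)
  u <- stats::runif(n)
  ifelse(T_switch == 1, u^(1 / alpha), u)
}

#' Posterior probability of the significance switch
#'
#' Bayes inversion of the switch prior: given the association score
#' \code{F} (the prior \code{P(T = 1)}) and the observed p-value,
#' \deqn{P(T = 1 | p) = \frac{F \alpha p^{\alpha-1}}{F \alpha p^{\alpha-1} + (1-F)}.}
#' Computed from log branch likelihoods with max-subtraction so that
#' \code{alpha * p^(alpha - 1)} never overflows for tiny p.
#'
#' @inheritParams beta1_logpdf
#' @param F_score association score in (0, 1); clipped to
#'   \code{[f_eps, 1 - f_eps]} before use.
#' @param f_eps clipping bound for \code{F_score} (default \code{1e-6}).
#' @return posterior P(T = 1 | p) in [0, 1], vectorized.
#' @export
posterior_T <- function(p, alpha, F_score, f_eps = 1e-6) {
  F_score <- clip_F(F_score, f_eps)
  l1 <- log(F_score) + beta1_logpdf(p, alpha)
  l0 <- log1p(-F_score)
  m <- pmax(l1, l0)
  e1 <- exp(l1 - m)
  e1 / (e1 + exp(l0 - m))
}

#' Clip an association score into the open unit interval
#' @param F_score numeric vector.
#' @param f_eps boundary margin.
#' @return values clipped into \code{[f_eps, 1 - f_eps]}.
#' @keywords internal
clip_F <- function(F_score, f_eps = 1e-6) {
  pmin(pmax(F_score, f_eps), 1 - f_eps)
}

#' Clip p-values away from zero
#'
#' Replaces values below \code{p_eps} (including exact zeros) by
#' \code{p_eps} and caps at 1, so that \code{log(p)} is always finite.
#' Idempotent.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param p_eps lower clipping bound, default \code{1e-300}.
#' @return clipped vector in \code{[p_eps, 1]}.
#' @export
clip_pvalues <- function(p, p_eps = 1e-300) {
  pmin(pmax(p, p_eps), 1)
}
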