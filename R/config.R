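#' Run configuration
#'
#' Collects every tunable of a fit in one validated list.  Defaults are the
#' package's documented desk-scale settings; all can be overridden per call
#' or from the command line.
#'
#' @param mode "static" (fixed embeddings, Monte-Carlo MLE) or "dynamic"
#'   (learnable VAE embeddings, MAP-MLE).
#' @param seed integer seed controlling every random draw of the run.
#' @param learning_rate positive gradient-ascent step size (eta), applied to
#'   per-gene-averaged gradients.
#' @param mc_samples positive integer N of Monte-Carlo latent draws per gene
#'   in the dynamic objective.
#' @param latent_samples number of latent (T, F) draws averaged per gradient
#'   step; sampling is cheap next to the network passes, so a few draws buy
#'   a large variance reduction.
#' @param weight_decay nonnegative L2 penalty (lambda_w) on encoder/decoder
#'   weights and biases in the dynamic MAP objective.
#' @param max_iters maximum number of ascent iterations.  Default 2000 in
#'   static mode and 800 in dynamic mode (a dynamic iteration costs several
#'   times a static one, and the VAE warm-up shortens the joint phase it
#'   needs).
#' @param tol convergence tolerance: the fit stops when the maximum absolute
#'   change of any per-gene (alpha, a, b) stays below \code{tol} for
#'   \code{conv_window} consecutive iterations.
#' @param conv_window length of the convergence window (iterations).
#' @param embedding_dim latent dimension K of the VAE (dynamic mode only).
#' @param hidden_dim width of the hidden layers of the perception network,
#'   encoder and decoder.
#' @param gibbs_sweeps Gibbs sweeps per latent sample in the static fit.
#' @param summary_sweeps number M of frozen-parameter sweeps averaged for the
#'   posterior summaries.
#' @param lenient_alpha fixed p-value cutoff of the lenient criterion.
#' @param strict_fdr_q Benjamini-Hochberg level of the strict criterion.
#' @param p_eps lower clipping bound for p-values.
#' @param f_eps clipping margin for the association score F.
#' @param map_f_floor clipping margin for F along the dynamic block updates
#'   (MAP update and switch conditional).  A score at the hard boundary is
#'   an absorbing state of the block scheme -- the switch can then never
#'   turn back on regardless of the p-value -- so the fitting path keeps F
#'   at least this open; final posterior summaries use \code{f_eps}.
#' @param vae_warmup number of initial dynamic iterations that train only
#'   the encoder/decoder (reconstruction plus KL).  Until the latent space
#'   carries the cluster structure of the descriptions, the parameter
#'   network cannot distinguish genes, and its early gradient -- dominated
#'   by the null majority -- would saturate the a head irrecoverably.
#' @param vae_learning_rate step size for the encoder/decoder blocks (both
#'   warm-up and joint phase); the reconstruction objective is smooth and
#'   tolerates a larger step than the PGM blocks.
#' @return an object of class \code{pheseq_config} (a named list).
#' @examples
#' cfg <- pheseq_config(mode = "static", seed = 1)
#' @export
pheseq_config <- function(mode = c("static", "dynamic"),
                          seed = 1L,
                          learning_rate = 0.05,
                          mc_samples = 4L,
                          latent_samples = 4L,
                          weight_decay = 1e-4,
                          max_iters = NULL,
                          tol = 1e-4,
                          conv_window = 5L,
                          embedding_dim = 16L,
                          hidden_dim = 64L,
                          gibbs_sweeps = 2L,
                          summary_sweeps = 50L,
                          lenient_alpha = 0.05,
                          strict_fdr_q = 0.05,
                          p_eps = 1e-300,
                          f_eps = 1e-6,
                          map_f_floor = 0.01,
                          vae_warmup = 500L,
                          vae_learning_rate = 0.2) {
  mode <- match.arg(mode)
  if (is.null(max_iters)) max_iters <- if (mode == "static") 2000L else 800L
  cfg <- list(
    mode = mode, seed = as.integer(seed),
    learning_rate = learning_rate, mc_samples = as.integer(mc_samples),
    latent_samples = as.integer(latent_samples),
    weight_decay = weight_decay, max_iters = as.integer(max_iters),
    tol = tol, conv_window = as.integer(conv_window),
    embedding_dim = as.integer(embedding_dim),
    hidden_dim = as.integer(hidden_dim),
    gibbs_sweeps = as.integer(gibbs_sweeps),
    summary_sweeps = as.integer(summary_sweeps),
    lenient_alpha = lenient_alpha, strict_fdr_q = strict_fdr_q,
    p_eps = p_eps, f_eps = f_eps, map_f_floor = map_f_floor,
    vae_warmup = as.integer(vae_warmup),
    vae_learning_rate = vae_learning_rate
  )
  validate_config(cfg)
  class(cfg) <- "pheseq_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$learning_rate > 0,
    cfg$mc_samples >= 1L,
    cfg$latent_samples >= 1L,
    cfg$weight_decay >= 0,
    cfg$max_iters >= 1L,
    cfg$tol > 0,
    cfg$conv_window >= 1L,
    cfg$embedding_dim >= 1L,
    cfg$hidden_dim >= 1L,
    cfg$gibbs_sweeps >= 1L,
    cfg$summary_sweeps >= 1L,
    cfg$lenient_alpha > 0, cfg$lenient_alpha < 1,
    cfg$strict_fdr_q > 0, cfg$strict_fdr_q < 1,
    cfg$p_eps > 0,
    cfg$f_eps > 0, cfg$f_eps < 0.5,
    cfg$map_f_floor > 0, cfg$map_f_floor < 0.5,
    cfg$vae_warmup >= 0L,
    cfg$vae_learning_rate > 0
  )
  invisible(cfg)
}

#' @export
print.pheseq_config <- function(x, ...) {
  cat("pheseq run configuration (", x$mode, ")\n", sep = "")
  for (nm in setdiff(names(x), "mode")) {
    cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
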