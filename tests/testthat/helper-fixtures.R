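# Shared fixtures: small file writers and memoized heavy fits so the
# acceptance tests reuse one static and one dynamic fit of the default
# simulation.

write_assoc_file <- function(df, path = tempfile(fileext = ".tsv"),
                             sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Monte-Carlo objective recomputed by direct assembly at explicit (mu,
# sigma): the independent oracle for the variational gradient checks.
mc_objective_at <- function(mu, sigma, L, F_score, phi, theta, eps) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1L)
  N <- length(eps)
  acc <- 0
  for (n in seq_len(N)) {
    Zn <- mu + sqrt(sigma) * eps[[n]]
    par <- phi_forward(Zn, phi)
    acc <- acc + sum(decode_loglik(L, Zn, theta)) +
      sum(pheseq:::beta_logpdf(F_score, par$a, par$b))
  }
  acc / N - sum(kl_isotropic(mu, sigma))
}

# memoized default-simulation fits (shared by the acceptance tests)
.fit_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fit_cache$sim)) .fit_cache$sim <- simulate_dataset(seed = 7)
  .fit_cache$sim
}

default_static_fit <- function() {
  if (is.null(.fit_cache$static)) {
    .fit_cache$static <- fit_static(default_sim()$dataset,
                                    pheseq_config(mode = "static", seed = 11))
  }
  .fit_cache$static
}

default_dynamic_fit <- function() {
  if (is.null(.fit_cache$dynamic)) {
    .fit_cache$dynamic <- fit_dynamic(default_sim()$dataset,
                                      pheseq_config(mode = "dynamic",
                                                    seed = 11))
  }
  .fit_cache$dynamic
}

balanced_accuracy <- function(pred, truth) {
  (mean(pred[truth == 1] == 1) + mean(pred[truth == 0] == 0)) / 2
}
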