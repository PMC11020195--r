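#' Synthetic datasets with the assumed fusion structure
#'
#' Generates gene sets in which a minority of genes is truly associated:
#' their p-values follow \code{Beta(alpha_true, 1)} while the rest are
#' Uniform(0, 1), and associated genes' embedding vectors cluster apart from
#' the null genes' embeddings -- the data congruence the fusion model
#' exploits.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Simulate an association dataset with ground truth
#'
#' Per gene: \code{T ~ Bernoulli(frac_assoc)}; p-value from the
#' switch-conditional mixture; embedding drawn from an isotropic Gaussian
#' centred on one of two unit-norm cluster means separated by
#' \code{separation}.
#'
#' @param G number of genes (>= 10).
#' @param D embedding dimension.
#' @param frac_assoc fraction of truly associated genes, in (0, 1).
#' @param alpha_true shape of the significant p-value component, in (0, 1).
#' @param separation Euclidean distance between the two cluster means.
#' @param noise_sd within-cluster standard deviation per coordinate.
#' @param seed integer seed; the draw is fully reproducible.
#' @param disease_id label stored on the dataset.
#' @return list with \code{dataset} (an \code{association_dataset}) and
#'   \code{truth} (per-gene \code{T_true}, the cluster means, and the
#'   generator settings).
#' @examples
#' sim <- simulate_dataset(G = 200, seed = 1)
#' table(sim$truth$T_true)
#' @export
simulate_dataset <- function(G = 2000L, D = 32L, frac_assoc = 0.1,
                             alpha_true = 0.1, separation = 3,
                             noise_sd = 1, seed = 1L,
                             disease_id = "simulated") {
  if (G < 10L) stop("G must be at least 10", call. = FALSE)
  if (frac_assoc <= 0 || frac_assoc >= 1) {
    stop("frac_assoc must lie in (0, 1)", call. = FALSE)
  }
  if (alpha_true <= 0 || alpha_true >= 1) {
    stop("alpha_true must lie in (0, 1)", call. = FALSE)
  }
  if (separation < 0 || noise_sd <= 0) {
    stop("separation must be >= 0 and noise_sd > 0", call. = FALSE)
  }
  set.seed(seed)
  # two unit-norm cluster centres at the requested distance
  dir1 <- stats::rnorm(D); dir1 <- dir1 / sqrt(sum(dir1^2))
  dir2 <- stats::rnorm(D); dir2 <- dir2 - sum(dir2 * dir1) * dir1
  dir2 <- dir2 / sqrt(sum(dir2^2))
  half <- separation / 2
  base <- sqrt(max(1 - half^2, 0))
  m1 <- base * dir2 + half * dir1
  m0 <- base * dir2 - half * dir1

  T_true <- stats::rbinom(G, 1L, frac_assoc)
  P <- sample_p(T_true, alpha_true)
  centres <- rbind(m0, m1)[T_true + 1L, , drop = FALSE]
  emb <- centres + matrix(stats::rnorm(G * D, sd = noise_sd), nrow = G)

  ids <- sprintf("G%05d", seq_len(G))
  dataset <- new_association_dataset(
    disease_id = disease_id, gene_ids = ids, p_values = P,
    embeddings = emb, emb_missing = rep(FALSE, G),
    source_label = "simulate_dataset"
  )
  truth <- list(
    T_true = T_true, alpha_true = alpha_true, m1 = m1, m0 = m0,
    separation = separation, noise_sd = noise_sd, frac_assoc = frac_assoc,
    seed = seed, p_only = integer(0), emb_only = integer(0)
  )
  list(dataset = dataset, truth = truth)
}

#' Inject discordant genes into a simulated dataset
#'
#' Creates the two disagreement patterns the fusion model is meant to
#' arbitrate: a fraction of truly associated genes get their embeddings
#' resampled from the null cluster (sequence significance without
#' phenotype description), and a fraction of null genes get a
#' lenient-range p-value (uniform draw kept below 0.05) paired with a
#' significant-cluster embedding (description without strong sequence
#' evidence).  Modified gene indices are recorded in the truth object.
#'
#' @param sim list with \code{dataset} and \code{truth} from
#'   [simulate_dataset()].
#' @param frac_p_only fraction of associated genes to strip of their
#'   cluster signal, in [0, 1).
#' @param frac_emb_only fraction of null genes to upgrade, in [0, 1).
#' @param seed integer seed for the resampling.
#' @return the modified \code{sim} list; \code{truth$p_only} and
#'   \code{truth$emb_only} hold the modified gene indices.
#' @export
inject_discordance <- function(sim, frac_p_only = 0.2, frac_emb_only = 0.2,
                               seed = 1L) {
  stopifnot(frac_p_only >= 0, frac_p_only < 1,
            frac_emb_only >= 0, frac_emb_only < 1,
            frac_p_only + frac_emb_only < 1)
  set.seed(seed)
  truth <- sim$truth
  dataset <- sim$dataset
  D <- ncol(dataset$embeddings)
  assoc <- which(truth$T_true == 1L)
  nulls <- which(truth$T_true == 0L)

  n_p <- floor(frac_p_only * length(assoc))
  p_only <- if (n_p > 0) sort(sample(assoc, n_p)) else integer(0)
  if (n_p > 0) {
    dataset$embeddings[p_only, ] <-
      matrix(truth$m0, n_p, D, byrow = TRUE) +
      matrix(stats::rnorm(n_p * D, sd = truth$noise_sd), nrow = n_p)
  }

  n_e <- floor(frac_emb_only * length(nulls))
  emb_only <- if (n_e > 0) sort(sample(nulls, n_e)) else integer(0)
  if (n_e > 0) {
    dataset$p_values[emb_only] <- stats::runif(n_e, min = 0, max = 0.05)
    dataset$embeddings[emb_only, ] <-
      matrix(truth$m1, n_e, D, byrow = TRUE) +
      matrix(stats::rnorm(n_e * D, sd = truth$noise_sd), nrow = n_e)
  }

  truth$p_only <- p_only
  truth$emb_only <- emb_only
  list(dataset = dataset, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the three delimited files consumed by the fitting pipeline: the
#' association table (gene_id, p_value), the embedding matrix and a truth
#' table (gene_id, T_true).
#'
#' @param sim list from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return named character vector of the three file paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  assoc_path <- file.path(dir, paste0(prefix, "_pvalues.tsv"))
  utils::write.table(
    data.frame(gene_id = ds$gene_ids,
               p_value = formatC(ds$p_values, digits = 15, format = "g")),
    assoc_path, sep = "\t", quote = FALSE, row.names = FALSE)

  emb_path <- file.path(dir, paste0(prefix, "_embeddings.tsv"))
  emb <- as.data.frame(ds$embeddings)
  names(emb) <- paste0("e", seq_len(ncol(emb)))
  emb[] <- lapply(emb, function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(cbind(gene_id = ds$gene_ids, emb), emb_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  utils::write.table(
    data.frame(gene_id = ds$gene_ids, T_true = sim$truth$T_true),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  c(pvalues = assoc_path, embeddings = emb_path, truth = truth_path)
}
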