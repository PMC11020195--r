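#' Dataset container and file I/O
#'
#' An association dataset aligns, per gene, a sequence-analysis p-value and a
#' phenotype-description embedding vector.  Files are tab-delimited with a
#' header (comma-delimited input is detected and accepted).
#'
#' @name io_formats
#' @keywords internal
NULL

new_association_dataset <- function(disease_id, gene_ids, p_values, embeddings,
                                    emb_missing, source_label = "",
                                    p_eps = 1e-300) {
  stopifnot(length(gene_ids) >= 1,
            length(p_values) == length(gene_ids),
            !anyDuplicated(gene_ids))
  if (!is.null(embeddings)) {
    stopifnot(is.matrix(embeddings), nrow(embeddings) == length(gene_ids))
  }
  structure(list(
    disease_id = disease_id,
    gene_ids = as.character(gene_ids),
    p_values = clip_pvalues(as.numeric(p_values), p_eps),
    embeddings = embeddings,       # G x D matrix or NULL
    emb_missing = emb_missing,     # logical G-vector; TRUE = imputed/missing
    source_label = source_label,
    p_eps = p_eps
  ), class = "association_dataset")
}

#' @export
print.association_dataset <- function(x, ...) {
  d <- if (is.null(x$embeddings)) "none" else ncol(x$embeddings)
  cat("association_dataset:", length(x$gene_ids), "genes, embedding dim:", d, "\n")
  if (!is.null(x$embeddings)) {
    cat("  missing/imputed embeddings:", sum(x$emb_missing), "\n")
  }
  invisible(x)
}

# sniff tab vs comma from the header line
detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L, warn = FALSE)
  if (length(hdr) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", hdr)) "\t" else if (grepl(",", hdr)) "," else "\t"
}

#' Read a per-gene association table
#'
#' Expects a delimited file with header columns \code{gene_id} and
#' \code{p_value}.  p-values are validated to lie in [0, 1] and then clipped
#' into \code{[p_eps, 1]}; row order is preserved and duplicate genes are
#' rejected.
#'
#' @param path file path.
#' @param p_eps lower clipping bound for p-values.
#' @param disease_id optional label stored on the dataset.
#' @return an \code{association_dataset} with embeddings marked missing.
#' @export
read_association_table <- function(path, p_eps = 1e-300, disease_id = "") {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  need <- c("gene_id", "p_value")
  if (!all(need %in% names(df))) {
    stop("association table must have columns gene_id and p_value; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  p <- suppressWarnings(as.numeric(df$p_value))
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad) > 0) {
    stop("invalid p-value in row ", bad[1], " (gene ",
         df$gene_id[bad[1]], "): '", df$p_value[bad[1]],
         "' is not a number in [0, 1]", call. = FALSE)
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  new_association_dataset(
    disease_id = disease_id, gene_ids = df$gene_id, p_values = p,
    embeddings = NULL, emb_missing = rep(TRUE, nrow(df)),
    source_label = path, p_eps = p_eps
  )
}

#' Read a per-gene embedding matrix
#'
#' First column \code{gene_id}, remaining D columns numeric.  All rows must
#' have the same dimension.
#'
#' @param path file path.
#' @return list with \code{vectors} (named G x D matrix) and \code{dim}.
#' @export
read_embedding_matrix <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", fill = FALSE)
  if (ncol(df) < 2) stop("embedding matrix needs gene_id plus >= 1 numeric column",
                         call. = FALSE)
  ids <- df[[1]]
  num <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(apply(num, 2, as.numeric))
  vals <- matrix(as.numeric(vals), nrow = nrow(df))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric embedding value at row ", idx[1], ", column ",
         idx[2] + 1L, call. = FALSE)
  }
  rownames(vals) <- ids
  list(vectors = vals, dim = ncol(vals))
}

#' Attach embedding vectors to a dataset
#'
#' Genes present in \code{emb$vectors} receive their vector; absent genes are
#' flagged missing and imputed with the all-zero vector (the neutral point of
#' the standard-normal latent prior), so the full gene universe is retained
#' in fitting and in report denominators.  Extra genes in the embedding map
#' are ignored.
#'
#' @param dataset an \code{association_dataset}.
#' @param emb result of [read_embedding_matrix()], or a named numeric matrix.
#' @param quiet suppress the imputation-count message.
#' @return the dataset with \code{embeddings} and \code{emb_missing} filled.
#' @export
attach_embeddings <- function(dataset, emb, quiet = FALSE) {
  if (is.matrix(emb)) emb <- list(vectors = emb, dim = ncol(emb))
  vec <- emb$vectors
  D <- emb$dim
  G <- length(dataset$gene_ids)
  out <- matrix(0, nrow = G, ncol = D)
  hit <- dataset$gene_ids %in% rownames(vec)
  out[hit, ] <- vec[dataset$gene_ids[hit], , drop = FALSE]
  dataset$embeddings <- out
  dataset$emb_missing <- !hit
  extra <- setdiff(rownames(vec), dataset$gene_ids)
  if (!quiet) {
    message(sum(!hit), " of ", G, " genes lack embeddings (zero-imputed); ",
            length(extra), " embedding rows unmatched")
  }
  dataset
}

#' Read a benchmark gene list
#'
#' Plain text, one gene symbol per line; \code{#} starts a comment.
#'
#' @param path file path.
#' @param disease_id,source_tag labels stored on the set.
#' @return list with \code{genes} (unique character vector) and the labels.
#' @export
read_benchmark <- function(path, disease_id = "", source_tag = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- unique(trimws(lines))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop("benchmark list is empty: ", path, call. = FALSE)
  list(disease_id = disease_id, genes = genes, source_tag = source_tag)
}

#' Write the per-gene results table
#'
#' One row per gene, input order, tab-delimited: gene_id, p_seq,
#' fused_posterior, fused_p, mean_F, alpha, a, b, call_seq_strict,
#' call_seq_lenient, call_fused.  Numeric fields carry 15 significant
#' digits so a read-back round trip is lossless at 12.
#'
#' @param results data.frame of gene results (see [gene_results()]).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_results_table <- function(results, path) {
  cols <- c("gene_id", "p_seq", "fused_posterior", "fused_p", "mean_F",
            "alpha", "a", "b", "call_seq_strict", "call_seq_lenient",
            "call_fused")
  out <- results[, intersect(cols, names(results)), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the -log10 p scatter table
#'
#' Per-gene coordinates for the standard fused-vs-sequence significance
#' scatter: \code{-log10} of the clipped sequence p-value against
#' \code{-log10} of the fused p-value, plus an evidence count column.
#'
#' @param results data.frame with \code{p_seq} and \code{fused_p}.
#' @param path output file path.
#' @param p_eps clipping bound applied before taking logs.
#' @return invisibly, the path.
#' @export
export_logp_scatter <- function(results, path, p_eps = 1e-300) {
  ev <- if ("evidence_count" %in% names(results)) results$evidence_count else 0L
  out <- data.frame(
    gene_id = results$gene_id,
    neglog10_p_seq = -log10(clip_pvalues(results$p_seq, p_eps)),
    neglog10_p_fused = -log10(clip_pvalues(results$fused_p, p_eps)),
    evidence_count = ev
  )
  num <- c("neglog10_p_seq", "neglog10_p_fused")
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
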