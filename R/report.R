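#' Fused significance calling and comparison reports
#'
#' Turns a fitted model into per-gene results (fused posterior, fused
#' p-value, significance calls under a strict BH-FDR criterion and a
#' lenient fixed cutoff) and into the summary counts used to compare fused
#' calls against single-omics calls, plus benchmark recall curves.
#'
#' @name posterior_report
#' @keywords internal
NULL

#' Benjamini-Hochberg step-up calls
#'
#' Wraps \code{stats::p.adjust(method = "BH")}: a p-value is called when its
#' BH-adjusted value is at most \code{q}, which equals the classical step-up
#' rule (all p-values up to the largest passing rank are called).
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param q FDR level in (0, 1).
#' @return logical vector of calls (empty input gives an empty vector).
#' @export
bh_fdr <- function(pvals, q) {
  if (length(pvals) == 0) return(logical(0))
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Assemble the per-gene results table from a fitted model
#'
#' @param fit a \code{pheseq_fit}.
#' @param evidence_count optional nonnegative integer vector (literature
#'   evidence counts); defaults to 0.
#' @return data.frame with gene_id, p_seq, fused_posterior, fused_p
#'   (\code{1 - fused_posterior}), mean_F, alpha, a, b, evidence_count.
#' @export
gene_results <- function(fit, evidence_count = NULL) {
  G <- length(fit$gene_ids)
  data.frame(
    gene_id = fit$gene_ids,
    p_seq = fit$p_values,
    fused_posterior = fit$mean_T,
    fused_p = 1 - fit$mean_T,
    mean_F = fit$mean_F,
    alpha = fit$params$alpha,
    a = fit$params$a,
    b = fit$params$b,
    evidence_count = if (is.null(evidence_count)) 0L else evidence_count,
    stringsAsFactors = FALSE
  )
}

#' Apply significance criteria to the results table
#'
#' Fills \code{call_seq_strict} (BH at \code{strict_fdr_q} on the sequence
#' p-values), \code{call_seq_lenient} (fixed cutoff \code{lenient_alpha}),
#' and \code{call_fused}: under the strict criterion BH at
#' \code{strict_fdr_q} on the fused p-values, under the lenient criterion
#' the fixed cutoff.
#'
#' @param results data.frame from [gene_results()].
#' @param config a \code{pheseq_config} (thresholds are read from it).
#' @param mode "strict" (default) or "lenient" -- the criterion used for
#'   \code{call_fused}.
#' @return the results data.frame with the three call columns filled.
#' @export
call_significance <- function(results, config, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  results$call_seq_strict <- bh_fdr(results$p_seq, config$strict_fdr_q)
  results$call_seq_lenient <- results$p_seq < config$lenient_alpha
  results$call_fused <- if (mode == "strict") {
    bh_fdr(results$fused_p, config$strict_fdr_q)
  } else {
    results$fused_p < config$lenient_alpha
  }
  attr(results, "call_mode") <- mode
  results
}

#' Summarize fused versus single-omics calls
#'
#' Counts and ratios over the background gene universe: fused calls,
#' sequence-only calls (strict or lenient column, matching the mode used
#' for the fused call), their overlap, and the genes recalled by fusion
#' alone.
#'
#' @param results data.frame with call columns (see [call_significance()]).
#' @param mode which sequence call column to compare against; defaults to
#'   the mode recorded on the results.
#' @return list of class \code{pheseq_summary} with fields n_background,
#'   n_fused_sig, ratio_fused, n_seq_sig, ratio_seq, n_overlap, n_recalled.
#' @export
summarize_calls <- function(results, mode = NULL) {
  if (is.null(mode)) mode <- attr(results, "call_mode")
  if (is.null(mode)) mode <- "strict"
  seq_call <- if (mode == "strict") results$call_seq_strict else
    results$call_seq_lenient
  n_bg <- nrow(results)
  n_fused <- sum(results$call_fused)
  n_seq <- sum(seq_call)
  n_overlap <- sum(results$call_fused & seq_call)
  structure(list(
    n_background = n_bg,
    n_fused_sig = n_fused,
    ratio_fused = if (n_bg > 0) n_fused / n_bg else NA_real_,
    n_seq_sig = n_seq,
    ratio_seq = if (n_bg > 0) n_seq / n_bg else NA_real_,
    n_overlap = n_overlap,
    n_recalled = n_fused - n_overlap,
    call_mode = mode
  ), class = "pheseq_summary")
}

#' @export
print.pheseq_summary <- function(x, ...) {
  cat("fused vs sequence calls (", x$call_mode, ")\n", sep = "")
  cat(sprintf("  background genes %d\n", x$n_background))
  cat(sprintf("  fused significant %d (%.2f%%)\n", x$n_fused_sig,
              100 * x$ratio_fused))
  cat(sprintf("  sequence significant %d (%.2f%%)\n", x$n_seq_sig,
              100 * x$ratio_seq))
  cat(sprintf("  overlap %d, recalled by fusion only %d\n", x$n_overlap,
              x$n_recalled))
  invisible(x)
}

# deterministic ranking: descending fused posterior, ties by ascending
# sequence p-value, then gene id
rank_genes <- function(results) {
  order(-results$fused_posterior, results$p_seq, results$gene_id)
}

#' Recall against a benchmark gene set
#'
#' Hits are benchmark genes among the fused calls; the cumulative curve
#' counts benchmark genes among the top-k ranked genes (ranking: descending
#' fused posterior, ties broken by ascending sequence p-value, then
#' gene id).
#'
#' @param results data.frame with \code{call_fused} filled.
#' @param benchmark list from [read_benchmark()] (or any list with a
#'   \code{genes} character vector).
#' @param k_list integer vector of list depths for the cumulative curve.
#' @return list with \code{hits}, \code{recall} (hits / benchmark size),
#'   \code{benchmark_size}, \code{source_tag} and a data.frame
#'   \code{curve} (k, hits).
#' @export
recall_vs_benchmark <- function(results, benchmark,
                                k_list = c(10L, 20L, 50L, 100L)) {
  genes <- unique(benchmark$genes)
  if (length(genes) == 0) stop("benchmark gene set is empty", call. = FALSE)
  called <- results$gene_id[results$call_fused]
  hits <- length(intersect(called, genes))
  ranked <- results$gene_id[rank_genes(results)]
  k_list <- sort(unique(pmin(as.integer(k_list), length(ranked))))
  curve <- data.frame(
    k = k_list,
    hits = vapply(k_list, function(k)
      length(intersect(ranked[seq_len(k)], genes)), integer(1))
  )
  list(hits = hits, recall = hits / length(genes),
       benchmark_size = length(genes),
       source_tag = benchmark$source_tag %||% "",
       curve = curve)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the full JSON-ready summary report
#'
#' @param results called results table.
#' @param benchmark optional benchmark set; adds a recall section.
#' @param k_list list depths for the recall curve.
#' @return nested list ready for \code{jsonlite::write_json}.
#' @export
summary_report <- function(results, benchmark = NULL,
                           k_list = c(10L, 20L, 50L, 100L)) {
  rep_ <- unclass(summarize_calls(results))
  if (!is.null(benchmark)) {
    rec <- recall_vs_benchmark(results, benchmark, k_list)
    rep_$recall <- list(
      source_tag = rec$source_tag,
      hits = rec$hits,
      benchmark_size = rec$benchmark_size,
      recall = rec$recall,
      curve = rec$curve
    )
  }
  rep_
}
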