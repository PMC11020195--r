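# Versioned model archive: a plain RDS holding the fit and a format
# version, checked on load so stale archives fail loudly.

ARCHIVE_VERSION <- 1L

#' Save a fitted model to a versioned archive
#'
#' @param fit a \code{pheseq_fit}.
#' @param path output file path (RDS).
#' @return invisibly, the path.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "pheseq_fit"))
  saveRDS(list(format = "pheseq_model", version = ARCHIVE_VERSION,
               fit = fit), path)
  invisible(path)
}

#' Load a fitted model from an archive
#'
#' @param path archive path written by [save_model()].
#' @return the stored \code{pheseq_fit}.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "pheseq_model")) {
    stop("not a model archive: ", path, call. = FALSE)
  }
  if (!identical(obj$version, ARCHIVE_VERSION)) {
    stop("model archive version ", obj$version, " does not match supported ",
         "version ", ARCHIVE_VERSION, call. = FALSE)
  }
  obj$fit
}
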