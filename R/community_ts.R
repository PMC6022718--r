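#' Community time series container
#'
#' A light wrapper around a taxa-by-time numeric matrix carrying the sampling
#' interval, whether entries are relative abundances, and the generating
#' model (when simulated).
#'
#' @param abundances numeric matrix, taxa in rows, time points in columns;
#'   all entries must be finite and non-negative.
#' @param time_step positive sampling interval in model steps.
#' @param is_relative logical; if `TRUE` every column must sum to 1
#'   (within 1e-9) and all-zero columns are forbidden.
#' @param taxon_ids character vector of taxon identifiers (defaults to
#'   rownames or `sp1..spS`).
#' @param model_tag provenance string, e.g. `"ricker"`, `"hubbell"`.
#'
#' @return an object of class `community_ts` (a matrix with attributes).
#' @export
community_ts <- function(abundances, time_step = 1, is_relative = FALSE,
                         taxon_ids = NULL, model_tag = "unknown") {
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  if (any(!is.finite(abundances))) stop("abundances must be finite")
  if (any(abundances < 0)) stop("abundances must be non-negative")
  if (time_step <= 0) stop("time_step must be positive")
  if (is.null(taxon_ids)) {
    taxon_ids <- rownames(abundances)
    if (is.null(taxon_ids)) taxon_ids <- paste0("sp", seq_len(nrow(abundances)))
  }
  rownames(abundances) <- taxon_ids
  if (is.null(colnames(abundances))) {
    colnames(abundances) <- paste0("t", seq_len(ncol(abundances)))
  }
  if (isTRUE(is_relative)) {
    cs <- colSums(abundances)
    if (any(abs(cs - 1) > 1e-9)) {
      stop("relative abundance columns must sum to 1 (within 1e-9)")
    }
  }
  structure(abundances,
            time_step = time_step, is_relative = isTRUE(is_relative),
            model_tag = model_tag, class = c("community_ts", "matrix", "array"))
}

#' @export
print.community_ts <- function(x, ...) {
  cat(sprintf("<community_ts> %d taxa x %d time points (%s, %s, interval %g)\n",
              nrow(x), ncol(x), attr(x, "model_tag"),
              if (attr(x, "is_relative")) "relative" else "absolute",
              attr(x, "time_step")))
  invisible(x)
}

#' Convert a community time series to relative abundances
#'
#' Columns are normalized to sum to 1. An all-zero column cannot be
#' normalized and raises an error.
#'
#' @param ts a [community_ts()] or a taxa-by-time matrix.
#' @return a `community_ts` with `is_relative = TRUE`.
#' @export
relative_abundances <- function(ts) {
  x <- unclass_ts(ts)
  cs <- colSums(x)
  if (any(cs <= 0)) stop("cannot normalize: some columns sum to zero")
  out <- sweep(x, 2, cs, "/")
  community_ts(out, time_step = ts_time_step(ts), is_relative = TRUE,
               taxon_ids = rownames(x), model_tag = ts_model_tag(ts))
}

# internal accessors tolerating bare matrices
unclass_ts <- function(ts) {
  x <- as.matrix(unclass(ts))
  attr(x, "time_step") <- NULL
  attr(x, "is_relative") <- NULL
  attr(x, "model_tag") <- NULL
  x
}
ts_time_step <- function(ts) {
  v <- attr(ts, "time_step")
  if (is.null(v)) 1 else v
}
ts_is_relative <- function(ts) isTRUE(attr(ts, "is_relative"))
ts_model_tag <- function(ts) {
  v <- attr(ts, "model_tag")
  if (is.null(v)) "unknown" else v
}
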