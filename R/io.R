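#' Write a community time series as tab-separated text
#'
#' Taxa as rows, time points as columns; the first column holds taxon
#' identifiers and the header row the time labels.
#'
#' @param ts a [community_ts()].
#' @param path output file.
#' @export
write_community_ts <- function(ts, path) {
  x <- unclass_ts(ts)
  df <- data.frame(taxon = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a community time series from tab-separated text
#'
#' @param path input file in the layout written by [write_community_ts()].
#' @param time_step sampling interval metadata.
#' @param is_relative whether entries are relative abundances.
#' @param model_tag provenance string.
#' @return a [community_ts()].
#' @export
read_community_ts <- function(path, time_step = 1, is_relative = FALSE,
                              model_tag = "file") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- as.character(df[[1]])
  community_ts(x, time_step = time_step, is_relative = is_relative,
               model_tag = model_tag)
}

#' Write an interaction matrix as tab-separated text
#'
#' Square table with taxon identifiers as row and column headers; rows are
#' targets, columns are sources.
#'
#' @param A an [interaction_matrix()] or square matrix.
#' @param path output file.
#' @export
write_interaction_matrix <- function(A, path) {
  A <- as.matrix(A)
  df <- data.frame(taxon = rownames(A), A, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction matrix from tab-separated text
#' @param path input file in the layout written by
#'   [write_interaction_matrix()].
#' @return an [interaction_matrix()].
#' @export
read_interaction_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- as.character(df[[1]])
  colnames(A) <- rownames(A)
  interaction_matrix(A)
}

#' Export an interaction matrix as an edge list
#'
#' @param A square matrix.
#' @param keep_diagonal include self-loops.
#' @return data.frame with columns source, target, sign, weight.
#' @export
interaction_edge_list <- function(A, keep_diagonal = FALSE) {
  A <- as.matrix(A)
  w <- which(A != 0, arr.ind = TRUE)
  if (!keep_diagonal) w <- w[w[, 1] != w[, 2], , drop = FALSE]
  data.frame(
    source = colnames(A)[w[, 2]],
    target = rownames(A)[w[, 1]],
    sign = ifelse(A[w] > 0, "+", "-"),
    weight = A[w],
    stringsAsFactors = FALSE)
}
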