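#' Add Poisson measurement noise
#'
#' Replaces every entry by a Poisson draw with mean `scale * x`. The default
#' scale depends on the generating model (chosen so that count magnitudes
#' are comparable across models): 1000 for Ricker and gLV, 2 for Hubbell,
#' 1 for DM, 50 for SOI.
#'
#' @param ts a [community_ts()] (non-negative).
#' @param scale positive scaling factor; when `NULL` the model tag decides.
#' @param seed optional RNG seed.
#' @return a [community_ts()] of noisy counts.
#' @export
add_poisson_noise <- function(ts, scale = NULL, seed = NULL) {
  .ecosig_seed(seed)
  if (is.null(scale)) scale <- poisson_scale_for(ts_model_tag(ts))
  if (scale <= 0) stop("scale must be positive")
  x <- unclass_ts(ts)
  y <- matrix(stats::rpois(length(x), lambda = scale * x), nrow = nrow(x),
              dimnames = dimnames(x))
  community_ts(y, time_step = ts_time_step(ts), model_tag = ts_model_tag(ts))
}

#' Default Poisson noise scale per generating model
#' @param model_tag model provenance string.
#' @return a positive scale.
#' @export
poisson_scale_for <- function(model_tag) {
  switch(model_tag,
         ricker = 1000, glv = 1000, hubbell = 2, dm = 1, soi = 50,
         1)
}

#' Add multinomial sequencing noise
#'
#' Per time point, draws a sequencing depth uniformly from `depth_range`
#' and resamples the column as `Multinomial(depth, proportions)`.
#'
#' @param ts a [community_ts()]; columns are converted to proportions
#'   (all-zero columns are an error).
#' @param depth_range integer depth bounds, default `c(1000, 1500)`.
#' @param seed optional RNG seed.
#' @return a [community_ts()] of counts.
#' @export
add_multinomial_noise <- function(ts, depth_range = c(1000, 1500), seed = NULL) {
  .ecosig_seed(seed)
  x <- unclass_ts(ts)
  cs <- colSums(x)
  if (any(cs <= 0)) stop("all-zero columns cannot be resampled")
  depths <- sample(seq(depth_range[1], depth_range[2]), ncol(x), replace = TRUE)
  y <- vapply(seq_len(ncol(x)),
              function(t) rmultinom(1, depths[t], x[, t] / cs[t])[, 1],
              numeric(nrow(x)))
  dimnames(y) <- dimnames(x)
  community_ts(y, time_step = ts_time_step(ts), model_tag = ts_model_tag(ts))
}

#' Thin a time series to a sampling interval
#'
#' Keeps columns `1, 1 + interval, 1 + 2 * interval, ...` and multiplies
#' the recorded sampling interval accordingly.
#'
#' @param ts a [community_ts()].
#' @param interval positive integer, must be smaller than the number of
#'   time points.
#' @return a [community_ts()].
#' @export
thin_to_interval <- function(ts, interval) {
  interval <- as.integer(interval)
  if (interval < 1) stop("interval must be at least 1")
  x <- unclass_ts(ts)
  if (interval >= ncol(x)) stop("interval must be smaller than the number of time points")
  keep <- seq(1, ncol(x), by = interval)
  community_ts(x[, keep, drop = FALSE],
               time_step = ts_time_step(ts) * interval,
               is_relative = ts_is_relative(ts),
               model_tag = ts_model_tag(ts))
}

#' Rarefy a count column to fixed depth
#'
#' Subsamples reads without replacement to exactly `depth` per sample.
#'
#' @param counts_column integer counts for one sample.
#' @param depth target depth; the column sum must be at least `depth`.
#' @param seed optional RNG seed.
#' @param sample_name used in the error message.
#' @return rarefied counts summing to `depth`.
#' @export
rarefy_counts <- function(counts_column, depth, seed = NULL,
                          sample_name = "sample") {
  .ecosig_seed(seed)
  counts <- as.integer(round(counts_column))
  total <- sum(counts)
  if (total < depth) {
    stop(sprintf("sample '%s' has only %d reads, cannot rarefy to %d",
                 sample_name, total, depth))
  }
  if (total == depth) return(counts)
  # sequential multivariate hypergeometric draw
  out <- integer(length(counts))
  remaining <- depth
  rest <- total
  for (i in seq_along(counts)) {
    if (remaining == 0) break
    rest <- rest - counts[i]
    d <- stats::rhyper(1, counts[i], rest, remaining)
    out[i] <- d
    remaining <- remaining - d
  }
  names(out) <- names(counts_column)
  out
}

#' Rarefy every sample of a count table
#' @param ts a [community_ts()] of counts.
#' @param depth target depth per sample.
#' @param seed optional RNG seed.
#' @return a [community_ts()].
#' @export
rarefy_table <- function(ts, depth = 10000, seed = NULL) {
  .ecosig_seed(seed)
  x <- unclass_ts(ts)
  y <- vapply(seq_len(ncol(x)),
              function(j) rarefy_counts(x[, j], depth,
                                        sample_name = colnames(x)[j]),
              integer(nrow(x)))
  dimnames(y) <- dimnames(x)
  community_ts(y, time_step = ts_time_step(ts), model_tag = ts_model_tag(ts))
}

#' Interpolate a series onto an equidistant grid
#'
#' Monotone piecewise-cubic interpolation (Fritsch-Carlson, no overshoot
#' between observations) of each taxon onto the integer grid spanning the
#' observation window; any small negative interpolants are clipped to 0.
#'
#' @param ts a [community_ts()] whose columns were observed at
#'   `observation_times`.
#' @param observation_times strictly increasing observation times (>= 2).
#' @return a [community_ts()] on the unit-spaced grid.
#' @export
interpolate_equidistant <- function(ts, observation_times) {
  x <- unclass_ts(ts)
  tt <- as.numeric(observation_times)
  if (length(tt) != ncol(x)) stop("one observation time per column required")
  if (length(tt) < 2) stop("need at least 2 observation times")
  if (anyDuplicated(tt)) stop("duplicate observation times")
  if (is.unsorted(tt)) stop("observation times must be increasing")
  grid <- seq(ceiling(tt[1]), floor(tt[length(tt)]))
  y <- t(apply(x, 1, function(row) {
    f <- splinefun(tt, row, method = "monoH.FC")
    pmax(f(grid), 0)
  }))
  colnames(y) <- paste0("t", grid)
  community_ts(y, time_step = 1, model_tag = ts_model_tag(ts))
}

#' Three-step classification of a community time series
#'
#' Runs the classification scheme: (1) noise-type profiling — when the
#' white-taxon percentage exceeds `white_threshold` the series is declared
#' unstructured and the pipeline stops; (2) otherwise the neutral
#' covariance test — when `p > alpha` the series is declared neutral and no
#' interactions are inferred; (3) otherwise LIMITS interaction inference.
#' Interaction inference is attached only for structured, non-neutral
#' series.
#'
#' @param ts a [community_ts()].
#' @param white_threshold percentage of white taxa above which the series
#'   counts as unstructured (default 50; a configurable convention, always
#'   reported in the output).
#' @param alpha significance level of the neutrality test.
#' @param n_transformations,null_replicates passed to
#'   [neutral_covariance_test()].
#' @param n_top,n_bags,improvement_threshold passed to [limits_infer()].
#' @param relative analyze relative abundances.
#' @param strict strict noise-class boundaries.
#' @param seed optional RNG seed (all stages draw from one stream).
#' @return an object of class `classification_report`.
#' @export
classify_time_series <- function(ts, white_threshold = 50, alpha = 0.05,
                                 n_transformations = 500, null_replicates = 200,
                                 n_top = 60, n_bags = 100,
                                 improvement_threshold = 0.05,
                                 relative = TRUE, strict = FALSE, seed = NULL) {
  .ecosig_seed(seed)
  profile <- community_noise_profile(ts, relative = relative, strict = strict)
  white_pct <- profile$class_percentages[["white"]]
  structured <- white_pct <= white_threshold

  neutrality <- NULL
  inference <- NULL
  if (structured) {
    neutrality <- neutral_covariance_test(ts,
                                          n_transformations = n_transformations,
                                          null_replicates = null_replicates)
    if (neutrality$p_value <= alpha) {
      inference <- limits_infer(ts, n_top = n_top, n_bags = n_bags,
                                improvement_threshold = improvement_threshold,
                                relative = relative)
    }
  }
  structure(list(
    structure_verdict = if (structured) "structured" else "unstructured",
    white_percentage = white_pct,
    white_threshold = white_threshold,
    noise_profile = profile,
    neutrality_verdict = if (is.null(neutrality)) NA_character_
      else if (neutrality$p_value > alpha) "neutral" else "non-neutral",
    neutrality = neutrality,
    alpha = alpha,
    inference = inference,
    provenance = list(model_tag = ts_model_tag(ts), seed = seed,
                      n_taxa = nrow(ts), n_timepoints = ncol(ts),
                      time_step = ts_time_step(ts))),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> (%s)\n", x$provenance$model_tag))
  cat(sprintf("  step 1: %s (white %.1f%%, threshold %g%%)\n",
              x$structure_verdict, x$white_percentage, x$white_threshold))
  if (!is.na(x$neutrality_verdict)) {
    cat(sprintf("  step 2: %s (p = %.4g)\n", x$neutrality_verdict,
                x$neutrality$p_value))
  } else {
    cat("  step 2: skipped (unstructured)\n")
  }
  if (!is.null(x$inference)) {
    cat(sprintf("  step 3: LIMITS fit, goodness of fit %.3f\n",
                x$inference$goodness_of_fit))
  } else {
    cat("  step 3: skipped\n")
  }
  invisible(x)
}

#' Summarize an inferred interaction network
#'
#' Counts positive and negative links, per-node degrees (hub report), and
#' intra-/inter-phylum link numbers (matrix entries counted *including* the
#' diagonal), with significance from repeatedly randomizing the positions
#' of the non-zero entries over all matrix slots while preserving their
#' values. Empirical p-values are `(1 + #{randomized >= observed}) /
#' (n_randomizations + 1)`.
#'
#' @param A_hat square interaction matrix with taxon dimnames.
#' @param taxon_metadata data.frame with columns `taxon` and `phylum`
#'   covering every matrix taxon.
#' @param n_randomizations number of randomizations (default 100).
#' @param seed optional RNG seed.
#' @return an object of class `network_summary`.
#' @export
network_summary <- function(A_hat, taxon_metadata, n_randomizations = 100,
                            seed = NULL) {
  .ecosig_seed(seed)
  A <- as.matrix(A_hat)
  S <- nrow(A)
  taxa <- rownames(A)
  if (is.null(taxa)) stop("A_hat needs taxon dimnames")
  idx <- match(taxa, taxon_metadata$taxon)
  if (any(is.na(idx))) {
    stop(sprintf("unlabeled taxa: %s",
                 paste(taxa[is.na(idx)], collapse = ", ")))
  }
  phylum <- as.character(taxon_metadata$phylum[idx])

  offdiag <- row(A) != col(A)
  nz_off <- offdiag & A != 0
  n_pos <- sum(A > 0 & offdiag)
  n_neg <- sum(A < 0 & offdiag)
  pct_negative <- if (n_pos + n_neg > 0) 100 * n_neg / (n_pos + n_neg) else NA_real_

  degree <- data.frame(
    taxon = taxa,
    out_degree = colSums(nz_off),  # column = source
    in_degree = rowSums(nz_off),
    negative_links = colSums(A < 0 & offdiag) + rowSums(A < 0 & offdiag),
    stringsAsFactors = FALSE)

  # phylum-pair link counts include the diagonal
  phyla <- sort(unique(phylum))
  pair_count <- function(M) {
    nz <- M != 0
    tab <- matrix(0L, length(phyla), length(phyla),
                  dimnames = list(phyla, phyla))
    w <- which(nz, arr.ind = TRUE)
    if (nrow(w) > 0) {
      for (r in seq_len(nrow(w))) {
        pi <- phylum[w[r, 1]]; pj <- phylum[w[r, 2]]
        tab[pi, pj] <- tab[pi, pj] + 1L
      }
    }
    tab
  }
  obs_tab <- pair_count(A)

  vals <- A[A != 0]
  ge_count <- matrix(0L, length(phyla), length(phyla),
                     dimnames = list(phyla, phyla))
  for (r in seq_len(n_randomizations)) {
    M <- matrix(0, S, S)
    M[sample.int(S * S, length(vals))] <- vals
    rt <- pair_count(M)
    ge_count <- ge_count + (rt >= obs_tab)
  }
  p_values <- (1 + ge_count) / (n_randomizations + 1)

  structure(list(n_links = sum(A != 0), n_positive = n_pos, n_negative = n_neg,
                 negative_link_percentage = pct_negative,
                 degree = degree, phylum_link_counts = obs_tab,
                 phylum_link_p_values = p_values,
                 n_randomizations = n_randomizations),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> %d entries (%d+, %d-), %.1f%% negative links\n",
              x$n_links, x$n_positive, x$n_negative,
              x$negative_link_percentage))
  invisible(x)
}
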