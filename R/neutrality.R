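#' Constant-volatility transformation of a share series
#'
#' Under neutral (Wright-Fisher-type) drift the variance of share
#' increments is proportional to `x * (1 - x)`. The arcsine map
#' `f(x) = asin(2x - 1)` (derivative `1 / sqrt(x (1 - x))`) renders the
#' increment variance state-independent; it is the reference transform.
#' The `"logitnorm"` method works on the logit scale: the transformed
#' series is `logit(x)`, and the matching increment model rescales logit
#' increments by `sqrt(x (1 - x))` (see [grouping_statistic()]), which
#' stabilizes Wright-Fisher volatility as well. Values at 0 or 1 are
#' shrunk into `(eps, 1 - eps)` first.
#'
#' @param x share series in `[0, 1]`.
#' @param method `"logitnorm"` (default) or `"arcsine"`.
#' @param eps boundary shrinkage.
#' @return the transformed series.
#' @export
volatility_stabilizing_transform <- function(x, method = c("logitnorm", "arcsine"),
                                             eps = 1e-6) {
  method <- match.arg(method)
  if (any(x < 0 | x > 1)) stop("shares must lie in [0, 1]")
  x <- pmin(pmax(x, eps), 1 - eps)
  switch(method,
         arcsine = asin(2 * x - 1),
         logitnorm = qlogis(x))
}

# Variance-stabilized increments of share paths (rows of G).
# Returns E (increments, n x (T-1)) and V (state g*(1-g) at the left end).
.stabilized_increments <- function(G, method, eps = 1e-6) {
  G <- pmin(pmax(G, eps), 1 - eps)
  T <- ncol(G)
  left <- G[, -T, drop = FALSE]
  right <- G[, -1, drop = FALSE]
  if (method == "arcsine") {
    E <- asin(2 * right - 1) - asin(2 * left - 1)
  } else {
    mid <- (left + right) / 2
    E <- (qlogis(right) - qlogis(left)) * sqrt(mid * (1 - mid))
  }
  list(E = E, V = left * (1 - left))
}

# Row-wise Pearson correlation between rows of A and rows of B.
.row_cor <- function(A, B) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  num <- rowSums(A * B)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Heteroskedasticity score of a grouped share series
#'
#' Sums the relative abundances of the taxa in one side of a binary
#' partition into an aggregate share `g(t)`, applies the constant-volatility
#' transformation, and returns the correlation between squared transformed
#' increments and the volatility state `g (1 - g)` (a normalized
#' squared-increment regression slope). Under Wright-Fisher drift the
#' transformed increments have state-independent variance and the score is
#' centered on zero; the score is invariant to swapping the partition with
#' its complement. The per-partition volatility level (mean squared
#' transformed increment), which the neutral covariance test compares
#' across partitions, is attached as attribute `"volatility"`.
#'
#' @param ts a [community_ts()] (converted to relative abundances).
#' @param grouping logical or integer index vector selecting one non-empty
#'   side of the partition (the other side must be non-empty too).
#' @param method `"logitnorm"` or `"arcsine"`.
#' @return the score, or `NA` for a degenerate (constant) aggregate.
#' @export
grouping_statistic <- function(ts, grouping, method = c("logitnorm", "arcsine")) {
  method <- match.arg(method)
  x <- unclass_ts(if (ts_is_relative(ts)) ts else relative_abundances(ts))
  sel <- seq_len(nrow(x)) %in% (if (is.logical(grouping)) which(grouping) else grouping)
  if (!any(sel) || all(sel)) stop("both sides of the partition must be non-empty")
  g <- colSums(x[sel, , drop = FALSE])
  if (sd(g) < 1e-12) {
    return(structure(NA_real_, volatility = NA_real_))
  }
  si <- .stabilized_increments(matrix(g, nrow = 1), method)
  score <- .row_cor(si$E^2, si$V)
  structure(as.numeric(score), volatility = mean(si$E^2))
}

# Group-invariance F-ratio over many partitions.
# P: n_part x S indicator matrix; X: S x T relative abundances.
# Under neutrality every partition's stabilized volatility estimates one
# common constant; the statistic is the between-partition variance of the
# volatility estimates over their average within-partition sampling
# variance (lag-1 serial-correlation corrected).
.invariance_statistic <- function(P, X, method) {
  G <- P %*% X
  keep <- apply(G, 1, sd) >= 1e-12
  n_deg <- sum(!keep)
  if (sum(keep) < 3) {
    return(list(statistic = NA_real_, vols = NULL, n_degenerate = n_deg))
  }
  si <- .stabilized_increments(G[keep, , drop = FALSE], method)
  W <- si$E^2
  vols <- rowMeans(W)
  Wc <- W - vols
  n <- ncol(W)
  g0 <- rowSums(Wc^2) / n
  g1 <- rowSums(Wc[, -1, drop = FALSE] * Wc[, -n, drop = FALSE]) / n
  se2 <- pmax(g0 + 2 * pmax(g1, 0), .Machine$double.xmin) / n
  list(statistic = var(vols) / mean(se2), vols = vols, n_degenerate = n_deg)
}

# Median lag-1 autoregression coefficient of arcsine-transformed aggregates;
# measures the mean reversion the neutral surrogate must match.
.aggregate_ar1 <- function(P, X, eps = 1e-6) {
  G <- pmin(pmax(P %*% X, eps), 1 - eps)
  U <- asin(2 * G - 1)
  U <- U - rowMeans(U)
  n <- ncol(U)
  num <- rowSums(U[, -1, drop = FALSE] * U[, -n, drop = FALSE])
  den <- rowSums(U^2)
  phi <- num / den
  phi <- phi[is.finite(phi)]
  if (length(phi) == 0) return(1)
  median(phi)
}

# Multinomial Wright-Fisher proportion path (S x T) with immigration m
# toward the fixed pool p0 (m = 0: pure drift; m = 1: i.i.d. sampling).
.wright_fisher_path <- function(p0, Ne, m, T) {
  S <- length(p0)
  out <- matrix(0, S, T)
  counts <- as.integer(rmultinom(1, Ne, p0))
  out[, 1] <- counts / Ne
  for (t in 2:T) {
    q <- (1 - m) * counts / Ne + m * p0
    counts <- as.integer(rmultinom(1, Ne, q))
    out[, t] <- counts / Ne
  }
  out
}

#' Neutral covariance test
#'
#' Tests whether a community time series is compatible with neutral
#' (species-identity-free) drift by checking group invariance of the
#' covariance structure. For `n_transformations` random balanced binary
#' partitions of the taxa, the aggregated share path is
#' volatility-stabilized; under any neutral (Wright-Fisher-type) model the
#' stabilized increment variance is one common constant regardless of how
#' species are grouped, whereas interactions or species-specific rates make
#' it grouping-dependent. The test statistic is an F-ratio: the
#' between-partition variance of the fitted volatilities over their
#' average within-partition sampling variance (corrected for lag-1 serial
#' correlation of the squared increments). Its null distribution is
#' calibrated by parametric bootstrap against multinomial Wright-Fisher
#' surrogates matched to the observed community (same number of taxa and
#' time points, mean composition, fitted volatility via an effective
#' population size, and fitted mean reversion via an immigration rate);
#' the p-value is two-sided, so covariance structure both more and less
#' grouping-dependent than neutral drift is flagged.
#'
#' @param ts a [community_ts()] with >= 3 taxa and >= 10 time points.
#' @param n_transformations number of random partitions (default 500).
#' @param method `"logitnorm"` (default) or `"arcsine"`.
#' @param seed optional RNG seed.
#' @param null_replicates bootstrap replicates for the null calibration.
#' @return an object of class `neutrality_result` with fields `statistic`,
#'   `p_value`, `n_transformations`, `method`, `n_degenerate`,
#'   `effective_population`, `immigration`, `null_statistics`.
#' @export
neutral_covariance_test <- function(ts, n_transformations = 500,
                                    method = c("logitnorm", "arcsine"),
                                    seed = NULL, null_replicates = 200) {
  method <- match.arg(method)
  if (n_transformations < 1) stop("n_transformations must be at least 1")
  x <- unclass_ts(if (ts_is_relative(ts)) ts else relative_abundances(ts))
  S <- nrow(x)
  T <- ncol(x)
  if (S < 3) stop("need at least 3 taxa")
  if (T < 10) stop("need at least 10 time points")
  .ecosig_seed(seed)

  # canonical taxon order (by decreasing mean abundance) makes the partition
  # stream invariant to row relabeling
  ord <- order(-rowMeans(x), rowSums(x != 0))
  x <- x[ord, , drop = FALSE]

  half <- floor(S / 2)
  P <- matrix(0, n_transformations, S)
  for (k in seq_len(n_transformations)) {
    P[k, sample.int(S, half)] <- 1
  }

  obs <- .invariance_statistic(P, x, method)
  if (obs$n_degenerate >= n_transformations) {
    stop("all groupings are degenerate (constant aggregates); test failed")
  }
  statistic <- obs$statistic
  if (!is.finite(statistic)) stop("test statistic undefined for this input")

  # matched neutral surrogate: effective population size from the fitted
  # volatility (Var(e) ~ 1/Ne per step), immigration from mean reversion
  vols <- obs$vols[is.finite(obs$vols) & obs$vols > 0]
  Ne <- 1 / median(vols)
  Ne <- min(max(round(Ne), 10 * S), 1e8)
  m <- min(max(1 - .aggregate_ar1(P, x), 0), 1)
  p0 <- rowMeans(x)
  p0 <- pmax(p0, 1e-8)
  p0 <- p0 / sum(p0)

  null_stats <- rep(NA_real_, null_replicates)
  for (r in seq_len(null_replicates)) {
    Xn <- .wright_fisher_path(p0, Ne, m, T)
    null_stats[r] <- .invariance_statistic(P, Xn, method)$statistic
  }
  null_stats <- null_stats[is.finite(null_stats)]
  if (length(null_stats) < 20) stop("null calibration failed (degenerate surrogates)")
  center <- median(null_stats)
  p <- (1 + sum(abs(null_stats - center) >= abs(statistic - center))) /
    (length(null_stats) + 1)

  structure(list(statistic = statistic, p_value = p,
                 n_transformations = n_transformations, method = method,
                 n_degenerate = obs$n_degenerate,
                 effective_population = Ne, immigration = m,
                 null_statistics = null_stats),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf(paste0("<neutrality_result> statistic %.4f, p = %.4g ",
                     "(%d groupings, method %s)\n  %s at alpha = 0.05\n"),
              x$statistic, x$p_value, x$n_transformations, x$method,
              if (x$p_value < 0.05) "neutrality REJECTED" else "consistent with neutrality"))
  invisible(x)
}
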