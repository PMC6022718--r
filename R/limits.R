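#' Infer a Ricker interaction matrix with LIMITS
#'
#' Forward stepwise regression with bagging. For each focal taxon `i` the
#' log-abundance increment `y_i(t) = ln x_i(t+1) - ln x_i(t)` is regressed
#' on predictor abundances `x_j(t)` (intercept included, self-interaction
#' always kept). Predictors are added greedily while the held-out error of
#' a random half split improves by more than `improvement_threshold`
#' (relative). Coefficients are aggregated over `n_bags` splits by the
#' median, a predictor selected in fewer than half the bags yielding 0.
#' The carrying capacity of each taxon is estimated as its mean abundance.
#'
#' @param ts a [community_ts()] with >= 20 time points.
#' @param n_top number of top-abundant taxa (ranked by abundance sum) to
#'   analyze; capped at the number of available taxa.
#' @param n_bags number of random half splits (default 100).
#' @param improvement_threshold relative held-out error improvement required
#'   to accept a predictor (default 0.05).
#' @param seed optional RNG seed.
#' @param relative analyze relative abundances (default, matching
#'   sequencing-data practice) or the raw matrix.
#' @param max_predictors cap on the number of non-self predictors per taxon.
#' @param abundance_floor values below this are raised to it before logs.
#' @return an object of class `limits_fit` with fields `inferred_matrix`,
#'   `carrying_capacities`, `selection_frequency`, `kept_predictors`,
#'   `n_bags`, `goodness_of_fit`, `predicted`, `observed`, `taxa`.
#' @export
limits_infer <- function(ts, n_top = 60, n_bags = 100,
                         improvement_threshold = 0.05, seed = NULL,
                         relative = TRUE, max_predictors = 15,
                         abundance_floor = 1e-10) {
  x <- unclass_ts(if (relative && !ts_is_relative(ts)) relative_abundances(ts) else ts)
  T <- ncol(x)
  if (T < 20) stop("need at least 20 time points")
  nonzero <- rowSums(x) > 0
  if (!all(nonzero)) {
    warning(sprintf("excluding %d taxa with zero abundance throughout",
                    sum(!nonzero)))
    x <- x[nonzero, , drop = FALSE]
  }
  if (nrow(x) < 3) stop("need at least 3 taxa with non-degenerate variation")
  .ecosig_seed(seed)
  n_top <- min(n_top, nrow(x))
  keep <- order(-rowSums(x))[seq_len(n_top)]
  keep <- sort(keep) # preserve original taxon order
  x <- x[keep, , drop = FALSE]

  xf <- pmax(x, abundance_floor)
  lx <- log(xf)
  Y <- t(lx[, -1, drop = FALSE] - lx[, -T, drop = FALSE]) # (T-1) x S
  X <- t(xf[, -T, drop = FALSE])                          # (T-1) x S
  fit <- .limits_bag_cpp(X, Y, as.integer(n_bags), improvement_threshold,
                         as.integer(max_predictors))
  A_hat <- fit$matrix
  freq <- fit$frequency
  dimnames(A_hat) <- dimnames(freq) <- list(rownames(x), rownames(x))
  K_hat <- rowMeans(x)

  kept <- lapply(seq_len(nrow(A_hat)), function(i) {
    colnames(A_hat)[freq[i, ] >= 0.5]
  })
  names(kept) <- rownames(A_hat)

  pred <- predict_one_step(x, A_hat, K_hat)
  gof <- goodness_of_fit(x, pred)

  structure(list(inferred_matrix = A_hat, carrying_capacities = K_hat,
                 selection_frequency = freq, kept_predictors = kept,
                 n_bags = n_bags, improvement_threshold = improvement_threshold,
                 goodness_of_fit = gof, predicted = pred, observed = x,
                 taxa = rownames(x)),
            class = "limits_fit")
}

#' @export
print.limits_fit <- function(x, ...) {
  cat(sprintf(paste0("<limits_fit> %d taxa, %d bags, goodness of fit %.3f, ",
                     "%d non-zero off-diagonal entries\n"),
              length(x$taxa), x$n_bags, x$goodness_of_fit,
              sum(x$inferred_matrix[row(x$inferred_matrix) !=
                                      col(x$inferred_matrix)] != 0)))
  invisible(x)
}

#' Stabilize an inferred interaction matrix
#'
#' If the matrix has an eigenvalue with positive real part, it is
#' Schur-factorized, the offending diagonal entries of the (quasi-)
#' triangular factor are shifted to `-epsilon`, and the matrix is
#' reconstructed, so that no eigenvalue with positive real part remains.
#' Matrices that are already stable are returned unchanged.
#'
#' @param A_hat square real matrix.
#' @param epsilon magnitude of the shifted diagonal entries.
#' @return a matrix with spectral abscissa <= 0.
#' @export
stabilize_interaction_matrix <- function(A_hat, epsilon = 1e-4) {
  A <- as.matrix(A_hat)
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) <= 0) return(A_hat)
  sch <- Matrix::Schur(Matrix::Matrix(A))
  Q <- as.matrix(sch@Q)
  Tm <- as.matrix(sch@T)
  # LAPACK standardizes 2x2 blocks with equal diagonal entries = real part,
  # so shifting positive diagonal entries shifts the real parts.
  d <- diag(Tm)
  d[d > 0] <- -epsilon
  diag(Tm) <- d
  out <- Q %*% Tm %*% t(Q)
  abscissa <- max(Re(eigen(out, only.values = TRUE)$values))
  if (abscissa > 0) { # numerical safety net: uniform diagonal shift
    diag(out) <- diag(out) - (abscissa + epsilon)
  }
  dimnames(out) <- dimnames(A)
  out
}

#' One-step-ahead Ricker prediction
#'
#' Predicts each time point from the *observed* previous time point with
#' the noise-free Ricker update and the supplied interaction matrix and
#' carrying capacities; the first time point is copied.
#'
#' @param ts observed series (a [community_ts()] or matrix) on the scale
#'   used to fit `A_hat`.
#' @param A_hat interaction matrix (S x S).
#' @param K_hat carrying capacities (defaults to per-taxon mean abundance).
#' @return a matrix of predictions; non-finite predictions are set to `NA`.
#' @export
predict_one_step <- function(ts, A_hat, K_hat = NULL) {
  x <- unclass_ts(ts)
  A_hat <- as.matrix(A_hat)
  if (nrow(x) != nrow(A_hat)) stop("dimension mismatch between series and matrix")
  if (is.null(K_hat)) K_hat <- rowMeans(x)
  T <- ncol(x)
  pred <- x
  pred[, -1] <- x[, -T] * exp(A_hat %*% (x[, -T] - K_hat))
  bad <- !is.finite(pred)
  if (any(bad)) pred[bad] <- NA_real_
  pred
}

#' Accuracy of an inferred interaction matrix
#'
#' Mean Pearson correlation between corresponding rows of the known and
#' inferred interaction matrices; rows with zero variance in either matrix
#' are skipped.
#'
#' @param A_true,A_hat matrices of identical shape and taxon order.
#' @return mean row correlation in `[-1, 1]`, or `NA` if no row is usable.
#' @export
inference_accuracy <- function(A_true, A_hat) {
  A_true <- as.matrix(A_true)
  A_hat <- as.matrix(A_hat)
  if (!all(dim(A_true) == dim(A_hat))) stop("matrices must have the same shape")
  cors <- vapply(seq_len(nrow(A_true)), function(i) {
    a <- A_true[i, ]; b <- A_hat[i, ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  if (all(is.na(cors))) return(NA_real_)
  mean(cors, na.rm = TRUE)
}

#' Goodness of fit of predicted to observed series
#'
#' Mean per-taxon Pearson correlation across time between observed and
#' predicted series; taxa with undefined variance (or all-`NA` predictions)
#' are skipped.
#'
#' @param observed,predicted matrices of identical shape.
#' @return mean correlation in `[-1, 1]`, or `NA` if no taxon is usable.
#' @export
goodness_of_fit <- function(observed, predicted) {
  obs <- unclass_ts(observed)
  pred <- as.matrix(predicted)
  if (!all(dim(obs) == dim(pred))) stop("shapes must agree")
  cors <- vapply(seq_len(nrow(obs)), function(i) {
    ok <- is.finite(obs[i, ]) & is.finite(pred[i, ])
    if (sum(ok) < 3) return(NA_real_)
    a <- obs[i, ok]; b <- pred[i, ok]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  if (all(is.na(cors))) return(NA_real_)
  mean(cors, na.rm = TRUE)
}
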