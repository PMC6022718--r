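#' Detrended periodogram
#'
#' Removes the least-squares linear trend from the series, applies a
#' split-cosine-bell taper to `taper` of the data at each end (the
#' `spectrum()` convention; tapering suppresses the spectral leakage that
#' otherwise caps measurable slopes near -2 for very steep spectra), and
#' returns the one-sided periodogram at the Fourier frequencies `k/T`,
#' `k = 1..floor(T/2)` (zero frequency excluded). The taper is
#' power-normalized; with `taper = 0` the ordinates sum exactly to the
#' (population) variance of the detrended series (Parseval).
#'
#' @param series numeric vector, length >= 8, finite.
#' @param taper proportion of data tapered at each end (default 0.1).
#' @return a list with `frequency`, `density`, and `degenerate` (`TRUE` when
#'   the detrended series has essentially zero variance, e.g. a constant or
#'   a pure linear ramp).
#' @export
detrended_periodogram <- function(series, taper = 0.1) {
  series <- as.numeric(series)
  T <- length(series)
  if (T < 8) stop("series must have at least 8 time points")
  if (any(!is.finite(series))) stop("series must be finite")
  fit <- lm.fit(cbind(1, seq_len(T)), series)
  resid <- fit$residuals
  scale2 <- mean(series^2) + 1
  degenerate <- mean(resid^2) <= 1e-20 * scale2
  if (taper > 0) {
    w <- stats::spec.taper(rep(1, T), p = taper)
    resid <- resid * w / sqrt(mean(w^2))
  }
  kmax <- floor(T / 2)
  X <- fft(resid)
  power <- Mod(X[2:(kmax + 1)])^2 / T^2
  dens <- 2 * power
  if (T %% 2 == 0) dens[kmax] <- power[kmax] # Nyquist ordinate is unpaired
  list(frequency = (1:kmax) / T, density = dens, degenerate = degenerate)
}

#' Spectral slope from a smoothed log-log periodogram
#'
#' Fits a smoothing spline to (log10 frequency, log10 density) with
#' equivalent degrees of freedom `max(2, log10(T))` and returns the minimum
#' of the spline's first derivative over the fitted frequency range. Zero
#' densities are floored at the smallest positive ordinate times 1e-3
#' before the log transform.
#'
#' @param frequencies positive Fourier frequencies.
#' @param densities spectral densities (>= 0).
#' @param T length of the original time series (sets the spline df).
#' @return the slope (a real number), or `NA` if no positive densities.
#' @export
spectral_slope <- function(frequencies, densities, T) {
  keep <- is.finite(frequencies) & is.finite(densities) & frequencies > 0
  f <- frequencies[keep]
  d <- densities[keep]
  if (length(f) < 4) return(NA_real_)
  pos <- d > 0
  if (!any(pos)) return(NA_real_)
  d <- pmax(d, min(d[pos]) * 1e-3)
  lf <- log10(f)
  ld <- log10(d)
  df <- max(2, log10(T))
  fit <- smooth.spline(lf, ld, df = df)
  grid <- seq(min(lf), max(lf), length.out = 200)
  min(predict(fit, grid, deriv = 1)$y)
}

#' Classify a spectral slope into a noise color
#'
#' Black for slopes at or below -2.25, brown in (-2.25, -1.75], pink in
#' (-1.75, -0.5], white otherwise; `NA` slopes map to `"undefined"`. With
#' `strict = TRUE`, stricter bands of width 0.2 around -1 (pink) and -2
#' (brown) are used and slopes falling in the gaps are `"unclassified"`.
#'
#' @param slope numeric vector of slopes (may contain `NA`).
#' @param strict use the stringent band definition.
#' @return a character vector of classes.
#' @export
classify_noise_type <- function(slope, strict = FALSE) {
  out <- character(length(slope))
  for (i in seq_along(slope)) {
    s <- slope[i]
    if (is.na(s)) {
      out[i] <- "undefined"
    } else if (!strict) {
      out[i] <- if (s <= -2.25) "black"
        else if (s <= -1.75) "brown"
        else if (s <= -0.5) "pink"
        else "white"
    } else {
      out[i] <- if (s <= -2.25) "black"
        else if (s >= -2.2 && s <= -1.8) "brown"
        else if (s >= -1.2 && s <= -0.8) "pink"
        else if (s > -0.5) "white"
        else "unclassified"
    }
  }
  out
}

noise_classes <- function(strict = FALSE) {
  c("white", "pink", "brown", "black",
    if (strict) "unclassified", "undefined")
}

#' Community noise-type profile
#'
#' Computes, per taxon, the slope of the detrended log-log periodogram and
#' the implied noise color, and aggregates class percentages over the
#' community. Taxa whose series are degenerate (no variance after
#' detrending) or more than `zero_fraction_max` zeros are classified
#' `"undefined"`.
#'
#' @param ts a [community_ts()] (>= 8 time points).
#' @param relative convert to relative abundances first (the default,
#'   matching sequencing-data practice).
#' @param strict use stringent class boundaries, see [classify_noise_type()].
#' @param zero_fraction_max taxa with a larger fraction of zeros are not
#'   classified.
#' @return an object of class `noise_profile`: a list with `taxa` (a
#'   data.frame of taxon, slope, class) and `class_percentages` (summing to
#'   100, `"undefined"` included).
#' @export
community_noise_profile <- function(ts, relative = TRUE, strict = FALSE,
                                    zero_fraction_max = 0.9) {
  x <- unclass_ts(ts)
  if (ncol(x) < 8) stop("need at least 8 time points")
  if (relative && !ts_is_relative(ts)) x <- unclass_ts(relative_abundances(ts))
  T <- ncol(x)
  slopes <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    if (mean(xi == 0) > zero_fraction_max) next
    pg <- detrended_periodogram(xi)
    if (pg$degenerate) next
    slopes[i] <- spectral_slope(pg$frequency, pg$density, T)
  }
  cls <- classify_noise_type(slopes, strict = strict)
  lev <- noise_classes(strict)
  pct <- 100 * as.numeric(table(factor(cls, levels = lev))) / nrow(x)
  names(pct) <- lev
  structure(list(
    taxa = data.frame(taxon = rownames(x), slope = slopes, class = cls,
                      stringsAsFactors = FALSE),
    class_percentages = pct,
    strict = strict, n_timepoints = T),
    class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf("<noise_profile> %d taxa, %d time points\n",
              nrow(x$taxa), x$n_timepoints))
  print(round(x$class_percentages, 1))
  invisible(x)
}

#' Dominant noise class of a profile
#'
#' The class with the highest percentage (ties broken toward darker noise).
#' @param profile a [community_noise_profile()] result.
#' @param ignore_undefined drop the `"undefined"` class before comparing.
#' @return a class name.
#' @export
dominant_noise_class <- function(profile, ignore_undefined = TRUE) {
  pct <- profile$class_percentages
  if (ignore_undefined) pct <- pct[setdiff(names(pct), "undefined")]
  names(which.max(rev(pct))) # rev(): darker classes win ties
}

#' Maximal autocorrelation beyond lag zero
#'
#' Maximum sample autocorrelation over lags `1..floor(10 * log10(T))` (the
#' conventional default lag window). Near-constant series (zero variance or
#' more than 90% zeros) return `NA`.
#'
#' @param series numeric vector, length >= 8.
#' @return a number or `NA`.
#' @export
max_autocorrelation <- function(series) {
  series <- as.numeric(series)
  T <- length(series)
  if (T < 8) stop("series must have at least 8 time points")
  if (sd(series) == 0 || mean(series == 0) > 0.9) return(NA_real_)
  lag_max <- floor(10 * log10(T))
  a <- acf(series, lag.max = lag_max, plot = FALSE)$acf[-1]
  max(a)
}

#' Hurst exponent (lag-1 autocovariance estimator)
#'
#' Kettani-Gubner estimator for fractional Gaussian noise:
#' `H = (1 + log2(1 + rho1)) / 2` with `rho1` the lag-1 sample
#' autocorrelation. Returns values clipped to (0, 1.5); constant series
#' return `NA`.
#'
#' @param series numeric vector, length >= 32.
#' @return the Hurst exponent estimate or `NA`.
#' @export
hurst_exponent <- function(series) {
  series <- as.numeric(series)
  T <- length(series)
  if (T < 32) stop("series must have at least 32 time points")
  if (sd(series) == 0) return(NA_real_)
  x <- series - mean(series)
  rho1 <- sum(x[-1] * x[-T]) / sum(x^2)
  H <- 0.5 * (1 + log2(1 + rho1))
  min(max(H, 1e-6), 1.5 - 1e-6)
}

#' Bin Hurst exponents into the conventional persistence bins
#'
#' Bins: `< 0.6`, `[0.6, 0.8)`, `[0.8, 0.9)`, `>= 0.9`; `NA` maps to
#' `"undefined"`.
#' @param H numeric vector of Hurst exponents.
#' @return a character vector of bin labels.
#' @export
hurst_bins <- function(H) {
  ifelse(is.na(H), "undefined",
         ifelse(H < 0.6, "<0.6",
                ifelse(H < 0.8, "[0.6,0.8)",
                       ifelse(H < 0.9, "[0.8,0.9)", ">=0.9"))))
}
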