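test_that("the periodogram localizes a pure sinusoid and satisfies Parseval", {
  T <- 1000
  x <- sin(2 * pi * 0.1 * seq_len(T))
  pg <- detrended_periodogram(x)
  expect_equal(pg$frequency[which.max(pg$density)], 0.1, tolerance = 1e-3)

  # Parseval holds exactly for the untapered periodogram
  set.seed(1)
  y <- cumsum(rnorm(512))
  pg0 <- detrended_periodogram(y, taper = 0)
  resid <- lm.fit(cbind(1, seq_len(512)), y)$residuals
  expect_equal(sum(pg0$density), mean(resid^2), tolerance = 0.01)

  # a pure linear ramp has no residual variance
  expect_true(detrended_periodogram(3 + 0.5 * seq_len(100))$degenerate)
  expect_error(detrended_periodogram(1:5), "at least 8")
})

test_that("spectral slope recovers the noise color of synthesized series", {
  T <- 3000
  white <- vapply(1:100, function(s) {
    set.seed(s)
    pg <- detrended_periodogram(rnorm(T))
    spectral_slope(pg$frequency, pg$density, T)
  }, numeric(1))
  expect_gt(mean(white), -0.3)
  expect_lt(mean(white), 0.3)

  brown <- vapply(1:100, function(s) {
    set.seed(s + 200)
    pg <- detrended_periodogram(cumsum(rnorm(T)))
    spectral_slope(pg$frequency, pg$density, T)
  }, numeric(1))
  expect_gte(sum(brown > -2.5 & brown < -1.6), 90)

  pink <- vapply(1:60, function(s) {
    pg <- detrended_periodogram(synth_power_law(T, 1, seed = s + 400))
    spectral_slope(pg$frequency, pg$density, T)
  }, numeric(1))
  expect_gte(mean(classify_noise_type(pink) == "pink"), 0.9)
})

test_that("slope accuracy is non-increasing in series length for 1/f^gamma inputs", {
  err <- function(gamma, T) {
    mean(vapply(1:25, function(s) {
      pg <- detrended_periodogram(synth_power_law(T, gamma,
                                                  seed = s + 37 * gamma))
      abs(spectral_slope(pg$frequency, pg$density, T) + gamma)
    }, numeric(1)))
  }
  for (gamma in 0:3) {
    e <- vapply(c(100, 1000, 3000), function(T) err(gamma, T), numeric(1))
    expect_true(all(diff(e) <= 0.05)) # non-increasing up to Monte-Carlo slack
  }
})

test_that("noise classes partition the real line at the printed boundaries", {
  expect_equal(classify_noise_type(c(-2.5, -1.0, 0.0)),
               c("black", "pink", "white"))
  expect_equal(classify_noise_type(c(-2.25, -1.75, -0.5)),
               c("black", "brown", "pink")) # boundary membership
  grid <- seq(-4, 1, by = 0.01)
  cls <- classify_noise_type(grid)
  expect_true(all(cls %in% c("white", "pink", "brown", "black")))
  expect_equal(classify_noise_type(NA_real_), "undefined")
  # strict boundaries open unclassified gaps but keep the partition disjoint
  strict <- classify_noise_type(grid, strict = TRUE)
  expect_true("unclassified" %in% strict)
  expect_equal(classify_noise_type(-1, strict = TRUE), "pink")
  expect_equal(classify_noise_type(-2, strict = TRUE), "brown")
})

test_that("community profiles sum to 100% and flag unusable taxa", {
  set.seed(5)
  x <- matrix(abs(rnorm(5 * 300)), 5, 300)
  x[4, ] <- 0                              # all-zero taxon
  x[5, ] <- c(rep(0, 280), abs(rnorm(20))) # > 90% zeros
  ts <- community_ts(x)
  prof <- community_noise_profile(ts, relative = FALSE)
  expect_equal(sum(prof$class_percentages), 100, tolerance = 1e-6)
  expect_equal(prof$taxa$class[4], "undefined")
  expect_equal(prof$taxa$class[5], "undefined")
})

test_that("the dominant class is robust to the absolute/relative choice", {
  run <- stable_ricker_run(40, 0.05, 16, sigma = 0.05, n_timepoints = 2000,
                           seed = 31)
  rel <- community_noise_profile(run$ts, relative = TRUE)
  abs_ <- community_noise_profile(run$ts, relative = FALSE)
  expect_equal(dominant_noise_class(rel), dominant_noise_class(abs_))
})

test_that("maximal autocorrelation detects periodicity and ignores iid noise", {
  per <- rep(c(5, 1, 2, 8, 3, 9, 4), length.out = 700)
  expect_gte(max_autocorrelation(per), 0.95)
  expect_true(is.na(max_autocorrelation(rep(2, 100))))
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    max_autocorrelation(rnorm(3000)) < 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the Hurst estimator matches fractional-Gaussian-noise oracles", {
  expect_error(hurst_exponent(rnorm(10)), "at least 32")
  expect_true(is.na(hurst_exponent(rep(1, 100))))
  set.seed(2)
  x <- rnorm(2000)
  expect_identical(hurst_exponent(x), hurst_exponent(x)) # deterministic
  h_iid <- mean(vapply(1:40, function(s) {
    set.seed(s); hurst_exponent(rnorm(2000))
  }, numeric(1)))
  expect_equal(h_iid, 0.5, tolerance = 0.1 / 0.5)
  h_rw <- vapply(1:40, function(s) {
    set.seed(s + 100); hurst_exponent(cumsum(rnorm(2000)))
  }, numeric(1))
  expect_gte(mean(h_rw > 0.9), 0.9)
  # Davies-Harte fGn synthesis at persistent H
  for (H in c(0.6, 0.8)) {
    est <- mean(vapply(1:30, function(s) {
      hurst_exponent(synth_fgn(4096, H, seed = s + 61 * H))
    }, numeric(1)))
    expect_equal(est, H, tolerance = 0.05 / H)
  }
  expect_equal(hurst_bins(c(0.5, 0.7, 0.85, 0.95, NA)),
               c("<0.6", "[0.6,0.8)", "[0.8,0.9)", ">=0.9", "undefined"))
})
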