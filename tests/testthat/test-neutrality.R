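test_that("the constant-volatility transform is monotone and kills constants", {
  x <- rep(0.5, 50)
  for (m in c("arcsine", "logitnorm")) {
    f <- volatility_stabilizing_transform(x, method = m)
    expect_equal(diff(f), rep(0, 49))
  }
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(volatility_stabilizing_transform(grid, "arcsine")) > 0))
  expect_true(all(diff(volatility_stabilizing_transform(grid, "logitnorm")) > 0))
  expect_error(volatility_stabilizing_transform(c(-0.1, 0.5)), "\\[0, 1\\]")
  # boundary values are shrunk, not propagated to +-Inf
  expect_true(all(is.finite(volatility_stabilizing_transform(c(0, 1)))))
})

test_that("the transform stabilizes Wright-Fisher volatility (two-allele oracle)", {
  # N and T chosen so fixation (which would degenerate the path) is rare
  raw_cor <- trans_cor <- numeric(20)
  for (s in 1:20) {
    p <- wf_two_allele(1000, N = 2000, seed = s)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    v <- (p * (1 - p))[-1000]
    raw_cor[s] <- cor(diff(p)^2, v)
    e <- diff(asin(2 * p - 1))
    trans_cor[s] <- cor(e^2, v)
  }
  expect_gt(mean(raw_cor), 0.1)          # volatility tracks p(1-p) before
  expect_lt(abs(mean(trans_cor)), 0.05)  # and is state-free after
})

test_that("a partition and its complement give identical scores", {
  set.seed(3)
  x <- matrix(rgamma(8 * 200, 2), 8, 200)
  ts <- relative_abundances(community_ts(x))
  for (m in c("arcsine", "logitnorm")) {
    s1 <- grouping_statistic(ts, 1:3, method = m)
    s2 <- grouping_statistic(ts, 4:8, method = m)
    expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-10)
  }
  expect_error(grouping_statistic(ts, 1:8), "non-empty")
})

test_that("degenerate aggregates are reported as NA with NA volatility", {
  x <- rbind(rep(0.25, 50), rep(0.25, 50), rep(0.3, 50), rep(0.2, 50))
  ts <- community_ts(x, is_relative = TRUE)
  s <- grouping_statistic(ts, c(1, 2))
  expect_true(is.na(as.numeric(s)))
  expect_true(is.na(attr(s, "volatility")))
})

test_that("neutral series score near the null center, interacting ones do not", {
  # Hubbell drift: statistic within the calibrated null band
  ts_h <- simulate_hubbell(n_species = 40, n_timepoints = 400,
                           n_individuals = 1000, death_rate = 20,
                           burn_in = 500, seed = 21)
  r_h <- neutral_covariance_test(ts_h, n_transformations = 200,
                                 null_replicates = 99, seed = 22)
  expect_gt(r_h$p_value, 0.05)
  expect_true(r_h$p_value >= 0 && r_h$p_value <= 1)

  # noise-free Ricker: rejected on the transient window (with a long
  # steady-state tail the volatility signal is diluted, a known limitation);
  # power grows with community size, so test at the 100-species study scale
  run <- stable_ricker_run(100, 0.05, 16, sigma = 0, n_timepoints = 120,
                           seed = 23)
  r_r <- neutral_covariance_test(first_n(run$ts, 100),
                                 n_transformations = 200,
                                 null_replicates = 99, seed = 24)
  expect_lt(r_r$p_value, 0.05)
})

test_that("the test is invariant to taxon relabeling", {
  ts <- simulate_hubbell(n_species = 30, n_timepoints = 300,
                         n_individuals = 900, death_rate = 30,
                         burn_in = 300, seed = 31)
  x <- unclass(ts)
  perm <- sample(nrow(x))
  x2 <- x[perm, ]
  rownames(x2) <- paste0("renamed", seq_len(nrow(x2)))
  r1 <- neutral_covariance_test(community_ts(x), n_transformations = 100,
                                null_replicates = 49, seed = 7)
  r2 <- neutral_covariance_test(community_ts(x2), n_transformations = 100,
                                null_replicates = 49, seed = 7)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("input contracts are enforced", {
  ts <- simulate_hubbell(n_species = 2, n_timepoints = 50,
                         n_individuals = 100, death_rate = 5,
                         burn_in = 10, seed = 1)
  expect_error(neutral_covariance_test(ts), "3 taxa")
  ts2 <- sample_dirichlet_multinomial(rep(0.2, 5), 0.1, 100, 5, seed = 2)
  expect_error(neutral_covariance_test(ts2), "10 time points")
})

test_that("Poisson measurement noise pushes neutral series toward rejection", {
  # known confounder: false positives under added Poisson noise
  p_clean <- p_noisy <- numeric(6)
  for (s in 1:6) {
    ts <- simulate_hubbell(n_species = 40, n_timepoints = 150,
                           n_individuals = 1000, death_rate = 20,
                           burn_in = 400, seed = 40 + s)
    noisy <- add_poisson_noise(ts, scale = 2, seed = 50 + s)
    p_clean[s] <- neutral_covariance_test(ts, n_transformations = 200,
                                          null_replicates = 99,
                                          seed = 60 + s)$p_value
    p_noisy[s] <- neutral_covariance_test(noisy, n_transformations = 200,
                                          null_replicates = 99,
                                          seed = 60 + s)$p_value
  }
  expect_gte(sum(p_noisy < 0.05), sum(p_clean < 0.05))
})
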