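test_that("broken stick proportions sum to 1 and match the closed-form ranks", {
  expect_equal(broken_stick_proportions(1), 1)
  expect_error(broken_stick_proportions(0), "at least 1")
  for (s in 1:10) {
    p <- broken_stick_proportions(37, seed = s)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  # E[sorted share i] = (1/n) * sum_{j>=i} 1/j: for n = 3 -> 11/18, 5/18, 2/18
  set.seed(99)
  m <- rowMeans(replicate(4000, sort(broken_stick_proportions(3),
                                     decreasing = TRUE)))
  expect_equal(m, c(11, 5, 2) / 18, tolerance = 0.02)
})

test_that("broken stick expectation agrees with vegan's deterministic model", {
  skip_if_not_installed("vegan")
  set.seed(7)
  m <- rowMeans(replicate(4000, sort(broken_stick_proportions(8),
                                     decreasing = TRUE)))
  expect_equal(m, sort(vegan::bstick(8, 1), decreasing = TRUE),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("Hubbell drift is zero-sum and reproducible", {
  ts <- simulate_hubbell(n_species = 20, n_timepoints = 200,
                         n_individuals = 400, death_rate = 10,
                         burn_in = 50, seed = 1)
  expect_true(all(colSums(unclass(ts)) == 400))
  ts2 <- simulate_hubbell(n_species = 20, n_timepoints = 200,
                          n_individuals = 400, death_rate = 10,
                          burn_in = 50, seed = 1)
  expect_identical(unclass(ts), unclass(ts2))
  expect_error(simulate_hubbell(n_individuals = 10, death_rate = 11),
               "death_rate")
})

test_that("full immigration drives time-averaged proportions to the metacommunity", {
  meta <- broken_stick_proportions(25, seed = 5)
  ts <- simulate_hubbell(n_species = 25, n_timepoints = 3000,
                         n_individuals = 5000, death_rate = 100,
                         immigration = 1, metacommunity = meta,
                         burn_in = 200, seed = 6)
  props <- rowMeans(unclass(ts)) / 5000
  expect_lt(sum(abs(props - meta)), 0.05)
})

test_that("SOI conserves sites and an empty community with no immigration stays empty", {
  A <- generate_interaction_matrix(10, connectance = 0.2, pep = 16, seed = 2)
  empty <- simulate_soi(A, n_timepoints = 60, n_sites = 120,
                        immigration_rates = rep(0, 10),
                        extinction_rates = rep(0.4, 10),
                        x0 = rep(0, 10), seed = 3)
  expect_true(all(unclass(empty) == 0))

  s <- simulate_soi(A, n_timepoints = 300, n_sites = 120, seed = 4)
  expect_true(all(colSums(unclass(s)) <= 120))
  s2 <- simulate_soi(A, n_timepoints = 300, n_sites = 120, seed = 4)
  expect_identical(unclass(s), unclass(s2))
  expect_error(simulate_soi(A, immigration_rates = rep(0.1, 3)), "match")
})

test_that("noise-free Ricker started at K stays at K to machine precision", {
  set.seed(8)
  K <- runif(30, 0.1, 0.5)
  A <- generate_interaction_matrix(30, connectance = 0.05, pep = 0, seed = 9)
  ts <- simulate_ricker(A, K = K, x0 = K, sigma = 0, n_timepoints = 3000)
  expect_equal(unclass(ts), matrix(K, 30, 3000), tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("Ricker explosions carry the step index", {
  A2 <- matrix(c(-1, 5, 5, -1), 2, 2)
  err <- tryCatch(
    simulate_ricker(A2, K = c(0.4, 0.4), x0 = c(0.6, 0.6), sigma = 0,
                    n_timepoints = 500),
    ecosig_explosion_error = function(e) e)
  expect_s3_class(err, "ecosig_explosion_error")
  expect_true(is.finite(err$step) && err$step > 1)
})

test_that("gLV converges to the interior fixed point -A^-1 b", {
  ts <- simulate_glv(-diag(4), b = rep(0.25, 4), x0 = rep(0.05, 4),
                     n_timepoints = 300)
  expect_equal(unclass(ts)[, 300], rep(0.25, 4), tolerance = 1e-4,
               ignore_attr = TRUE)
  # zero growth: monotone decay toward 0
  dec <- unclass(simulate_glv(-diag(3), b = rep(0, 3), x0 = rep(0.3, 3),
                              n_timepoints = 100))
  expect_true(all(diff(t(dec)) <= 1e-12))
})

test_that("Dirichlet-multinomial columns are exchangeable draws at fixed depth", {
  p <- c(0.5, 0.3, 0.15, 0.05)
  d <- sample_dirichlet_multinomial(p, theta = 0.2, depth = 500,
                                    n_timepoints = 10000, seed = 11)
  x <- unclass(d)
  expect_true(all(colSums(x) == 500))
  props <- x / 500
  se <- sqrt(apply(props, 1, var) / 10000)
  expect_true(all(abs(rowMeans(props) - p) < 3 * se + 1e-4))
  expect_error(sample_dirichlet_multinomial(p, theta = 1.5), "theta")
})

test_that("Dirichlet-multinomial proportions are overdispersed relative to multinomial", {
  p <- c(0.4, 0.3, 0.2, 0.1)
  dm <- unclass(sample_dirichlet_multinomial(p, theta = 0.2, depth = 400,
                                             n_timepoints = 10000, seed = 12)) / 400
  set.seed(13)
  mn <- rmultinom(10000, 400, p) / 400
  expect_true(all(apply(dm, 1, var) > apply(mn, 1, var)))
})

test_that("community time series round-trip through tab-separated text", {
  ts <- sample_dirichlet_multinomial(c(0.6, 0.4), theta = 0.1, depth = 100,
                                     n_timepoints = 12, seed = 14)
  path <- tempfile(fileext = ".tsv")
  write_community_ts(ts, path)
  back <- read_community_ts(path)
  expect_equal(unclass_mat <- unclass(back)[, ], unclass(ts)[, ],
               ignore_attr = TRUE)
})

test_that("the simulate_community dispatcher honors interval thinning", {
  ts <- simulate_community(list(model = "dm", n_species = 10,
                                n_timepoints = 200, theta = 0.1,
                                interval = 10, seed = 15))
  expect_equal(ncol(ts), 20)
  expect_equal(attr(ts, "time_step"), 10)
})
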