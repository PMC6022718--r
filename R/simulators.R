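#' Broken-stick initial proportions
#'
#' Random partition of the unit interval: `n - 1` uniform break points are
#' sorted and segment lengths returned. The expected sorted share of the
#' rank-i segment equals `(1/n) * sum(1/j, j = i..n)`, the classic
#' broken-stick expectation.
#'
#' @param n_species number of species (>= 1).
#' @param seed optional RNG seed.
#' @return a proportion vector summing to 1.
#' @export
broken_stick_proportions <- function(n_species, seed = NULL) {
  if (n_species < 1) stop("n_species must be at least 1")
  .ecosig_seed(seed)
  if (n_species == 1) return(1)
  diff(c(0, sort(runif(n_species - 1)), 1))
}

# Shared deterministic/stochastic Ricker iteration.
# x(t+1) = eta * x(t) * exp(A %*% (x(t) - K)), log eta ~ N(0, sigma^2).
ricker_core <- function(A, K, x0, sigma, n_timepoints,
                        extinction_floor = 1e-10, explosion_bound = 1e8) {
  S <- nrow(A)
  out <- matrix(0, S, n_timepoints)
  x <- as.numeric(x0)
  out[, 1] <- x
  for (t in seq_len(n_timepoints - 1)) {
    growth <- exp(as.numeric(A %*% (x - K)))
    if (sigma > 0) growth <- growth * exp(rnorm(S, 0, sigma))
    x <- x * growth
    x[x < extinction_floor] <- 0
    # an infinite bound makes the explosion check vacuous
    if (is.finite(explosion_bound) &&
        (any(!is.finite(x)) || any(x > explosion_bound))) {
      return(list(abundances = out, exploded = TRUE, step = t + 1))
    }
    out[, t + 1] <- x
  }
  list(abundances = out, exploded = FALSE, step = NA_integer_)
}

ecosig_explosion_error <- function(step, model) {
  stop(structure(class = c("ecosig_explosion_error", "error", "condition"),
                 list(message = sprintf("%s simulation diverged at step %d",
                                        model, step),
                      call = sys.call(-1), step = step)))
}

#' Simulate the Ricker model
#'
#' Discrete-time analogue of the generalized Lotka-Volterra model with
#' per-species carrying capacities and multiplicative log-normal intrinsic
#' noise: `x[i](t+1) = eta[i](t) * x[i](t) * exp(sum_j A[i,j] (x[j](t) - K[j]))`
#' with `log eta ~ Normal(0, sigma^2)`. `K` is the interior fixed point of
#' the noise-free map. Abundances below `extinction_floor` are set to 0.
#'
#' @param A interaction matrix (S x S).
#' @param K carrying capacities; drawn from Uniform(0, 0.5) when `NULL`.
#' @param x0 initial abundances; broken-stick proportions when `NULL`.
#' @param sigma intrinsic noise strength (>= 0); 0 gives the deterministic map.
#' @param n_timepoints number of time points returned (including `x0`).
#' @param seed optional RNG seed.
#' @param extinction_floor abundances below this are set to 0.
#' @param explosion_bound abundance bound; exceeding it raises an explosion
#'   error carrying the step index (`condition$step`).
#' @return a [community_ts()] with `model_tag = "ricker"`.
#' @export
simulate_ricker <- function(A, K = NULL, x0 = NULL, sigma = 0.05,
                            n_timepoints = 3000, seed = NULL,
                            extinction_floor = 1e-10, explosion_bound = 1e8) {
  if (sigma < 0) stop("sigma must be non-negative")
  .ecosig_seed(seed)
  A <- as.matrix(A)
  S <- nrow(A)
  if (is.null(K)) K <- runif(S, 0, 0.5)
  if (is.null(x0)) x0 <- broken_stick_proportions(S)
  if (any(K < 0) || any(x0 < 0)) stop("K and x0 must be non-negative")
  res <- ricker_core(A, K, x0, sigma, n_timepoints,
                     extinction_floor, explosion_bound)
  if (res$exploded) ecosig_explosion_error(res$step, "Ricker")
  community_ts(res$abundances, model_tag = "ricker",
               taxon_ids = rownames(A))
}

#' Simulate the generalized Lotka-Volterra model
#'
#' Integrates `dx[i]/dt = x[i] * (b[i] + sum_j A[i,j] x[j])` with an
#' adaptive solver (deSolve::ode, lsoda, relative tolerance `rtol`) and
#' samples the solution at unit time intervals.
#'
#' @param A interaction matrix (S x S).
#' @param b growth rates; drawn from Uniform(0, 0.5) when `NULL`.
#' @param x0 initial abundances; broken-stick proportions when `NULL`.
#' @param n_timepoints number of sampled time points (t = 0, 1, ...).
#' @param seed optional RNG seed (used only for default `b`/`x0` draws).
#' @param rtol relative integration tolerance.
#' @param extinction_floor abundances below this are set to 0 in the output.
#' @param explosion_bound bound above which the run is declared divergent.
#' @return a [community_ts()] with `model_tag = "glv"`.
#' @export
simulate_glv <- function(A, b = NULL, x0 = NULL, n_timepoints = 3000,
                         seed = NULL, rtol = 1e-6,
                         extinction_floor = 1e-10, explosion_bound = 1e8) {
  .ecosig_seed(seed)
  A <- as.matrix(A)
  S <- nrow(A)
  if (is.null(b)) b <- runif(S, 0, 0.5)
  if (is.null(x0)) x0 <- broken_stick_proportions(S)
  if (any(x0 < 0)) stop("x0 must be non-negative")
  deriv <- function(t, x, parms) {
    x <- pmax(x, 0)
    list(x * (b + as.numeric(A %*% x)))
  }
  sol <- deSolve::ode(y = as.numeric(x0), times = seq(0, n_timepoints - 1),
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = 1e-12)
  x <- t(sol[, -1, drop = FALSE])
  if (nrow(sol) < n_timepoints || any(!is.finite(x)) || any(x > explosion_bound)) {
    ecosig_explosion_error(nrow(sol), "gLV")
  }
  x[x < extinction_floor] <- 0
  community_ts(x, model_tag = "glv", taxon_ids = rownames(A))
}

#' Simulate Hubbell's neutral model
#'
#' Zero-sum drift in a local community of `n_individuals` individuals: each
#' step, `death_rate` individuals die uniformly at random (a multivariate
#' hypergeometric draw); each vacancy is filled by an immigrant drawn from
#' the fixed metacommunity with probability `immigration`, otherwise by the
#' offspring of an individual drawn from the current local community.
#' Vacancies are filled sequentially, so earlier replacements within a step
#' can parent later ones. The first `burn_in` steps are discarded.
#'
#' @param n_species number of species.
#' @param n_timepoints number of recorded time points.
#' @param n_individuals local community size (constant over time).
#' @param death_rate individuals replaced per step (<= `n_individuals`).
#' @param immigration immigration probability `m` in `[0, 1]`.
#' @param metacommunity metacommunity proportions (even when `NULL`);
#'   constant over time (no speciation).
#' @param x0 initial proportions (defaults to the metacommunity).
#' @param burn_in steps discarded before recording; when `NULL`, 5000 for
#'   `immigration <= 0.1` (slow convergence at low immigration), else 1000.
#' @param seed optional RNG seed.
#' @return a [community_ts()] of individual counts, `model_tag = "hubbell"`.
#' @export
simulate_hubbell <- function(n_species = 100, n_timepoints = 3000,
                             n_individuals = 1500, death_rate = 10,
                             immigration = 0.1, metacommunity = NULL,
                             x0 = NULL, burn_in = NULL, seed = NULL) {
  if (death_rate > n_individuals) stop("death_rate must not exceed n_individuals")
  if (immigration < 0 || immigration > 1) stop("immigration must be in [0, 1]")
  .ecosig_seed(seed)
  if (is.null(metacommunity)) metacommunity <- rep(1 / n_species, n_species)
  if (abs(sum(metacommunity) - 1) > 1e-8) stop("metacommunity must sum to 1")
  if (length(metacommunity) != n_species) stop("metacommunity length mismatch")
  if (is.null(x0)) x0 <- metacommunity
  if (is.null(burn_in)) burn_in <- if (immigration <= 0.1) 5000 else 1000
  init <- as.integer(rmultinom(1, n_individuals, x0))
  counts <- .hubbell_sim_cpp(init, metacommunity, as.integer(death_rate),
                             immigration, as.integer(n_timepoints),
                             as.integer(burn_in))
  community_ts(counts, model_tag = "hubbell")
}

#' Simulate the self-organized instability (SOI) model
#'
#' Individual-based community assembly on `n_sites` sites. Per generation:
#' (1) immigration, species `i` colonizes each empty site with probability
#' `immigration_rates[i]` (species order randomized); (2) extinction, each
#' individual dies with probability `extinction_rates[i]`; (3) interaction,
#' as many ordered pairs of occupied sites as there are individuals are
#' sampled, and the first individual (species `i`) replaces the second
#' (species `j`) when `A[j, i] < 0` and `|A[j, i]|` exceeds a Uniform(0, 1)
#' draw.
#'
#' @param A interaction matrix (S x S), `A[j, i]` = effect of `i` on `j`.
#' @param n_timepoints number of recorded generations.
#' @param n_sites number of sites (bounds the total number of individuals).
#' @param immigration_rates per-species colonization probabilities in
#'   `[0, 1]`; defaults to the initial species proportions.
#' @param extinction_rates per-species death probabilities in `[0, 1]`;
#'   drawn from Uniform(0, 1) when `NULL`.
#' @param x0 initial proportions (broken-stick when `NULL`); sites are
#'   initially filled by a multinomial draw from `x0`.
#' @param seed optional RNG seed.
#' @return a [community_ts()] of individual counts, `model_tag = "soi"`.
#' @export
simulate_soi <- function(A, n_timepoints = 3000, n_sites = 1500,
                         immigration_rates = NULL, extinction_rates = NULL,
                         x0 = NULL, seed = NULL) {
  .ecosig_seed(seed)
  A <- as.matrix(A)
  S <- nrow(A)
  if (is.null(x0)) x0 <- broken_stick_proportions(S)
  if (is.null(immigration_rates)) immigration_rates <- x0
  if (is.null(extinction_rates)) extinction_rates <- runif(S)
  if (length(immigration_rates) != S || length(extinction_rates) != S) {
    stop("rate vectors must match the interaction matrix dimension")
  }
  if (any(immigration_rates < 0 | immigration_rates > 1) ||
      any(extinction_rates < 0 | extinction_rates > 1)) {
    stop("rates must lie in [0, 1]")
  }
  if (sum(x0) > 0) {
    init <- as.integer(rmultinom(1, n_sites, x0))
  } else {
    init <- integer(S)
  }
  counts <- .soi_sim_cpp(init, as.integer(n_sites), immigration_rates,
                         extinction_rates, A, as.integer(n_timepoints))
  community_ts(counts, model_tag = "soi", taxon_ids = rownames(A))
}

#' Sample Dirichlet-multinomial community compositions
#'
#' Each time point is an independent draw: `q ~ Dirichlet(alpha)` with
#' `alpha[i] = p[i] * (1 - theta) / theta`, then
#' `counts ~ Multinomial(depth, q)`. Columns are independent, so the series
#' has no temporal structure by construction.
#'
#' @param proportions expected species proportions (sum to 1).
#' @param theta overdispersion parameter in (0, 1).
#' @param depth total counts per time point.
#' @param n_timepoints number of time points.
#' @param seed optional RNG seed.
#' @return a [community_ts()] of counts, `model_tag = "dm"`.
#' @export
sample_dirichlet_multinomial <- function(proportions, theta = 0.02,
                                         depth = 10000, n_timepoints = 3000,
                                         seed = NULL) {
  if (theta <= 0 || theta >= 1) stop("theta must lie strictly between 0 and 1")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  .ecosig_seed(seed)
  S <- length(proportions)
  alpha <- proportions * (1 - theta) / theta
  gam <- matrix(rgamma(S * n_timepoints, shape = alpha), nrow = S)
  q <- sweep(gam, 2, colSums(gam), "/")
  counts <- vapply(seq_len(n_timepoints),
                   function(t) rmultinom(1, depth, q[, t])[, 1],
                   numeric(S))
  community_ts(counts, model_tag = "dm")
}

#' Simulate a community time series from a configuration list
#'
#' Dispatcher used by the command-line interface. `config` mirrors the
#' fields of the individual simulators: `model` (one of `dm`, `hubbell`,
#' `soi`, `ricker`, `glv`), `n_species`, `n_timepoints`, `sigma`, `theta`,
#' `depth`, `immigration`, `death_rate`, `n_individuals`, `n_sites`,
#' `interval`, `seed`, plus an optional interaction `matrix` (for `soi`,
#' `ricker`, `glv`; generated with [generate_interaction_matrix()] when
#' absent, using `connectance` and `pep`).
#'
#' @param config a named list.
#' @return a [community_ts()]; when `interval > 1` the series is thinned
#'   with [thin_to_interval()].
#' @export
simulate_community <- function(config) {
  cfg <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  model <- match.arg(config$model, c("dm", "hubbell", "soi", "ricker", "glv"))
  seed <- cfg("seed", NULL)
  .ecosig_seed(seed)
  S <- cfg("n_species", 100)
  n_tp <- cfg("n_timepoints", 3000)
  A <- config$matrix
  if (is.null(A) && model %in% c("soi", "ricker", "glv")) {
    A <- generate_interaction_matrix(S, connectance = cfg("connectance", 0.05),
                                     pep = cfg("pep", 16),
                                     clique_size = cfg("clique_size", 10))
  }
  ts <- switch(model,
    dm = sample_dirichlet_multinomial(
      proportions = cfg("proportions", broken_stick_proportions(S)),
      theta = cfg("theta", 0.02), depth = cfg("depth", 10000),
      n_timepoints = n_tp),
    hubbell = simulate_hubbell(
      n_species = S, n_timepoints = n_tp,
      n_individuals = cfg("n_individuals", 1500),
      death_rate = cfg("death_rate", 10),
      immigration = cfg("immigration", 0.1),
      burn_in = cfg("burn_in", NULL)),
    soi = simulate_soi(A, n_timepoints = n_tp, n_sites = cfg("n_sites", 1500)),
    ricker = simulate_ricker(A, sigma = cfg("sigma", 0.05), n_timepoints = n_tp),
    glv = simulate_glv(A, n_timepoints = n_tp))
  interval <- cfg("interval", 1)
  if (interval > 1) ts <- thin_to_interval(ts, interval)
  ts
}
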