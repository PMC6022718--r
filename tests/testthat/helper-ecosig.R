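# Shared fixtures and independent oracles, all generated in code.

# Spectrally synthesized 1/f^gamma series (inverse-FFT with random phases):
# oracle for the spectral-slope estimator.
synth_power_law <- function(T, gamma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kmax <- floor(T / 2)
  f <- (1:kmax) / T
  amp <- f^(-gamma / 2)
  phase <- runif(kmax, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(T))
  full[2:(kmax + 1)] <- spec
  full[T:(T - kmax + 2)] <- Conj(spec[1:(kmax - 1)])
  if (T %% 2 == 0) full[kmax + 1] <- complex(real = amp[kmax]) # real Nyquist
  Re(fft(full, inverse = TRUE)) / T
}

# Davies-Harte exact synthesis of fractional Gaussian noise with Hurst
# exponent H: oracle for the Hurst estimator.
synth_fgn <- function(T, H, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gamma_k <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                                  abs(k - 1)^(2 * H))
  g <- gamma_k(0:(T - 1))
  circ <- c(g, 0, rev(g[-1]))
  lambda <- Re(fft(circ))
  lambda[lambda < 0] <- 0 # tiny negative eigenvalues from rounding
  n <- length(circ)
  z <- complex(real = rnorm(n), imaginary = rnorm(n))
  w <- sqrt(lambda / (2 * n)) * z
  w[1] <- sqrt(lambda[1] / n) * Re(z[1])
  w[n / 2 + 1] <- sqrt(lambda[n / 2 + 1] / n) * Re(z[n / 2 + 1])
  Re(fft(w))[1:T]
}

# Two-allele Wright-Fisher binomial share path: oracle for the
# constant-volatility transform.
wf_two_allele <- function(T, N, p0 = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- numeric(T)
  p[1] <- p0
  for (t in 2:T) p[t] <- rbinom(1, N, p[t - 1]) / N
  p
}

# Small stable interaction matrix + Ricker series, regenerating the matrix
# (shifted seed) when the noisy simulation diverges.
stable_ricker_run <- function(n_species, connectance, pep, sigma, n_timepoints,
                              seed, tries = 20) {
  for (k in 0:(tries - 1)) {
    s <- seed + 101 * k
    A <- generate_interaction_matrix(n_species, connectance = connectance,
                                     pep = pep, seed = s)
    ts <- tryCatch(
      simulate_ricker(A, K = attr(A, "K"), sigma = sigma,
                      n_timepoints = n_timepoints, seed = s + 1),
      ecosig_explosion_error = function(e) NULL)
    if (!is.null(ts)) return(list(ts = ts, A = A))
  }
  stop("no stable Ricker run found")
}

first_n <- function(ts, n) {
  community_ts(unclass(ts)[, seq_len(n), drop = FALSE],
               time_step = attr(ts, "time_step"),
               model_tag = attr(ts, "model_tag"))
}
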