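# ecosig

Signatures of ecological processes in microbial community time series.

Dense longitudinal sequencing data (daily gut samples, lake surveys, ...)
are increasingly used to infer species interaction networks or to
parameterize community models. Those analyses silently assume that the
observed fluctuations were *generated* by interactions — an assumption that
fails for communities governed by independent resampling (no temporal
structure at all) or by neutral drift (no species-specific rates), both of
which still produce plausible-looking "networks" when fed to inference
algorithms. `ecosig` is a screening toolkit for deciding, directly from a
taxa-by-time abundance table, which class of process is compatible with the
data, and for running interaction inference only when it is warranted.

The package implements a three-step classification scheme:

1. **Noise-type profiling.** Each taxon's (relative) abundance series is
   linearly detrended, tapered, and Fourier-transformed; the slope *s* of
   the smoothed log-log spectrum classifies the taxon as
   black (*s* ≤ −2.25), brown (−2.25 < *s* ≤ −1.75), pink
   (−1.75 < *s* ≤ −0.5) or white (otherwise). A community dominated by
   white taxa carries no temporal structure and the pipeline stops.
2. **Neutral covariance test.** For hundreds of random binary groupings of
   the taxa, the aggregated share g(t) is variance-stabilized (under
   neutral Wright-Fisher drift Var(dg) ∝ g(1−g), so arcsine/logit
   transforms equalize it); neutrality predicts one common volatility
   across *all* groupings. The test statistic is an F-ratio of
   between-grouping to within-grouping volatility variance, calibrated by
   parametric bootstrap against matched Wright-Fisher surrogates. Neutral
   series (p > 0.05) are not forwarded to interaction inference.
3. **LIMITS interaction inference.** Sparse Ricker-model regression
   y_i(t) = ln x_i(t+1) − ln x_i(t) = Σ_j α_ij (x_j(t) − K_j): forward
   stepwise predictor selection under a 5% held-out-error improvement
   rule, bagged over 100 random half-splits with median aggregation.
   Reported with one-step-ahead predictions, goodness of fit (mean
   observed-vs-predicted correlation), optional accuracy against a known
   matrix, Schur-based stabilization, and network summaries
   (signed degrees, intra/inter-phylum link enrichment).

Everything is testable without external data: the package bundles
simulators for the five generating processes the scheme is validated on —
Dirichlet-multinomial sampling, Hubbell's neutral model, a self-organized
instability model, the Ricker map with intrinsic noise, and generalized
Lotka-Volterra dynamics — plus a Klemm-Eguiluz interaction-matrix
generator with tunable connectance and positive-edge percentage under a
Ricker stability constraint, measurement-noise models (Poisson,
multinomial), and preprocessing utilities (rarefaction, monotone
interpolation, interval thinning) for real tables.

## Worked example

Simulate an interacting community with known ground truth, then classify
it blind:

```r
library(ecosig)

A  <- generate_interaction_matrix(100, connectance = 0.05, pep = 16, seed = 1)
ts <- simulate_ricker(A, K = attr(A, "K"), sigma = 0.05,
                      n_timepoints = 3000, seed = 2)

community_noise_profile(ts)
#> <noise_profile> 100 taxa, 3000 time points
#>     white      pink     brown     black undefined
#>         0        50        14        11        25

report <- classify_time_series(ts, n_top = 30, n_bags = 50,
                               null_replicates = 99, seed = 3)
report
#> <classification_report> (ricker)
#>   step 1: structured (white 0.0%, threshold 50%)
#>   step 2: non-neutral (p = 0.01)
#>   step 3: LIMITS fit, goodness of fit 0.874

fit <- report$inference
inference_accuracy(as.matrix(A)[fit$taxa, fit$taxa], fit$inferred_matrix)
#> [1] 0.86
```

Reading the output: no white taxa means the series has temporal structure
(an i.i.d.-sampled community would be mostly white); the pink/brown/black
mixture reflects the intrinsic noise level σ = 0.05. The neutrality test
rejects (p = 0.01), so species-specific dynamics — here, real
interactions — are required, and the pipeline proceeds to inference. The
inferred 30×30 interaction matrix predicts held-out one-step dynamics with
mean correlation 0.87, and its rows correlate 0.86 with the generating
matrix. For a Hubbell (neutral) input the same pipeline stops after step 2
with a high p-value; for a Dirichlet-multinomial input it stops after
step 1 — even though both would have yielded a high goodness of fit had the
Ricker model been fitted anyway, which is exactly the confound the gating
prevents.

A thin command-line interface over the same functions is installed at
`inst/cli/ecosig.R` (subcommands `simulate`, `classify-noise`,
`test-neutrality`, `infer`, `perturb`, `pipeline`), reading and writing
tab-separated taxa-by-time tables.

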