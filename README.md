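# survcalib

Goodness-of-fit calibration tests for survival prediction models under
random right-censoring.

## The problem

Before a survival model's predicted curves `Ŝ(t | z)` can be trusted for
decision making, their *calibration* — the agreement between predicted and
actual outcome probabilities — has to be checked on independent validation
data. Discrimination measures (C-index) and mixed measures (integrated Brier
score) do not isolate calibration, and calibration plots require choosing a
fixed time point. The probability integral transform (PIT) gives a
follow-up-wide alternative: if `Ŝ` is the true model, then `Ŝ(X | Z)` is
standard uniform, so binning the residuals and running a Pearson test
assesses calibration directly. Censoring is the obstacle — with
right-censored times `T = min(X, C)`, `Δ = 1[X < C]`, the observed residuals
`Ŝ(t_i | z_i)` are a *censored* uniform sample.

`survcalib` implements two tests that resolve this differently:

- **D-calibration** (`d_calibration_test`) imputes the censored mass under
  the null hypothesis: a subject censored with `Ŝ(t_i | z_i) = s` spreads
  its unit count over `[0, s)` proportionally to interval lengths, and the
  resulting fractional counts `Ñ_k` are contrasted with `E_k = n |I_k|`.
  Because the imputation uses the very hypothesis being tested, the test is
  conservative under censoring — its actual type-I error falls well below
  the nominal level and power is lost.

- **A-calibration** (`a_calibration_test`) instead applies an Akritas-type
  Pearson goodness-of-fit test to the right-censored sample
  `r_i = 1 − Ŝ(t_i | z_i)`. Observed counts `N_k` are the uncensored
  residuals in each interval `I_k` of a partition of `[0, a]` (with `a` the
  empirical support of the residuals, or 1 for unbounded censoring), and the
  expected counts adjust for censoring nonparametrically:

  ```
  N_k = Σ_i 1[δ_i = 1, r_i ∈ I_k],      E_k = n ∫_{I_k} (1 − Ĥ(t)) / (1 − t) dt,
  ```

  where `Ĥ` is the ECDF of all residuals. The statistic
  `Σ_k (N_k − E_k)² / E_k` is chi-square with `K` degrees of freedom under
  the null. Only `E_k` depends on the null, so no power is lost to
  imputation: the actual significance level tracks the nominal one under
  every censoring scheme, and power is uniformly similar or superior to
  D-calibration.

The package also provides the Weibull simulation harness
(`S(t; α, σ) = exp(−(t/σ)^α)`, `σ = exp(βᵀz)`) with memoryless, uniform and
zero censoring schemes calibrated to a target censoring rate
(`simulate_dataset`, `calibrate_censoring`), and a Monte-Carlo engine
(`run_cell`, `run_grid`, `adjusted_level_comparison`) that estimates type-I
error and power of both tests over misspecification grids.

## Worked example

Simulate a validation set of 1,000 subjects under the default truth
(`α = 1`, `β = (log 2, log ½, log 2, log 1.5)`, `z₁, z₂ ~ N(0,1)`,
`z₃, z₄ ~ Bernoulli(0.5)`) with exponential censoring calibrated to 20%,
and test a model whose shape is misspecified by `λ = 0.85`:

```r
library(survcalib)
set.seed(2024)
scheme <- calibrate_censoring("memoryless", weibull_spec(), q = 0.2)
miscal <- misspecify(weibull_spec(), "shape", 0.85)
ds <- simulate_dataset(1000, truth = weibull_spec(), scheme = scheme, model = miscal)
s <- make_pit_sample(ds)
a_calibration_test(s, K = 10)
#>     A-calibration (Akritas-type GOF test for right-censored PIT residuals)
#>
#> X-squared = 58.3843, df = 10, p-value = 7.31731e-09
#> K = 10 intervals on [0, 0.993492]
d_calibration_test(s, K = 10)
#>     D-calibration (Pearson GOF test with null-imputed censored mass)
#>
#> X-squared = 42.6365, df = 9, p-value = 2.51323e-06
```

Both tests reject this miscalibrated model at n = 1,000; the A-calibration
statistic is larger relative to its reference distribution, reflecting its
greater power (the gap widens as censoring increases). Each result object
also carries the per-interval `observed` and `expected` vectors: here the
model systematically shifts event mass out of the early residual intervals
(e.g. 63 observed vs 100.5 expected in `I₁`), which is exactly the
early-time overestimation of survival a too-small shape produces.

Rejection rates over a grid (here a single cell, 200 repetitions):

```r
run_cell(n = 1000, m = 200, scheme = "memoryless", q = 0.2,
         mode = "shape", lambda = 1, seed = 1, scheme_obj = scheme)
```

returns `power_A ≈ 0.05` (the nominal level) and `power_D ≈ 0.015`
(conservative), with binomial standard errors.

A thin command-line front end with `test`, `simulate`, `power`, `fixture`
and `plot` subcommands is installed at
`system.file("cli/survcalib", package = "survcalib")`; results are emitted
as versioned JSON.

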