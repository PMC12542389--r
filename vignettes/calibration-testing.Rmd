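---
title: "Calibration testing for censored survival predictions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration testing for censored survival predictions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survcalib)
```

## Setting and notation

We observe i.i.d. right-censored survival data $(t_i, \delta_i, z_i)$,
$i = 1, \dots, n$, where $t_i = \min(x_i, c_i)$, $\delta_i = 1[x_i < c_i]$,
and a predictive model $\hat S(\cdot \mid z)$ fitted on *independent*
training data. The null hypothesis under test is that $\hat S$ is the true
conditional survival function — a simple hypothesis about this one model,
not a composite hypothesis about a model class.

Both tests in this package start from the probability integral transform:
if $X \mid Z$ has continuous survival function $S(\cdot \mid Z)$, then
$S(X \mid Z) \sim U(0, 1)$. Continuity is the only requirement — strict
monotonicity is not needed, because the generalized inverse
$S^{-1}_{\text{gen}}(y) = \inf\{t : S(t \mid z) \le y\}$ carries the
argument through flat segments (the test suite verifies uniformity for a
survival curve with a flat stretch). Conditional independence
$X \perp C \mid Z$ suffices for everything that follows: the transformed
times $U = S(X \mid Z)$ and $V = S(C \mid Z)$ are *unconditionally*
independent, because PIT values are independent of $Z$ and the dependence
between $X$ and $C$ runs only through $Z$. The suite checks this by
simulating censoring whose rate depends on the predictors and confirming
that the empirical correlation of $U$ and $V$ vanishes.

The residuals actually observed are $\hat S(t_i \mid z_i)$ — a
left-censored uniform sample (equivalently, $r_i = 1 - \hat S(t_i \mid
z_i)$ is right-censored). Both tests are Pearson-type,

$$\chi^2 \;=\; \sum_{k=1}^K \frac{(N_k - E_k)^2}{E_k},$$

over a partition $\{I_k\}$ of the residual scale; they differ in how
censoring enters $N_k$ and $E_k$.

## D-calibration

`d_calibration_test()` bins the $\hat S$-values on $[0, 1]$. An uncensored
subject contributes 1 to its interval. For a subject censored at $t_i$ with
$s = \hat S(t_i \mid z_i)$, the unobserved $\hat S(x_i \mid z_i)$ is, under
the null, uniform on $(0, s)$; its unit mass is therefore spread over
$[0, s)$ in proportion to interval lengths:

$$w_k \;=\;
\begin{cases}
0 & s \le \inf I_k,\\
(s - \inf I_k)/s & s \in I_k,\\
|I_k|/s & s \ge \sup I_k.
\end{cases}$$

These three cases collapse to
$w_k = (\min(s, \sup I_k) - \min(s, \inf I_k))/s$, which is how the
vectorized implementation computes them; the test suite asserts equality
with the literal case-by-case form and that every subject's weights sum to
one, so $\sum_k \tilde N_k = n$ exactly. Expected counts are $E_k = n|I_k|$.

Because $\tilde N_k$ is imputed from the null hypothesis itself, censoring
pulls the observed counts *toward* their expectations: the test keeps
(approximate) validity but becomes conservative, with an actual type-I
error below the nominal level that depends on the censoring scheme and
rate, and correspondingly reduced power. With no censoring the procedure
reduces exactly — bit for bit, as the suite asserts — to the classical
Pearson uniformity test on the $\hat S$-values.

**Degrees of freedom.** No reference distribution is derived for the
censored case in the literature this comparator reproduces; we use the
classical Pearson convention $K - 1$, and expose `df` as an argument for
sensitivity analysis. Simulation results involving D-calibration depend on
this choice only through the rejection threshold, and the conservatism
under censoring dwarfs the difference between $K$ and $K-1$.

## A-calibration

`a_calibration_test()` treats $r_i = 1 - \hat S(t_i \mid z_i)$ with
indicator $\delta_i$ as what it is — a right-censored i.i.d. sample — and
applies an Akritas-type goodness-of-fit construction. Writing $F$, $G$, $H$
for the distribution functions of $U' = 1 - U$, $V' = 1 - V$ and
$\min(U', V')$, the expected number of *uncensored* observations in $I_k$
is $n\int_{I_k}(1-G)\,dF$. Random censoring gives $(1-F)(1-G) = 1-H$, so
the unknown censoring distribution can be estimated as
$1 - \hat G = (1 - \hat H)/(1 - F_0)$ with $\hat H$ the ECDF of all
residuals and $F_0(t) = t$ the null (uniform) distribution. Hence

$$N_k = \sum_i 1[\delta_i = 1,\; r_i \in I_k], \qquad
  E_k = n \int_{I_k} \frac{1 - \hat H(t)}{1 - t}\, dt,$$

and the statistic is referred to $\chi^2_K$ — one degree of freedom per
interval, not $K - 1$, because the $E_k$ are not constrained to sum to the
observed total. Only $E_k$ involves the null hypothesis; no data are
imputed, which is where the power advantage over D-calibration comes from.

**Closed-form expected counts.** $1 - \hat H$ is a right-continuous step
function, so on each maximal subinterval $(u, v]$ of $I_k$ where it equals
a constant $c$ the integral contributes $c\,[\log(1-u) - \log(1-v)]$. The
implementation precomputes the cumulative integral at the order statistics
(one `cumsum`) and evaluates arbitrary partition edges from it in $O(n
\log n)$; the test suite checks it against adaptive quadrature
(`stats::integrate` piecewise between ECDF knots) to $10^{-8}$ relative
tolerance on hundreds of random censored samples, and that the value is
insensitive to the "$\le$" versus "$<$" ECDF convention (the conventions
differ on a Lebesgue-null set).

**Support truncation.** When censoring is bounded, $H$ has support
$[0, a]$ with $a < 1$ and intervals beyond $a$ would have $E_k = 0$. The
partition is therefore laid over $[0, a]$ with the pragmatic empirical
choice $a = \sup\{t : 1 - \hat H(t) > 0\}$, i.e. the largest residual.
This truncation has no theoretical coverage guarantee, but the null
distribution of the statistic remains indistinguishable from $\chi^2_K$ in
the package's own simulations (the p-value uniformity checks below). When
the censoring distribution is known to be unbounded the caller can override
with `support = 1`.

**Numerical safeguards.**

* Residuals are clamped to $[0, 1 - 10^{-12}]$ before any ECDF or integral
  computation. $\hat S = 0$ is legitimate input, but $t = 1$ is a
  (removable) singularity of $1/(1-t)$; the clamp makes the boundary
  integrable without measurably perturbing any count.
* Intervals whose expected count falls below $10^{-10}$ — possible only
  when a caller-supplied partition extends beyond the effective support —
  are dropped from the sum with a warning and the degrees of freedom
  reduced accordingly, avoiding $0/0$.
* Interior partition edges follow the half-open convention (a residual on
  an edge belongs to the interval to its right); the last interval is
  closed. The D-calibration allocation uses the same convention, under
  which a censored $s$ equal to an interior edge receives zero weight from
  both adjacent cases consistently.
* p-values use the exact upper tail of the chi-square distribution; no
  continuity correction is applied.

`K = 10` equal-width intervals is the default for both tests. The choice of
partition is the one genuinely arbitrary ingredient both tests inherit from
the Pearson construction; `K` and custom `edges` are exposed so users can
run sensitivity analyses, and `n >= K` is enforced.

## The simulation harness

`simulate_dataset()` and friends generate the validation data used to
characterize both tests. Event times follow
$S(t; \alpha, \sigma) = \exp(-(t/\sigma)^\alpha)$ with
$\sigma = \exp(\beta^\top z)$, sampled by inverse transform
$X = \sigma(-\log U)^{1/\alpha}$. The default truth is $\alpha = 1$,
$\beta = (\log 2, \log \tfrac12, \log 2, \log 1.5)$ with
$z_1, z_2 \sim N(0,1)$ and $z_3, z_4 \sim \text{Bernoulli}(0.5)$ — an
exponential model with moderate predictor effects in both directions, the
configuration the whole power study is anchored to. Misspecified predictive
models scale the shape ($\alpha' = \lambda\alpha$), the coefficients
($\beta' = \lambda\beta$), or zero out one coefficient ("missing
predictor"). The missing-predictor model is the truncated model, not a
refit: the study evaluates fixed predictive models on validation data, and
no refitting step is part of that design; truncation is also the choice
that isolates the effect of omitting a predictor from everything else.

Three censoring schemes are provided: *memoryless*
($C \sim \text{Exp}(c)$), *uniform* ($C \sim U(0, b)$) and *zero* ($C = 0$
with probability $q$, else $C = \infty$). Zero-censored subjects enter with
$t = 0$, $\delta = 0$, $\hat S(0 \mid z) = 1$, residual 0 — they join
$\hat H$ for A-calibration and receive the full uniform spread $|I_k|$ in
D-calibration, which is precisely the mechanism that inflates D-calibration
p-values under heavy early censoring.

**Rate calibration.** `calibrate_censoring()` solves for the scheme
parameter hitting a target censoring fraction $q = P(C < X)$. For the zero
scheme the parameter *is* $q$. For the other two, $q(\text{param})$ is
estimated by Monte Carlo with a fixed internal seed and $10^6$ event-time
draws, integrating the closed-form conditional probability — $E[1 -
e^{-cX}]$ for the exponential scheme, $E[\min(X/b, 1)]$ for the uniform —
over the draws, and the monotone equation is solved by bracketed
root-finding (`uniroot` with geometric bracket expansion). Averaging the
conditional probability rather than simulating censoring indicators removes
most of the Monte-Carlo noise, so the achieved $|q - q_{\text{target}}|$ is
well inside the 0.002 acceptance bound; where closed forms exist (e.g.
$c = q/(1-q)$ for a unit-exponential event time) they serve as independent
oracles in the tests, never as the implementation.

## The Monte-Carlo power engine

`run_cell()` estimates rejection rates for one (scheme, $q$, mode,
$\lambda$, $n$) cell by repeated simulate–predict–test cycles;
`run_grid()` maps it over a factor grid, calibrating each (scheme, $q$)
pair once. Rejection proportions carry binomial standard errors
$\sqrt{p(1-p)/m}$. Per-repetition seeds are derived as
$\text{hash(cell)} + 10007\,\text{seed} + 97\,i \bmod (2^{31}-1)$, so every
cell is reproducible in isolation and results are independent of execution
order; all arithmetic stays below $2^{31}$.
`adjusted_level_comparison()` reruns a cell with A-calibration's level set
to a reference value — typically D-calibration's measured actual level — so
the two tests can be compared at matched actual size rather than matched
nominal size.

**Problem sizes.** The package's own validation uses desk-scale replication
counts: 5,000 repetitions for the null-model type-I-error checks, 2,000 per
cell for power comparisons and p-value uniformity checks, $n = 1000$
subjects per dataset, and $2 \times 10^5$ draws for law-of-large-numbers
checks of the generator. These sizes put three binomial standard errors at
well under one percentage point for the quantities being checked, which is
tight enough to separate an actual level near 1.7% from a nominal 5% by a
wide margin.

## What the synthetic data does and does not show

The generator reproduces the study conditions exactly: a correctly
specified or deliberately misspecified parametric model, independent
subjects, covariate-independent censoring from three analytic families, and
predictors with clean marginals. Passing tests therefore demonstrate the
distributional properties of the *tests* (null calibration, conservatism,
power ordering) under those conditions. They do not exercise: dependent or
informative censoring beyond what Proposition-style independence covers,
model uncertainty from estimating $\hat S$ on finite training data
(validation data must be independent of training data for the PIT argument
to hold), ties or coarsened observation times, left truncation, or
real-data quirks such as administrative censoring spikes. For real
validation studies the p-value is best read as a continuous calibration
measure — larger is better calibrated — and comparisons across models are
meaningful only at equal $n$, equal partition and the same validation set.

## Known limitations

* The choice of $K$ (and of equal-width intervals) is inherited from the
  Pearson construction and left to the investigator; distribution-free
  alternatives (censored Kolmogorov–Smirnov / Anderson–Darling) would
  remove it but are out of scope here.
* The empirical-support truncation for bounded censoring is a pragmatic
  device without distribution theory; its adequacy is established
  empirically by the null p-value uniformity checks across censoring
  schemes, including uniform censoring where the bound binds.
* The D-calibration reference distribution under censoring is approximate
  by construction; this package reproduces the comparator as published
  rather than attempting a correction.
* A censored subject with $\hat S(t_i \mid z_i) = 0$ has no defined
  allocation in D-calibration and is rejected as invalid input rather than
  silently dropped.
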