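---
title: "Second-order causal discovery for autocorrelated time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-order causal discovery for autocorrelated time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soccd)
```

## The problem

Slow neuroimaging signals — fMRI BOLD, or the amplitude envelopes
("energies") of MEG/EEG sources — evolve on time scales an order of
magnitude slower than the neural propagation between brain regions.
Causal influences between such signals therefore appear *instantaneous*:
they happen within a single sampling interval, which makes them invisible
to lag-based methods such as Granger causality. Non-Gaussianity-based
structural equation models (LiNGAM) handle instantaneous effects but fail
when the data are close to Gaussian, which is typical after the heavy
preprocessing and averaging common in neuroimaging pipelines.

`soccd` implements a third source of identification: *temporal
autocorrelation*. For a standardized, jointly Gaussian pair of stationary
series the two candidate models

\[
y_t = \alpha x_t + d_t \qquad\text{(x causes y)}
\]
\[
x_t = \alpha y_t + e_t \qquad\text{(y causes x)}
\]

share the same regression coefficient \(\alpha\), so second-order
*marginal* statistics cannot distinguish them. But if the regressor's
autocorrelation function differs from the noise's at any lag, the
*residual* of the correct model is independent of its regressor as a
process (at all lags jointly), while the residual of the wrong model is
not. The direction is identifiable if and only if regressor and noise
have different autocorrelation functions — exactly the identifiability
condition of second-order blind source separation.

## The decision criterion

Cut both standardized series into time-aligned windows of length \(L\)
and treat the windows as repeated instances of an \(L\)-dimensional
random vector. With \(\mathrm{cov}(\cdot)\) the \(L \times L\) window
covariance and \([a;b]\) the \(2L\)-dimensional concatenation, the
Gaussian mutual information between window variables is

\[
2 I(a, b) = \log\det \mathrm{cov}(a) + \log\det \mathrm{cov}(b)
          - \log\det \mathrm{cov}([a;b]),
\]

the entropy constants cancelling. (The Gaussian differential entropy used
throughout is \(h = \tfrac12 \log\det \mathrm{cov} +
\tfrac{n}{2}(1 + \log 2\pi)\), the standard closed form.) The decision
criterion compares the residual-regressor dependence under the two
models:

\[
C = 2 I(x, d) - 2 I(y, e),
\qquad d = y - \hat\alpha x,\quad e = x - \hat\alpha y .
\]

\(C < 0\) selects \(x \to y\), \(C > 0\) selects \(y \to x\). The
criterion equals the log-likelihood ratio of the two models, which gives
it the usual efficiency of likelihood methods — visible in the benchmark
as a pronounced advantage at small sample sizes. `soc_decide()` runs the
whole pipeline; `soc_population_criterion()` evaluates the same quantity
on the exact (Toeplitz) population covariances of the AR(1) generative
model, and is the infinite-data oracle the empirical estimator is tested
against.

Both plug-in mutual informations are nonnegative for any PSD covariance
estimates (Fischer's inequality), and swapping the arguments flips the
sign of \(C\) exactly, because the same pooled \(\hat\alpha\) and the
same ridge are used for both models.

## Tunable parameters

* **Window length `L`** (default 5 samples) and **stride** (default `L`,
  i.e. non-overlapping). Non-overlapping windows limit dependence between
  the "instances" used for covariance estimation. `L` trades off how many
  lags of autocorrelation contrast the criterion can see (larger is more
  informative) against the number of windows available (smaller is more
  stable). For short series the benchmark harness falls back to stride 1
  (maximally overlapping windows) whenever fewer than `m_min` complete
  windows would result; `m_min = max(20, 10 L)` guards against meaningless
  covariance estimates.
* **Ridge** (default `1e-6`, relative to the mean diagonal) keeps the
  log-determinants finite for near-singular sample covariances. If a
  Cholesky factorization still fails the ridge is escalated tenfold up to
  `1e-2`, identically for both models so the antisymmetry of \(C\) is
  preserved; beyond that the input is reported as degenerate.
* **Toeplitz projection** (off by default): averaging the window
  covariance along diagonals enforces stationarity and reduces variance
  at small sample sizes. It is off by default to match the plain
  covariance formulation of the criterion.
* **Tie tolerance** `1e-12`: `|C|` below it yields `"undetermined"`; the
  benchmark scores such decisions as a seeded fair coin flip.
* **Divisor convention**: population divisor \(m\) everywhere (not
  \(m-1\)); the choice cancels in the leading behavior of \(C\) but is
  fixed for reproducibility.
* \(\hat\alpha\) is the pooled lag-0 correlation of the windowed,
  standardized series, shared between the two candidate models (the
  models' regression coefficients coincide under standardization). The
  residuals are *not* re-standardized before entering the criterion:
  multivariate Gaussian MI is not invariant to the implied joint
  rescaling, so the covariances enter as-is.

## Baselines

* **Pairwise LiNGAM** (`pwlingam_decide()`): the likelihood-ratio
  statistic \(R = \hat\rho\,\mathrm{E}[x\,g(y) - g(x)\,y]\) with
  \(g=\tanh\), the nonlinearity suited to sparse/super-Gaussian sources;
  a cumulant variant \(\hat\rho\,\mathrm{E}[x^3 y - x y^3]\) is available
  behind a flag for sensitivity checks. It exploits non-Gaussianity only:
  on jointly Gaussian AR pairs it performs at chance, with Laplace
  innovations and no observational noise it is nearly perfect — both
  regimes are locked in by tests.
* **Granger causality** (`granger_decide()`): bivariate VAR fitted by
  per-equation OLS with intercept on standardized series, order selected
  in `1..p_max` by AIC of the full model's Gaussian likelihood over a
  common estimation sample (all candidate orders are scored on the
  observations left after dropping `p_max` initial values, so their AICs
  are comparable). The directional statistic is the log ratio of
  restricted (own lags only) to full residual variance; the larger of
  GC(x→y), GC(y→x) wins, with no significance gating, so every pair
  yields a direction — matching how benchmark accuracies are tabulated.
  `p_max` defaults to 10 and is capped at `n/20` in the harness so the
  fits stay well-conditioned at small `n`.

## The synthetic-data generator

`simulate_pair()` reproduces the benchmark's generative model: a
stationary AR regressor (default AR(1) with coefficient 0.8, Gaussian
innovations of unit variance), AR(1) model noise with coefficient 0.2,
instantaneous coupling \(y = \alpha x + d\), and optional Gaussian
observational noise added independently to both variables with variance
`var(signal)/snr` (SNR defined as a per-variable variance ratio). A
burn-in of 200 samples removes the influence of initial conditions.
Laplace innovations are drawn with scale \(b = \sigma/\sqrt2\) so the
innovation variance is unchanged; they make the process non-Gaussian
(excess kurtosis 3 at order 0) without touching its second-order
structure. The default AR(3) alternative uses coefficients
(0.5, 0.2, 0.1), a stationary spectrum distinct from the noise's.

`simulate_network()` extends this to an instantaneous SEM over a DAG:
each node carries an independent AR disturbance with its own spectrum,
and node values are built in topological order as disturbance plus
weighted parent values. Distinct per-node AR spectra are what make every
parent–child pair orientable.

`run_benchmark()` simulates `n_datasets` pairs per condition (per-dataset
seeds derived deterministically from the master seed and the condition
index, so conditions are decoupled), applies each detector to the same
pairs, and tabulates percent correct with exact binomial 95% intervals.
The default desk scale is 400 datasets per condition; the full 10,000 of
the original benchmark design is available through the same argument.

## Two-stage network estimation

`two_stage()` first estimates *which* nodes are connected, then *how*
each connection is directed:

1. **Skeleton**: L1-penalized precision matrix (graphical lasso) with the
   penalty chosen by K-fold cross-validated Gaussian log-likelihood over
   a descending log-spaced grid (warm starts along the path). The solver
   is the blockwise coordinate-descent algorithm, implemented in the
   package. By default the **one-standard-error rule** picks the
   sparsest penalty within one SE of the best CV score: raw CV
   maximization is known to over-select, and with ten independent
   sources it retains dozens of spurious edges where the 1-SE rule
   retains none. An edge is declared where the off-diagonal precision
   entry exceeds `1e-8` (the lasso produces exact zeros; the threshold
   only guards floating noise).
2. **Orientation**: the chosen pairwise detector is run on the
   full-length column pair of every skeleton edge; the two stages are
   treated as independent.

A caveat worth knowing: even at the CV-selected penalty, precision
entries that are zero in population (e.g. the end-points of a chain,
conditionally independent given the middle node) are frequently retained
at sampling-noise magnitude — the CV-optimal penalty sits at that noise
scale, and *larger* penalties make it worse because shrinking the strong
entries leaks marginal correlation into the conditionally-independent
ones. This is a property of the estimator class (the reference
cross-validated graphical-lasso implementations behave identically), not
of this implementation. Tests therefore check that spurious entries stay
at noise scale, far below true-edge partial correlations, rather than
demanding exact support recovery. Recall of true edges and orientation
accuracy — the quantities the two-stage method is used for — are
unaffected.

Orientations are pairwise and may jointly contain cycles; no global DAG
search is attempted. `flow_matrix()` exports the heatmap convention
out-flow positive / in-flow negative.

## Split-half reliability

For multi-subject data (subject × time × source), three edge-wise metrics
can be checked for reproducibility: precision-matrix entries, raw
pairwise criterion values on all source pairs, and skeleton-masked
criterion values ("two-stage"). `intra_subject_split_half()` splits each
subject at the temporal midpoint (odd sample to the first half) and
correlates the vectorized upper-triangle values between halves;
`inter_group_split_half()` does the same between temporal concatenations
of two random disjoint subject groups, repeated `n_repeats` times
(default 100). "Correlation" is Pearson by default, Spearman behind a
flag. For the two-stage metric the halves' skeletons are reconciled by
taking their union, with absent edges contributing 0.

`template_accuracy()` estimates a group-level directed network from the
concatenation of all subjects as a proxy for ground truth, re-orients the
template's edges on each sampled subject's data alone, and reports the
per-edge and global fraction of subjects that agree with the template
(chance level 0.5).

One reported real-data regularity is *not* reproduced by clean synthetic
cohorts: that skeleton masking increases split-half consistency relative
to the raw criterion values. On AR-SEM cohorts the two metrics come out
statistically indistinguishable (the masked variant a hair lower),
because (a) the CV-selected skeleton is dense, so little is masked;
(b) edges present in only one half's skeleton contribute pure (value, 0)
discordance under the union rule; and (c) truly disconnected pairs
produce consistent near-zero values that *stabilize* the raw Pearson
correlation rather than degrade it. The ordering observed on real MEG
envelopes plausibly reflects dense, nonstationary dependence structure
that the controlled AR generator deliberately does not emulate. The
corresponding property test states the ordering and is allowed to fail
on synthetic cohorts; the calibration controls (perfect correlation on
duplicated halves, chance on white noise, chance template accuracy for a
coin-flip orienter) all hold.

## Envelope preparation

`amplitude_envelope()` computes per-column amplitude envelopes as the
modulus of the analytic signal, constructed directly via FFT; the first
and last 2% of samples are affected by the transform's circularity and
can be trimmed with a flag. `resample_table()` downsamples with the
polyphase anti-aliasing resampler from the `signal` package, after
reflection-padding each column to suppress the filter's edge transients
(steady-state gain error is about `1e-4`). Envelopes are nonnegative and
invariant to sign flips of the input by construction; both properties
are tested against closed-form signals (constant-amplitude and
amplitude-modulated sinusoids).

## Problem sizes used by the tests

The packaged checks run at desk scale, chosen so the whole suite
completes in a few minutes while keeping binomial uncertainty small
relative to the effects tested: 400 Monte-Carlo datasets per benchmark
condition (99% binomial band around chance: ±0.064), 10,000 windows for
the analytic-oracle comparison (tolerance 0.05 nats), 20 seeds for
network-recovery and cohort-level properties, and 5-node / 8-node
synthetic networks with 2,000–5,000 samples. All stochastic steps take
explicit seeds; identical seeds give bit-identical results.

## Known limitations

* The identifiability condition is intrinsic: when regressor and noise
  share an autocorrelation function (the r = 0.2 boundary in the
  benchmark), no second-order method can recover the direction; the
  package returns chance-level decisions there, and the analytic
  criterion is exactly zero.
* The criterion has no attached significance test; only its sign and
  magnitude are reported, and the two-stage stage treats all skeleton
  edges equally.
* Windowing of a single long series assumes stationarity; the optional
  Toeplitz projection enforces it but is off by default.
* The AR generator validates method behavior under controlled temporal
  dependence. It does not emulate measurement nonstationarity,
  inter-subject variability, volume conduction, or source-separation
  error in real envelope data — passing synthetic benchmarks therefore
  shows correctness of the estimator, not end-to-end performance on real
  recordings.
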