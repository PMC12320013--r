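# soccd — second-order causal discovery for autocorrelated time series

`soccd` decides the direction of *instantaneous* (contemporaneous) causal
influence between two temporally autocorrelated signals, using only
second-order statistics. It is aimed at slow neuroimaging signals — fMRI,
or the amplitude envelopes of MEG/EEG sources — where causal influences
propagate faster than the sampling interval, so lag-based methods
(Granger causality) miss them, and where the data are too close to
Gaussian for non-Gaussianity-based SEM methods (LiNGAM) to work.

## The method

For standardized, jointly Gaussian series the two candidate models
`y = αx + d` and `x = αy + e` share the same coefficient α, but the
residual of the *correct* model is independent of its regressor as a
process. Cutting both series into aligned windows of length *L* and
writing `cov(·)` for the L×L window covariance, the criterion is the
difference of Gaussian mutual informations (equivalently, the
log-likelihood ratio of the two models):

    C = 2 I(x,d) − 2 I(y,e),
    2 I(a,b) = logdet cov(a) + logdet cov(b) − logdet cov([a;b])

`C < 0` ⇒ x → y, `C > 0` ⇒ y → x. The direction is identifiable if and
only if the regressor's autocorrelation function differs from the
noise's at some lag.

Around this core the package provides:

* `soc_decide()` — the decision pipeline; `soc_population_criterion()` —
  its closed-form infinite-data oracle for AR(1) models;
* `pwlingam_decide()`, `granger_decide()` — the standard baselines;
* `simulate_ar()` / `simulate_pair()` / `simulate_network()` and
  `run_benchmark()` — a controlled AR Monte-Carlo benchmark;
* `estimate_skeleton()` / `orient_edges()` / `two_stage()` — directed
  ("effective connectivity") network estimation: graphical-lasso skeleton
  with cross-validated penalty, pairwise orientation of each edge;
* `intra_subject_split_half()`, `inter_group_split_half()`,
  `template_accuracy()` — split-half reliability procedures for
  multi-subject data;
* `amplitude_envelope()` / `resample_table()` — Hilbert-envelope
  preparation of oscillatory signals.

## Worked example

```r
library(soccd)

# simulate a pair with known direction x -> y: AR(1) regressor (coef 0.8),
# AR(1) noise (coef 0.2), instantaneous coupling alpha = 0.5
spec <- pair_spec(alpha = 0.5, regressor = ar_spec(0.8),
                  noise = ar_spec(0.2), n_samples = 2000)
p <- simulate_pair(spec, seed = 7)
soc_decide(p$x, p$y)
#> soc decision: x_to_y
#>   criterion C = -1.83579 nats (negative => x -> y)
#>   alpha_hat = 0.6446, I(x,d) = 0.026193, I(y,e) = 0.944087

soc_population_criterion(r = 0.8, alpha = 0.5, noise_coef = 0.2, L = 5)$C
#> [1] -1.7814
```

The criterion is strongly negative: the model x → y leaves a residual
nearly independent of x (0.026 nats) while the reverse model's residual
carries 0.944 nats of dependence, and the empirical value sits close to
its analytic population limit (−1.78 nats). `alpha_hat` is the pooled
lag-0 correlation, the shared coefficient estimate of the two models.

Benchmarking against the baselines (percent of 100 simulated datasets per
condition decided correctly, with exact binomial 95% intervals):

```r
run_benchmark(data.frame(alpha = 0.5, n = c(100, 1000)), n_datasets = 100,
              methods = c("soc", "granger", "pwlingam"), seed = 7)
#>     method    n accuracy ci_lower ci_upper
#> 1      soc  100     0.99    0.946    1.000
#> 2  granger  100     0.96    0.901    0.989
#> 3 pwlingam  100     0.45    0.350    0.553
#> 4      soc 1000     1.00    0.964    1.000
#> 5  granger 1000     1.00    0.964    1.000
#> 6 pwlingam 1000     0.52    0.418    0.621
```

The pattern is the method's signature: pairwise LiNGAM is at chance
(these data are jointly Gaussian), Granger causality works but loses
ground at small n, and the second-order criterion stays near-perfect
even at n = 100.

## Command line

A thin front end over the same functions lives at `inst/cli/soc.R`:

```sh
Rscript inst/cli/soc.R simulate  --alpha 0.5 --r 0.8 --n 2000 --seed 7 --out pair.csv
Rscript inst/cli/soc.R direction --input pair.csv --x x --y y --out result.json
Rscript inst/cli/soc.R network   --input sources.csv --method soc --seed 7 --out edges.csv
Rscript inst/cli/soc.R envelope  --input raw.csv --fs 256 --resample 1 --out env.csv
Rscript inst/cli/soc.R splithalf --data-dir subjects/ --metric two_stage --seed 7
```

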