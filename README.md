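# metricCP

Statistically valid prediction bounds on **scalar clinical metrics derived
from probabilistic image reconstructions**.

Generative reconstruction algorithms for ill-posed imaging problems (e.g.
sparse-view CT) return an ensemble of plausible images per subject, and
those images can look convincing while being systematically wrong. For a
clinician the quantity of interest is usually not the pixels but a derived
scalar — thoracic fat volume, an organ volume, a dose metric. `metricCP`
calibrates distribution-free prediction intervals on such a metric with
split conformal prediction, maps the interval back to nearest-neighbour
reconstructions for visual inspection, and flags outlier reconstructions
whose metric values are statistically unlikely.

## The method

Let $f$ map an image to a scalar metric, and let subject $i$'s ensemble of
$n_s$ sampled reconstructions yield predicted metrics
$\hat Y_i = \{\hat Y_{i,j}\}$. Given a calibration set of $n$ subjects with
known ground truth $Y_i$ and mis-coverage rates $\alpha_{lo}, \alpha_{hi}$:

1. **Non-conformity scores** (per calibration subject):
   $s_{i,lo} = Q_{\alpha_{lo}}(\hat Y_i) - Y_i$,
   $s_{i,hi} = Y_i - Q_{1-\alpha_{hi}}(\hat Y_i)$,
   where $Q_\alpha$ is the lower empirical quantile
   ($k$-th smallest, $k = \max(1,\lceil \alpha m \rceil)$).
2. **Quantile adjustments** at the finite-sample adjusted levels
   $\hat\alpha = \lfloor \alpha(n+1) \rfloor / n$:
   $q_{lo} = Q_{1-\hat\alpha_{lo}}(\{s_{i,lo}\})$,
   $q_{hi} = Q_{1-\hat\alpha_{hi}}(\{s_{i,hi}\})$.
3. **Prediction interval** for a test ensemble $\hat Y$:
   $C(\hat Y) = [\,Q_{\alpha_{lo}}(\hat Y) - q_{lo},\;
   Q_{1-\alpha_{hi}}(\hat Y) + q_{hi}\,]$.

Under exchangeability of calibration and test subjects,
$P\{Y \in C(\hat Y)\} \gtrsim 1 - \alpha_{lo} - \alpha_{hi}$ marginally.
The ensemble members with metrics nearest $L$ and $U$ are the visual
lower/upper bound reconstructions; members with metrics outside $[L, U]$
are outliers.

The package also implements the uncalibrated metric-quantile baseline,
pixel-wise quantile bounds, per-pixel conformalized bounds, a fat-volume
metric (pixels in the closed window $[-150, -50]$ HU times slice
thickness), a repeated random-split evaluation harness, and a synthetic
generator (scalar ensembles and CT-like fat phantoms) that makes everything
testable without any data download.

## Worked example

```r
library(metricCP)

# a synthetic exchangeable pool: biased, over-dispersed ensembles
pool <- generate_metric_pool(n_subjects = 100, ns = 50, seed = 1)
fit <- metric_cp(pool, alpha_lo = 0.05, alpha_hi = 0.05)
fit
#> Metric-guided split conformal calibration
#>   calibration subjects: n = 100
#>   rates: alpha_lo = 0.05, alpha_hi = 0.05 (nominal coverage 0.9)
#>   adjusted levels: alpha_hat_lo = 0.05, alpha_hat_hi = 0.05
#>   quantile adjustments: q_lo = -1.527, q_hi = -16.5

test <- generate_metric_pool(n_subjects = 1, ns = 50, seed = 2)
iv <- predict(fit, newdata = test$ensembles[[1]])
iv
#> Prediction interval(s) on the metric (1 subject)
#>   lower upper length
#> 1 80.88 92.43  11.55

retrieval_report(test$ensembles[[1]], iv)
#> Metric-space retrieval report
#>   interval: [80.88, 92.43] (length 11.55)
#>   lower-bound image: index 36 (metric 81.1)
#>   upper-bound image: index 7 (metric 92.25)
#>   inliers: 18 / 50; outliers: 1, 2, 4, 5, 6, 8, 9, ...
```

The fitted adjustments are both *negative*: this pool's ensembles
over-disperse (spread inflated 1.5x) as well as sit high (bias +7.5), so
calibration tightens the wide upper quantile by 16.5 metric units while
nearly keeping the lower one. The test subject's truth (86.5) falls inside
the interval; 32 of the 50 sampled reconstructions are flagged as metric
outliers. Coverage against the uncalibrated baseline over repeated random
75%–25% splits:

```r
run_split_experiment(pool, methods = c("metric_cp", "metric"),
                     n_splits = 200, seed = 3)
#> Random-split evaluation: 200 splits, seed 3
#>     method coverage mean_interval_length normalized_interval_length
#>  metric_cp   0.8942                7.672                       1.00
#>     metric   0.9906               25.241                       3.29
```

The calibrated method sits at the nominal 0.9 with intervals a third the
length of the raw quantile interval. (With a larger ensemble bias the raw
interval's coverage collapses while the calibrated one holds — see the test
suite.)

A command-line interface with subcommands `simulate`, `calibrate`,
`predict`, `retrieve` and `evaluate` wraps the same functions; see
`system.file("cli", "metriccp", package = "metricCP")` and `?cli_main`.
Methodological details are in the vignette
(`vignettes/metric-conformal-bounds.Rmd`).

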