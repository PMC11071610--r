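---
title: "Metric-guided conformal bounds for reconstruction ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-guided conformal bounds for reconstruction ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metricCP)
```

## The problem

Probabilistic reconstruction algorithms for ill-posed imaging problems —
sparse-view CT being the motivating case — return not one image but a
*sample* of plausible images per subject. Modern generative reconstructions
look convincing even when they are wrong, so a clinician asking a concrete
question ("how much thoracic fat does this patient have?") cannot trust the
spread of the sample at face value: the ensemble may be systematically
biased or over/under-dispersed relative to the true scan.

`metricCP` addresses this by working on a *derived scalar metric* rather
than on pixels. A metric function $f:\mathbb{R}^\Omega \to \mathbb{R}$
(e.g. fat volume by Hounsfield-unit windowing) turns each sampled
reconstruction of subject $i$ into a predicted metric value
$\hat Y_{i,j}$, $j = 1,\dots,n_s$. Using a calibration set of $n$ subjects
whose ground-truth metric $Y_i$ is known, split conformal prediction turns
the ensemble of a new subject into an interval $[L, U]$ that contains the
true metric with probability at least about
$1 - \alpha_{lo} - \alpha_{hi}$, *marginally* over calibration/test draws,
under the single assumption that calibration and test subjects are
exchangeable. No distributional assumption on the metric or the
reconstruction algorithm is needed.

## The calibration procedure

For each calibration subject the two one-sided *non-conformity scores*
measure how far the ensemble's sample quantiles miss the truth:

$$ s_{i,lo} = Q_{\alpha_{lo}}(\hat Y_i) - Y_i, \qquad
   s_{i,hi} = Y_i - Q_{1-\alpha_{hi}}(\hat Y_i). $$

A positive $s_{i,lo}$ means the ensemble's lower quantile sits *above* the
truth (the raw interval would miss from below); negative scores mean the
ensemble is already conservative on that side. The calibrated adjustments
are score quantiles at the finite-sample adjusted levels

$$ \hat\alpha = \lfloor \alpha (n+1) \rfloor / n, \qquad
   q_{lo} = Q_{1-\hat\alpha_{lo}}(\{s_{i,lo}\}), \quad
   q_{hi} = Q_{1-\hat\alpha_{hi}}(\{s_{i,hi}\}), $$

and the prediction interval for a test ensemble $\hat Y$ is

$$ C(\hat Y) = [\, Q_{\alpha_{lo}}(\hat Y) - q_{lo}, \;
                 Q_{1-\alpha_{hi}}(\hat Y) + q_{hi} \,]. $$

Design points worth spelling out:

* **The two sides are calibrated independently**, each from its own
  one-sided score set. The nominal two-sided miss is
  $\alpha_{lo} + \alpha_{hi}$.
* **Scores may be negative and are used as-is.** If the ensemble is
  already conservative on a side, the adjustment is negative and
  *tightens* the interval — this follows the formulas literally and is
  why calibrated intervals can be much shorter than raw quantile
  intervals when the ensemble over-disperses.
* **The floor-based level adjustment** selects the
  $k = n - \lfloor \alpha(n+1) \rfloor$-th smallest score, giving
  per-side coverage $k/(n+1)$ — a whisker *below* the nominal
  $1 - \alpha$ (e.g. $178/188 \approx 0.947$ per side at $n = 187$,
  $\alpha = 0.05$, hence about $0.894$ two-sided). This discrete
  shortfall is inherent to the convention and visible in the repeated
  split simulations below; it shrinks as $n$ grows.
* **Degenerate calibration sizes**: when
  $\lfloor \alpha(n+1) \rfloor = 0$ the adjusted level is 0, the
  adjustment is the score *maximum* (the most conservative choice), and
  a warning is emitted that $n$ is too small for the requested rate.

## The quantile convention

Sample quantiles on small sets are convention-sensitive, and the
conformal guarantee is an exact statement about order statistics, so the
package fixes **one** convention everywhere ([`empirical_quantile()`]):
the level-$\alpha$ quantile of $m$ values is the $k$-th smallest with
$k = \max(1, \lceil \alpha m \rceil)$ — the lower empirical quantile, no
interpolation. Level 0 is the minimum and level 1 the maximum.
Interpolating conventions (the default types of `stats::quantile()`)
were deliberately rejected: they break the integer-indexing on which the
finite-sample argument rests. A fuzz of $10^{-9}$ is applied before the
ceiling/floor so that products that are integers in exact arithmetic
(such as $(1 - 9/187)\cdot 187 = 178$ or $0.7 \cdot 10 = 7$) are not
pushed to a neighbouring order statistic by floating-point error — the
same pragmatic guard `stats::quantile()` uses.

One subtlety follows from the convention: the *composed* interval
endpoint is not pointwise monotone in $\alpha$. Shrinking $\alpha$ moves
the base quantile outward and raises the adjustment level, but it also
shifts the score set itself, and on a fixed data set the net endpoint
can move either way by a small amount. What monotonically improves is
the *coverage*; the test suite asserts monotonicity of the two
components separately and checks coverage by simulation.

## From metric bounds back to images

The interval is mapped back into image space (`retrieval_report()`):

* the **lower/upper bound reconstructions** are the ensemble members
  whose metric is nearest (absolute distance, exhaustive scan) to $L$
  and $U$ — ties break to the smallest index, deterministically;
* **inliers** are members with metric in the *closed* interval
  $[L, U]$, **outliers** the rest. Interval membership is closed
  everywhere in the package (retrieval, coverage, the fat window), so a
  value sitting exactly on a bound is always "in".
* a crossed interval ($U < L$, which adjusted endpoints can produce) is
  treated as empty: every member is an outlier and a warning is raised;
  its length is reported as 0 rather than negative.

Outlier members are the practically interesting ones: reconstructions
that look plausible as images but whose metric is statistically unlikely
given the calibrated bounds.

Endpoints are *not* clamped to the metric's physical domain (e.g.
non-negative volumes) by default; `predict(fit, newdata, domain = c(0, Inf))`
opts in, since clamping is a presentation choice, not part of the
guarantee.

## Baselines

Three comparison methods are included so the value of metric-space
calibration can be demonstrated rather than asserted:

* **metric** — the raw quantile interval
  $[Q_{\alpha_{lo}}(\hat Y), Q_{1-\alpha_{hi}}(\hat Y)]$, no
  calibration. It under-covers as soon as the ensemble bias exceeds the
  raw interval's reach.
* **pixel** — per-pixel intensity quantiles across the ensemble,
  yielding a lower and an upper bound *image*; the metric function is
  never consulted.
* **pixel_cp** — per-pixel *independent* split conformal calibration
  with the same score form as the scalar method, each pixel treated as
  its own scalar metric. Published pixel-CP variants differ in details
  (pooled vs per-pixel adjustments, alternative scores); the per-pixel
  independent form was chosen because it is the most direct reading of
  "adjust the pixel-wise quantiles" and because it collapses *exactly*
  to the scalar algorithm on $1\times1$ images — an equality the test
  suite checks bit-for-bit, which pins the implementation to the scalar
  reference.

Scoring pixel methods on metric coverage needs a mapping from a bound
image pair to a metric interval; the package applies $f$ to both bound
images and orders the two values
($[\min, \max]$), because a metric need not be monotone in intensity —
a windowed fat count can be *larger* on the pixel-wise lower bound — and
adjusted pixel bounds can cross.

## Evaluation protocol

`run_split_experiment()` repeats random calibration/testing splits of an
exchangeable subject pool: $\lfloor$ `cal_fraction` $\cdot N \rfloor$
subjects calibrate (rounding down; the remainder test), every method
produces intervals for the test subjects, and *test coverage* (fraction
of truths inside the closed interval) and *interval length*
($\max(0, U - L)$) are recorded. Aggregation across splits is the
arithmetic mean; per-split values are kept in the `"per_split"`
attribute. Each method's mean length is divided by the calibrated metric
method's mean length (*normalised interval length*; the reference is 1
by construction, and the ratio is reported as `NA` if the reference
length is 0). Ensembles are fixed per subject and only the split
assignment is re-randomised — reconstruction sampling is expensive in
practice, so re-drawing ensembles per split would not emulate any
realistic protocol. Per-subject ensemble quantiles and scores are
precomputed once, which is what makes hundreds of splits cheap.

## The synthetic generator

Real calibration data (reconstruction ensembles from a trained
generative model plus ground-truth scans) cannot ship with a package, so
`generate_metric_pool()` emulates its essential statistics: per-subject
truths $Y_i \sim N(\mu, \sigma_{pop}^2)$ (a scaled-$t$ option stresses
heavy tails) and samples
$\hat Y_{i,j} = Y_i + \text{bias} + \text{dispersion} \cdot
\varepsilon_{i,j}$ with Gaussian noise, plus optional outlier
displacement of $\pm$ `outlier_scale` $\cdot$ `noise_sd` at rate
`outlier_rate`. Subjects are i.i.d., hence exchangeable — the one
property conformal validity actually needs. The defaults
($N = 250$ subjects, $n_s = 100$ samples, truths $N(100, 15^2)$, bias
$7.5 = 1.5\times$ `noise_sd`, dispersion $1.5$) describe a noticeably
miscalibrated pipeline: biased upward and over-dispersed, the regime in
which calibration visibly matters while raw quantile intervals still
often cover. Doubling the bias to $3\times$ `noise_sd` is the regime
where the uncalibrated baseline collapses; the test suite exercises
both.

What the generator does **not** emulate: spatial artifact structure,
metric-dependent noise, distribution shift between calibration and test
(exchangeability is built in, not checked), or discreteness beyond count
rounding. Passing tests therefore show that the *procedure* is correct
and its guarantee holds under exchangeability — not that any particular
real reconstruction pipeline is exchangeable.

For the image pipeline, `generate_phantom_pool()` builds CT-like
phantoms with fat content known *by construction*: fat pixels at
$-100$ HU (the centre of the adipose window $[-150, -50]$ HU) on a
0 HU water background, filled in order of distance from the image
centre so any count gives a roughly circular, nested blob. The truth
image's `fat_volume()` is exactly `fat_region_pixels * slice_thickness`,
and each "reconstruction" perturbs the count with the scalar bias/noise
law ($+60$ pixels bias, SD 40 by default, $64\times64$ images,
$n_s = 20$, thickness 3 mm), so phantom-derived metric pools follow the
scalar generator's law up to rounding — a correspondence the tests check
at two-sample scale.

## Numerical and reproducibility choices

* All randomness flows through an explicit `seed` argument; generators
  and the split experiment save and restore the caller's RNG state, so
  results are pure functions of (arguments, seed) and never perturb the
  session.
* The fat window and all interval memberships are closed; window
  endpoints count as fat.
* `fat_volume()` defaults to `pixel_area = 1` (the bare
  pixels-times-thickness definition); pass the physical in-plane
  spacing for mm³.
* Adjustment files record the MD5 hash of the calibration table;
  `read_adjustments()` warns when predictions are about to be made with
  adjustments calibrated on different data.
* Simulation sizes in the shipped tests and acceptance script — 250
  subjects / 500 splits for the scalar study, 100 phantoms
  ($64\times64$) / 200 splits for the image study — were chosen so the
  Monte-Carlo error of mean coverage is well below 0.01 while a full
  run stays in the seconds-to-minutes range on a single core.

## Worked example

```{r}
pool <- generate_metric_pool(n_subjects = 100, ns = 50, seed = 1)
fit <- metric_cp(pool, alpha_lo = 0.05, alpha_hi = 0.05)
fit

test <- generate_metric_pool(n_subjects = 1, ns = 50, seed = 2)
iv <- predict(fit, newdata = test$ensembles[[1]])
iv
retrieval_report(test$ensembles[[1]], iv)
```

Repeated-split evaluation of the calibrated method against the
uncalibrated baseline:

```{r}
run_split_experiment(pool, methods = c("metric_cp", "metric"),
                     n_splits = 200, seed = 3)
```

## Known limitations

* Coverage is **marginal**, averaged over subjects and calibration
  draws — not conditional per subgroup or per subject.
* One metric at a time; simultaneous multi-metric bounds are out of
  scope.
* Bound-image retrieval is only informative when the ensemble contains
  members with metrics near the bounds; with few samples or a heavily
  biased ensemble the nearest neighbour can be far from the bound.
* The floor-based level adjustment leaves two-sided coverage slightly
  below $1 - \alpha_{lo} - \alpha_{hi}$ at moderate $n$ (see above).
* Pixel CP is one member of a family of pixel-wise calibration schemes;
  conclusions about "pixel methods" from the included baseline apply to
  the per-pixel independent variant.
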