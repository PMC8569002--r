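---
title: "Quantifying a surgical learning curve with CUSUM charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a surgical learning curve with CUSUM charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cusumcurve)
```

## The problem

When a surgeon adopts a demanding procedure — here the motivating setting is
reverse shoulder arthroplasty for complex proximal humerus fractures, where
the tuberosities must be reattached to the prosthesis — early cases tend to
have worse functional outcomes, longer operation times and more
complications than later ones. Two complementary questions arise from a
chronologically ordered case series: *do outcomes improve with experience*,
and *after how many cases does performance stabilize at an acceptable
level*? `cusumcurve` answers both with the cumulative summation (CUSUM)
methodology used for sequential performance monitoring, combined with simple
linear trend fits, and ships a synthetic-cohort simulator so every step can
be validated against a known ground truth.

## The CUSUM model

For a continuous outcome $x_1, x_2, \dots$ (in chronological case order) and
a predefined target level $T$, the chart accumulates

$$S_0 = 0, \qquad S_k = S_{k-1} + d\,(x_k - T),$$

where $d = +1$ when higher values are better (shoulder scores, range of
motion) and $d = -1$ when lower values are better (operation time). The
increment is $+|x_k - T|$ when the case beat the target, $-|x_k - T|$ when
it fell short, and $0$ on a tie, so the chart falls while the surgeon
performs below target and rises once performance exceeds it. We draw the
unbounded chart: no decision limits, holding barriers or resets, and no
burn-in cases are discarded. All $n$ cases contribute; a case missing one
metric is dropped from that metric's series only, and the surviving cases
are renumbered consecutively so that the CUSUM x-axis and the trend
regressor stay aligned.

For binary complication events the chart compares each case against a
reference complication probability $p_0$ (default 0.20): a
complication-free case adds $+p_0$, a case with at least one attributable
complication adds $-(1 - p_0)$. These magnitudes make the chart exactly
drift-free when events truly occur at rate $p_0$ — the expected increment is
$(1-p_0)p_0 - p_0(1-p_0) = 0$ — while preserving the down-is-worse reading
of the continuous charts. The closed form
$S_n = p_0\,n_{\text{no event}} - (1-p_0)\,n_{\text{event}}$ is the oracle
the test suite checks against. Other step conventions (e.g. $\pm 1$) differ
from this one only by an affine transform of the vertical axis; every shape
feature the analysis extracts (trough position, plateau) is invariant to
that choice up to scaling of the plateau tolerance.

### Target levels

Targets are predefined per metric, not fitted. The shipped ledger uses
literature-based levels for the patient-reported scores (Oxford Shoulder
Score 34.5 of 48; Constant Shoulder Score 50 of 100) and
activities-of-daily-living levels for range of motion in an elderly
population (forward flexion 105°, extension 40°, abduction 90°, external
rotation 15°, all higher-better). Operation time has no natural external
standard, so it is charted against the cohort's own arithmetic mean
(`source: cohort_mean`, resolved from the data at analysis time and never
read from the config file); this measures consistency relative to the
surgeon's average rather than against an external benchmark. All targets can
be overridden from a YAML/JSON config.

## Phase segmentation

Visually, a learning curve is read off a CUSUM chart in three phases: a
*learning* phase while the chart falls, a *consolidation* phase while it
recovers, and a *mastering* phase once it runs flat at a steady level.
Reading a trough "by eye" is not reproducible, so the package fixes two
explicit rules:

* **Learning end** = the position of the global minimum of
  $S_0, S_1, \dots, S_n$, the chart's trough. Ties resolve to the earliest
  position, which is the conservative choice (the shortest defensible
  learning phase). If the path never drops below its starting level
  ($S_0 = 0$ is the minimum), there is no learning phase and the learning
  end is reported as 0.
* **Mastering start** = the first position after the learning end from which
  *every* trailing window of `plateau_window` cases has mean absolute
  increment at most `plateau_tol` — the chart must flatten *for good*, so a
  temporary stall during consolidation does not count. Defaults:
  `plateau_window = 10` cases and `plateau_tol` = 25% of the series' mean
  absolute increment. Both are reported alongside the cutoffs. When the
  window is longer than the series, mastering detection is skipped with a
  warning rather than failing the run.

These rules are deterministic, so segmentation is idempotent, and they are
this package's operational definition of the phases; published analyses that
read charts visually report ranges, and the global-minimum rule will
generally land inside such ranges but is not obliged to match any one
eyeballed value. The per-metric cutoffs are pooled only by taking their
median, reported as the cohort's single-number learning length.

## Trend regression

As a complementary view, each metric is regressed on its consecutive case
position by ordinary least squares (`stats::lm`), reporting slope, intercept
and $R^2 = 1 - SSE/SST$. No inference (confidence intervals, p-values) is
attached: the fit's role is descriptive, a trend line through the scatter
plot. A constant outcome leaves $SST = 0$; such fits return $R^2 = 0$ with a
`degenerate` flag instead of `NaN` so downstream tables remain
machine-readable.

## Complication accounting

Events are classified *minor* versus *major* by a declarative rule: an event
is major when it required considerable revision surgery, long-term
medication (e.g. long-term antibiotics), or compromised the surgical
outcome; events annotated on none of the criteria come back `unclassified`
for manual review rather than defaulting to minor. Rates are counted over
*patients*, not events (a patient with two minor events contributes once),
as percentages of the cohort size. Events marked non-attributable — the
canonical example being a post-operative fall — are excluded from every rate
and from the binary CUSUM. The packaged example log encodes a published
50-case cohort's complication table: 6 patients with minor and 3 with major
attributable complications (12% and 6%), i.e. an 18% tabulated patient rate,
while the binary chart's reference probability stays at the separately
stated $p_0 = 0.20$; the report flags this divergence rather than silently
reconciling it. The case indices in that file are synthetic, because the
source table does not say which case each event belongs to.

## The synthetic cohort generator

Because patient-level data of this kind are generally not shareable, the
generator is a first-class module: it produces cohorts with exactly the
structure the analysis assumes, with known ground truth. Learning is modeled
as a smooth exponential approach to an asymptote. For metric value at case
$k$:

$$\mu_k = a + (s - a)\,e^{-(k-1)/\tau}, \qquad
  \sigma_k = \sigma_\infty + (\sigma_1 - \sigma_\infty)\,e^{-(k-1)/\tau},$$

with a Gaussian draw $x_k \sim N(\mu_k, \sigma_k^2)$ clipped to the metric's
valid range, and the complication probability decays the same way,
$p_k = p_\infty + (p_1 - p_\infty)e^{-(k-1)/\tau_p}$, feeding a Bernoulli
draw per case. The exponential family was chosen over piecewise-linear
alternatives because it has a closed-form *crossing case*

$$k^\ast = 1 + \left\lceil \tau \,
  \ln\frac{|s - a|}{|T - a|} \right\rceil,$$

the first case whose expected performance is on the better side of the
target — a clean ground truth for validating the trough rule. The decaying
$\sigma_k$ implements, as a testable mechanism, the clinical observation
that outcomes become less variable with experience.

Determinism: each cohort is drawn under a single seed set once per call
(`withr::with_seed`, so the caller's RNG stream is untouched), with a fixed
draw order — one `rnorm` vector per metric in registry order, then one
`runif` vector for complications. Identical parameters and seed give a
bit-identical cohort; cross-implementation bit-compatibility is not
promised. Clipping is plain truncation at the range bounds rather than
resampling — simpler, and under the shipped calibration it alters well under
1% of draws (asserted in the suite), so it cannot meaningfully distort the
calibration.

### Shipped calibration

`frsa_learning_params()` is a 50-case parameter set whose coarse features
echo a published fracture-arthroplasty cohort: asymptotes near the reported
cohort medians (OSS 38, CSS 62, flexion 120 — slightly above the median,
since the median averages over the learning phase; operation time decaying
from 170 toward 115 minutes, giving a cohort mean near 130), start levels on
the wrong side of each target, time constants chosen so the noiseless mean
crosses its target near case 20, noise dispersions on the order of the
reported interquartile ranges and shrinking with experience, and a
complication probability decaying from 0.45 to 0.12 ($\tau_p = 10$), about
20% on average over 50 cases. This is a calibration for simulation studies —
nothing in it reconstructs real patients, and no validation result depends
on matching any published patient-level number.

## What the simulation studies show — and what they cannot

The validation suite exercises the pipeline at the study's natural problem
sizes: 50-case cohorts, 200 replicates for recovery experiments, $10^5$
events for the drift check, 1,000 random series for the CUSUM oracle. Two
results matter most:

* **Cutoff recovery.** With the generator's time constant set so the true
  crossing case is 10, 20 or 30, the trough rule's learning end over 200
  noisy replicates has its median at (or within a case or two of) the truth.
  So when real data have the assumed exponential-learning structure with
  roughly these noise levels, the reported cutoff is an essentially unbiased
  estimate of the target-crossing case — though with a per-cohort spread of
  several cases (IQR on the order of ±5 at default noise).
* **No hallucinated cutoff.** On stationary cohorts already at target, the
  trough position is close to the arcsine law of a driftless random walk:
  spread across the whole series, concentrated on no single value. The rule
  finds a learning phase when there is one, but it always reports *some*
  trough position; the companion null distribution is the reason the package
  reports the cutoff per metric and summarizes across metrics by the median
  rather than treating any single chart's trough as proof of learning.

Passing these simulations does **not** show that real cohorts follow an
exponential learning model, that outcomes are Gaussian, that complications
are independent across cases, or that case-mix is stable over time — the
generator deliberately omits case-mix covariates (fracture type, ASA class)
and serial correlation. Conclusions about a real series still rest on the
plausibility of its targets and on inspecting its charts.

## Numerical and degenerate-input choices

* Quartiles in descriptive summaries use linear interpolation between order
  statistics (`type = 7`, R's default); the estimator is configurable
  because statistical packages disagree slightly at these sample sizes.
* Ties with the target contribute a zero increment — forced by the
  better/worse dichotomy.
* The trough rule includes the implicit $S_0 = 0$, which is what makes
  "no learning phase" (`learning_end = 0`) well-defined on charts that rise
  from case 1.
* All-missing metrics are flagged absent (`n = 0`, `NA` summaries), never
  imputed or reported as zero; duplicate or non-contiguous case indices are
  hard errors naming the offending case.
* CSV dialect is fixed: comma separator, decimal point, UTF-8, header row.

## Limitations

* The binary CUSUM is not risk-adjusted: $p_0$ is one number for the whole
  series, so a drifting case-mix masquerades as a learning (or unlearning)
  signal.
* No formal changepoint inference is attached to the cutoffs — the trough
  and plateau rules are descriptive formalizations of a visual reading, with
  no control of the probability that a driftless chart shows a trough.
* Segmentation of very short series (shorter than the plateau window) skips
  mastering detection entirely.
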