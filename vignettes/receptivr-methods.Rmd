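---
title: "Hour-resolution endometrial receptivity testing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hour-resolution endometrial receptivity testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptivr)
```

## The problem

In hormone-replacement (HRT) frozen embryo transfer cycles, blastocysts are
conventionally transferred five days after the first progesterone
administration (P+5 = 120 h), on the assumption that the endometrium is then
inside its window of implantation (WOI). In a substantial fraction of
patients with repeated implantation failure (RIF) the WOI is displaced —
typically delayed — so a transfer at the standard time meets a pre-receptive
endometrium. RNA-seq-based endometrial receptivity testing (rsERT) estimates
each patient's WOI position from the transcriptome of a single endometrial
biopsy, with hourly rather than half-day resolution, so that the next
transfer can be rescheduled to the individual optimum (personalized embryo
transfer, pET).

`receptivr` implements that analysis end to end on simulated cohorts: a
synthetic-data generator with known ground truth, hour-offset label
construction, marker-gene ranking, a bagged regression-tree ensemble with
infinitesimal-jackknife standard errors, clinical receptivity reporting,
injection/transfer scheduling, and the 2×2 outcome statistics used to
compare personalized against standard-timing transfers.

## Hour-offset labels

Training data come from cycles whose embryo transfer produced an
intrauterine pregnancy: if a biopsy was taken at time $t_s$ and the
successful transfer happened at $t_x$ (both in hours after the first
progesterone administration), the biopsy's offset from the WOI is
$t_x - t_s$. Positive offsets mean the tissue was sampled before its window
(pre-receptive), negative offsets after it (post-receptive). Historical
training sets sampled each patient at P+3, P+5 and P+7, 48 h apart, so
offsets live naturally on the grid
$\{0, \pm 24, \pm 48, \pm 72, \pm 96\}$ h and any consistent triplet of
phase calls maps to grid labels decreasing by exactly 48 across the three
biopsies:

```{r labels}
label_from_outcome(c(72, 120, 168), successful_transfer_time = 96)
enumerate_label_combinations(c("pre-receptive", "post-receptive",
                               "post-receptive"))
```

Numerical choices. Raw offsets are snapped to the nearest grid point; exact
midpoints (e.g. +12 or +36) resolve toward the smaller-magnitude label, so
a biopsy equally distant from "receptive" and "one day early" is not pushed
outward. Offsets beyond ±108 h are rejected rather than clamped, because the
grid ends at ±96 and clamping would fabricate a label four days away from
the evidence. The receptive phase is called for offsets within a half-width
of 12 h — half the 24 h grid step; an example case with a +19 h displacement
must be non-receptive, so the half-width has to be below 19, and half the
grid step is the natural choice. The half-width is configurable and shared
between labeling and reporting so that the label geometry and the clinical
call never disagree.

## Synthetic cohorts

The generator (`cohort_config()`, `generate_cohort()`, `sample_biopsies()`)
emulates the statistical structure the estimator relies on, with known
ground truth per patient:

* Each patient is receptive (WOI centered at the 120 h reference) with
  probability 0.391, matching the observed receptive fraction in rsERT
  cohorts of RIF patients; otherwise the WOI is delayed by a uniform
  13–96 h. Delay-only displacement is the default because observed
  displacements in this population were exclusively delays; a
  signed-displacement switch exists for generality. The lower bound 13 h
  keeps displaced patients strictly outside the 12 h receptive half-width;
  the upper bound 96 h is the label-grid edge.
* Marker gene $g$ has mean log2 abundance
  $b_g + a_g f_g\!\big((t - \tau_i)/w_g\big)$ at sampling time $t$ for a
  patient with WOI center $\tau_i$; the shape $f_g$ is a Gaussian bump or a
  logistic switch (the minimal pair producing both peaked and monotone
  receptivity markers), with per-gene baseline, amplitude (either sign) and
  width (18–48 h) drawn once per cohort. Background genes are
  time-constant. Expression profiles therefore depend on time only through
  $t - \tau_i$: two patients differ exactly by a time shift equal to their
  displacement difference, which is the property the hour-offset regressor
  exploits. i.i.d. Gaussian noise (default SD 0.25 log2 units) is added; a
  negative-binomial count mode with the same mean structure is available.
* Transfer outcomes: a transfer at time $t_x$ yields a clinical pregnancy
  with probability $p_{\max} \exp(-(\Delta/s)^2)$, where
  $\Delta = t_x - \tau_i$, $p_{\max} = 0.55$ (the clinical pregnancy rate
  observed under rsERT-guided, i.e. approximately aligned, transfers) and
  $s = 36$ h. Among hCG-positive cycles a fraction 0.15 end as biochemical
  pregnancies; flags nest (clinical ⇒ hCG-positive; biochemical ⇒
  hCG-positive and not clinical). The 36 h decay scale is a calibration
  constant, not an estimate from data: it makes badly mistimed transfers
  rare successes while leaving ±12 h misalignments mild. Under the default
  delay distribution it yields a standard-timing clinical rate of roughly
  0.29 — somewhat below the ~0.39 reported for standard-FET comparison
  groups — which we accept rather than tune, since the generator's role is
  to exercise the estimator, not to impersonate any particular cohort.

What the generator does not emulate: sequencing-depth and library-size
effects, gene–gene correlation beyond the shared WOI dependence,
between-patient amplitude heterogeneity, cycle-type covariates, or
measurement batch structure. Passing tests therefore demonstrate that the
pipeline recovers the truth under its own model assumptions, not that it
would achieve the same accuracy on real biopsies.

## Marker ranking

The deposited marker panels behind published receptivity tests are not
public, so the package ranks genes itself: each gene is scored by its
one-way ANOVA F statistic across the discrete label groups and the top
k = 175 are kept — the published panel size. A grouped F test is used
rather than correlation with the continuous label because training labels
live on a 9-point grid. Recovering any particular published gene list is
explicitly not a goal.

## The hour-offset forest

The core estimator (`woi_forest()`) is a bagged ensemble of regression
trees predicting the signed hour offset from marker expression:

* B = 1000 trees by default, each grown on a bootstrap resample (n draws
  with replacement); `mtry` = ⌈p/3⌉ candidate features per split;
  minimum node size 5; unlimited depth. These are standard
  regression-forest defaults; the cross-validation grid search
  (`cv_forest()`) is the sanctioned mechanism for choosing anything else.
* Splits maximize the sum-of-squares reduction; ties resolve
  deterministically to the lowest feature index, then the lowest
  threshold, so a fixed seed reproduces the forest bit for bit.
* The bootstrap membership count $N_{ib}$ of every training sample in
  every tree is retained. Out-of-bag (OOB) predictions average a sample's
  per-tree predictions over the trees where $N_{ib} = 0$.
* Cross-validation folds partition patients, not samples: a three-point
  training patient contributes correlated biopsies, and splitting them
  across folds would leak. Held-out R² is computed per fold as
  $1 - SS_{res}/SS_{tot}$, and the setting with the best mean R² wins.

### Prediction uncertainty

For a test point $x$ with per-tree predictions $t_b(x)$, the infinitesimal
jackknife variance estimate is

$$\widehat V_{IJ}(x) \;=\; \sum_{i=1}^{n}
  \mathrm{Cov}_b\!\big(N_{ib},\, t_b(x)\big)^2 ,$$

with the finite-B Monte-Carlo bias removed by subtracting
$(n/B^2) \sum_b (t_b - \bar t)^2$, flooring at zero. A
jackknife-after-bootstrap variant built from out-of-bag tree means is
available behind a flag; the clinical-precedent description ("standard
errors based on the out-of-bag predictions") is ambiguous between the two,
and the corrected IJ estimator is the better-studied default.

Individual corrected estimates are noisy and right-skewed when B is not
large relative to n. Reference implementations of this estimator therefore
calibrate: `ij_variance(calibrate = )` measures the Monte-Carlo noise of
the estimates by recomputing them on a deterministic half of the trees and
shrinks the raw values toward their cross-point mean with the normal-normal
posterior factor $\tau^2/(\tau^2 + \sigma^2)$. Calibration engages
automatically for batches of more than 20 test points; for smaller batches
the cross-point moments are not estimable and raw values are returned. In
replicate-cohort experiments at n = 300 patients and B = 2000 trees
(the sizes used by the package's own tests), calibrated ±1.96·SE intervals
cover the expected prediction for ~92% of draws, versus ~75% uncalibrated.

## Clinical report and scheduling

A single P+5 biopsy yields a predicted offset; the receptivity report
places the optimal WOI at `sampling_time + offset`, the displacement
relative to the 120 h reference, and the phase call:

```{r report}
report_receptivity(19, sampling_time = 120)
```

Scheduling holds the clinic's transfer hour fixed and floats the first
progesterone injection: for an optimal elapsed time $E$ and transfer clock
hour $c$, the injection is given at $(c - E) \bmod 24$ on day 0 and the
transfer lands on day $\lfloor\cdot\rfloor$ at exactly $E$ hours elapsed.
The fixed-transfer-hour rule is inferred from clinical practice (the
transfer stays at 15:00; the injection moves); both clocks are exposed.

```{r plan}
plan_transfer("5d19h", transfer_clock = 15)
```

## Outcome statistics

Outcome comparisons use the classical 2×2 machinery, implemented directly:
odds ratio $ad/bc$ with Haldane–Anscombe 0.5 correction only when a zero
cell occurs; Woolf (log-OR Wald) 95% CI
$\exp(\ln OR \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$; Pearson chi-square
without continuity correction by default (the convention that reproduces
published headline p-values; Yates is available behind a flag); and
covariate-adjusted odds ratios from a self-contained iteratively
reweighted least-squares logistic regression (Newton–Raphson, convergence
at 1e-8, separation detected and raised as an error). Biochemical-pregnancy
comparisons are conditioned on positive hCG — their denominator is the
hCG-positive count — matching how such tables are printed. Percentages
round half-up, the presentation convention of clinical tables.

```{r outcomes}
outcome_table(list(n = 115, hcg = 73, biochemical = 10, clinical = 63),
              list(n = 272, hcg = 140, biochemical = 35, clinical = 105))
```

Adjusted odds ratios on real cohorts cannot be reproduced here because
individual-level covariates are not published; the adjusted path is
validated against `glm()` and by parameter recovery on synthetic records.

## Pipeline, determinism and problem sizes

`run_pipeline()` wires the stages — simulate, label, rank markers, train,
report, schedule, evaluate — writing every artifact as plain text
(TSV/CSV/JSON) plus a manifest with the seed, a configuration content hash
and per-file MD5 sums; a rerun with the same configuration is bit-identical.
One cohort provides the training and evaluation arms so that both share
gene-level parameters (the same "assay"), with disjoint patients.

The package's own test suite exercises the estimator at n = 300 training
patients (with B = 1000–2000 trees, p = 175 markers for recovery and a
60-gene assay for the replicated coverage experiment) and the pipeline at a
few dozen patients — sizes chosen to characterize the methods well while
keeping a full check run in minutes on a single core.

## Known limitations

* The generator's expression model is deliberately minimal; see above for
  the real-data features it omits.
* Training labels assume one pregnancy-confirmed cycle per patient;
  unsuccessful transfers contribute no label and multiple successful
  cycles are out of scope.
* The receptive half-width, the delay distribution, and the outcome decay
  scale are stand-ins where published sources are silent; all are
  configurable.
* The IJ calibration requires a batch of test points; single-biopsy SEs
  are reported uncalibrated.
* No narrow-WOI (window-duration) estimation is attempted; the package
  reports the window's position only.
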