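# receptivr

Hour-resolution endometrial receptivity testing and personalized embryo
transfer (pET) scheduling.

In hormone-replacement frozen embryo transfer (FET) cycles, blastocysts are
conventionally transferred five days after the first progesterone
administration (P+5 = 120 h). Many patients with repeated implantation
failure (RIF) have a *displaced* window of implantation (WOI), so the
standard-time transfer meets a non-receptive endometrium. RNA-seq-based
endometrial receptivity testing (rsERT) estimates each patient's WOI
position from a single endometrial biopsy with hourly resolution, and the
next transfer is rescheduled to the individual optimum.

`receptivr` implements that analysis as a tested pipeline on simulated
cohorts with known ground truth:

* **Synthetic cohorts** — patients are receptive with probability 0.391 or
  have a uniformly distributed 13–96 h WOI delay; marker genes follow
  Gaussian-bump or logistic-switch trajectories in time relative to each
  patient's WOI center; transfer outcomes decay with misalignment as
  `p_max · exp(−(Δ/36 h)²)`.
* **Hour-offset labels** — for a pregnancy-confirmed cycle, a biopsy at
  `t_s` with transfer at `t_x` gets the signed label `t_x − t_s`, snapped
  to the grid {0, ±24, ±48, ±72, ±96} h (positive = pre-receptive).
* **Marker ranking** — per-gene one-way ANOVA F across label groups, top
  175 kept.
* **Hour-offset forest** — bagged regression trees (B = 1000, mtry = ⌈p/3⌉)
  with recorded bootstrap membership counts `N[i,b]`, out-of-bag
  predictions, patient-grouped 10-fold cross-validation, and
  infinitesimal-jackknife standard errors
  `V̂ = Σᵢ Cov_b(N[i,b], t_b(x))² − (n/B²) Σ_b (t_b − t̄)²`,
  with empirical-Bayes calibration across prediction batches.
* **Clinical report & scheduler** — phase call
  (pre-receptive / receptive / post-receptive, half-width 12 h), predicted
  optimal WOI, and a transfer plan that holds the clinic's transfer hour
  fixed while the first progesterone injection floats:
  `injection_clock = (transfer_clock − optimal_elapsed) mod 24`.
* **Outcome statistics** — 2×2 tables, odds ratios with Woolf 95% CIs
  `exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))`, Pearson chi-square (no
  continuity correction by default), and covariate-adjusted ORs from a
  self-contained IRLS logistic regression.

## Worked example

```r
library(receptivr)

cfg <- cohort_config(n_patients = 150, n_genes = 1000, n_markers = 100,
                     noise_sd = 0.2, seed = 101)
run <- run_pipeline(tempfile("run"), config = cfg, n_test = 100,
                    n_markers = 100, hp = list(n_trees = 300L), seed = 101)
print(run)
#> rsERT pipeline run
#>   receptive 39.0% / delayed 61.0% / advanced 0.0%
#>   outcome comparison (personalized vs standard timing):
#>                outcome        exposed      unexposed odds_ratio  p_value
#>           Positive hCG 62/100 (62.0%) 77/200 (38.5%)      2.606 0.000119
#>  Biochemical pregnancy   9/62 (14.5%)  14/77 (18.2%)      0.764 0.563189
#>     Clinical pregnancy 53/100 (53.0%) 63/200 (31.5%)      2.452 0.000312
```

The pipeline simulated a cohort in which 39% of patients were truly
receptive, trained the hour-offset forest on pregnancy-confirmed
three-point biopsies, and recovered that fraction on held-out patients from
a single P+5 biopsy each. Transfers timed to each patient's predicted
optimum roughly double the clinical pregnancy odds relative to fixed P+5
timing in this simulation (53.0% vs 31.5%).

A single patient's report and schedule:

```r
report_receptivity(19, sampling_time = 120)
#> Endometrial receptivity report
#>   biopsy at 5 d 0 h after first progesterone administration
#>   phase: pre-receptive (WOI delayed)
#>   predicted optimal WOI: 5 d 19 h (displacement +19 h)

plan_transfer("5d19h")
#> Personalized embryo-transfer plan
#>   optimal WOI elapsed time: 5 d 19 h
#>   first progesterone injection: 20:00 on day 0
#>   embryo transfer: 15:00 on day 6
```

A biopsy at P+5 predicted +19 h to the window's center: the WOI is delayed,
and the optimum falls 5 days 19 h after the first injection. Keeping the
transfer at 15:00, the injection moves from 15:00 to 20:00 and the transfer
lands on day 6 — the transfer then happens exactly 139 elapsed hours after
the first injection.

Outcome tables from printed counts:

```r
effect_estimate(make_table(63, 115, 105, 272))
#> OR 1.93 (95% CI 1.24-2.99), chi-square 8.61, P = 0.003
```

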