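---
title: "Strain-volume and strain-area loop analysis: models, parameters and reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-volume and strain-area loop analysis: models, parameters and reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainloops)
```

## The loop model

Speckle-tracking echocardiography yields, for one R-wave gated cardiac
cycle, a per-frame longitudinal strain curve (%, negative during
shortening) together with the instantaneous cavity size: volume (mL) for
the left ventricle, area (cm²) for the right ventricle. Plotting strain
against size over the cycle traces a closed loop — the LV strain–volume
loop (SVL) or RV strain–area loop (SAL) — whose shape captures the dynamic
coupling between deformation and loading rather than a single static
index.

`strainloops` splits the cycle at the end-systolic frame (the global size
minimum; end-diastole is frame 1 by the R-wave gating convention) and
interpolates both limbs onto a common grid of 101 uniformly spaced
*absolute* size values spanning `[ESV, EDV]`. Absolute rather than
%EDV-normalized size is used because the systolic slope is reported in
%/mL and %/cm², which implies an absolute abscissa. Within a limb,
non-monotonic size runs are resolved by sorting the limb by size and
averaging strain at duplicate sizes — this preserves the mean limb shape
without introducing smoothing assumptions. The two limbs share the
end-systolic point by construction.

Ten scalar parameters are extracted per loop:

| parameter | definition | units |
|---|---|---|
| `ss` | OLS slope of strain on size over systolic frames (ED..ES) | %/mL, %/cm² |
| `ess` | same, over frames within the first 5% of the EDV→ESV excursion | %/mL, %/cm² |
| `ps` | most negative strain of the cycle | % |
| `eds`, `lds` | OLS slope of the diastolic limb over the lower / upper half of the grid | %/mL, %/cm² |
| `early_u`, `late_u` | mean limb difference (diastolic − systolic) over the lower / upper grid half | % |
| `total_u` | grid-wide mean limb difference | % |
| `loop_area` | absolute shoelace area of the per-frame polygon | %·mL, %·cm² |
| `ps_ed_ratio` | `ps` / end-diastolic size | %/mL, %/cm² |

Design choices where the literature leaves latitude, and why:

* **SS by regression, not the ED–ES chord.** OLS over all systolic frames
  is the standard choice in the loop literature and is robust to endpoint
  noise.
* **Early/late diastole split at 50% of the size excursion**, not at a
  detected diastasis: deterministic and data-independent. (A
  diastasis-based split would inherit the diastasis detector's noise.)
* **`ess` window of 5%** of the excursion, widened to the three earliest
  systolic frames (and flagged) when fewer qualify; the window size is not
  standardized in the field, so it is a configurable argument.
* **`total_u` is the grid-wide mean** of the limb difference, hence equal
  to the average of `early_u` and `late_u` when the two halves contain
  equally many grid points.
* **Uncoupling sign:** diastolic minus systolic, so a diastolic limb lying
  above (less negative than) the systolic limb is positive.
* **Drift correction is off by default**; `dedrift = TRUE` subtracts a
  linear ramp removing the end-of-cycle strain residual before the limbs
  are split.
* **LV view averaging:** each apical view is resampled by linear
  interpolation onto 201 uniform points of normalized cycle time, strain
  and volume are averaged pointwise, and ES is re-detected on the averaged
  volume curve. Whether one should instead align views on ES before
  averaging is not settled; the normalized-time average is this package's
  normative choice and is what the matched-view invariance tests exercise.

## The synthetic cohort

Real per-frame echo exports are rarely shareable, so the package carries a
generator that emulates a healthy-adult reliability study: `n = 29`
subjects, heart rate 58 (SD 8) bpm, frame rate 58 Hz (≥ 50 Hz), and loop
parameters centred on published healthy medians (LV systolic slope
0.27 %/mL with peak strain −18.4 %; RV systolic slope 2.42 %/cm² with peak
strain −22.5 %, early uncoupling 2.78 %, late uncoupling 1.29 %).
Between-subject SDs are approximations derived from printed interquartile
ranges via IQR/1.35 and should be treated as such.

One cycle of cavity size is a piecewise half-cosine: ejection EDV→ESV on
`[0, t_es]` (default `t_es = 0.35`), early filling to
`ESV + f_df·(EDV−ESV)` (default `f_df = 0.75`) until `t_df = 0.55`, a
diastasis plateau until `t_af = 0.80`, and atrial filling back to EDV.
This morphology is an idealization chosen for smoothness and analytic
landmark control; it reproduces the qualitative shape of published mean
loops but is not fitted to any measured curve. Strain is linearly coupled
to size, `ε(t) = s·(V(t) − EDV)` with `s = −PS/(EDV−ESV)`, plus diastolic
uncoupling offsets: `u_early` while less than half of the refill volume
has returned, `u_late` afterwards. With the default `taper = 0.05`
(fraction of the diastolic duration) the offset ramps up after
end-systole, crossfades between the two levels around the half-refill
time, and ramps out at the cycle end so strain is continuous and returns
to zero; `taper = 0` gives hard indicator windows for analytic tests.

Because the tapers and the shared end-systolic grid point attenuate the
*extracted* uncoupling relative to the generator offsets (the shared ES
point alone forces the limb difference to zero there, diluting the
early-half mean by a factor 50/51 on the default grid), `generate_cohort`
computes the 2×2 attenuation matrix of the extraction pipeline on the
population-mean subject once per chamber and inverts it when drawing
subjects, so that the *measured* cohort medians — not the internal
offsets — match the configured population means.

### The hierarchical error model

Each subject is measured in exactly the four arms of the reliability
design: baseline (scan 1, observer 1, analysis 1), intra-observer repeat
(scan 1, observer 1, analysis 2), inter-observer (scan 1, observer 2,
analysis 1) and test–retest (scan 2, observer 1, analysis 1). Three error
sources act at different levels, mirroring how variability arises
mechanistically:

* **Re-analysis noise** (`sigma2_analysis`, default 0.5² %²): smooth
  low-frequency strain noise — the first three half-cycle sine harmonics
  with random amplitudes — added independently per analysis cell and per
  LV view. Frame-level white noise would be unrealistic because any
  tracking algorithm suppresses it; the sine basis also vanishes at the
  cycle ends, preserving the gated `ε(0) = 0`. Averaging three LV views
  shrinks this component by √3, which is one mechanistic reason LV
  parameters come out more reliable than RV ones.
* **Observer bias** (`sigma2_observer`, default 0.06² on the log scale): a
  multiplicative strain-scale factor per (subject, observer) — tracing
  differences rescale the strain amplitude. It cancels within an observer
  (intra design) but not between observers.
* **Between-scan variation** (`sigma2_scan`, default 0.12² relative):
  scan 2 re-draws relative perturbations of EDV, systolic excursion and
  peak strain — acquisition plus short-term physiology. Heart rate gets
  its own between-scan jitter (`sigma_hr`, default 8.5%, which puts about
  a quarter of subjects beyond the 10% heart-rate sensitivity filter).

The three scales live in different units (strain %, log-scale,
relative), so the intra < inter < retest "nesting" refers to their effect
on the loop parameters, not to the raw numbers. The defaults were chosen
once, from the variance algebra, to target systolic-slope ICCs of roughly
0.95 / 0.88 / 0.72 for the three designs — a clearly separated version of
the published ordering (intra-observer highest, test–retest lowest) —
so that the ordering is reproduced in well over 90% of seeded cohorts.

What the generator does *not* emulate: image-quality heterogeneity,
tracking dropouts, arrhythmic or premature beats, view foreshortening,
and any nonlinearity of the true strain–volume relation. Passing the
simulation-based tests therefore demonstrates that the *pipeline* is
correct and that the statistics recover known ground truth — not that the
package has been validated against measured echocardiograms.

## The reliability battery

For each chamber × parameter × design, `run_study()` computes:

* **ICC(A,1)** — the single-rater, absolute-agreement intraclass
  correlation from the two-way ANOVA mean squares,
  `(MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE))`.
  The two-way *mixed* label is used for intra-observer and test–retest
  designs and the two-way *random* label for the inter-observer design;
  the computational formula is identical (as in standard implementations)
  and the label is recorded for reporting. Confidence intervals use the
  F-based method with a Satterthwaite approximation to the denominator
  degrees of freedom; the p-value tests ICC > 0 via `F = MSR/MSE` on
  `(n−1, (n−1)(k−1))` df, one-sided. Absolute agreement penalizes constant
  rater offsets: for `rater2 = rater1 + c` the ICC is strictly below 1 and
  approaches 1 as `c → 0`. An all-equal table is reported *not
  computable* rather than 1. ICCs are classified per Koo–Li with boundary
  membership `[−∞, 0.50)` poor, `[0.50, 0.75)` moderate, `[0.75, 0.90]`
  good, `(0.90, 1]` excellent (the published band labels overlap at the
  boundaries, so the memberships above are fixed here once).
* **Bland–Altman**: bias = mean difference (comparison − baseline), limits
  of agreement `bias ± 1.96·SD` (sample SD), and a proportional-bias check
  (OLS of differences on pairwise means) in place of visual funnel
  inspection.
* **Wilcoxon signed-rank vs the baseline arm** (never between non-baseline
  arms): zero differences are dropped (classical convention; Pratt's
  zero-ranking is available behind a flag), the two-sided p is exact — the
  positive-rank-sum distribution over all sign assignments, computed by
  convolution, with ties entering through their average ranks — for up to
  25 non-zero differences, and a tie- and continuity-corrected normal
  approximation beyond that. All-zero differences are flagged and reported
  as p = 1. Significance is flagged at two-sided p < 0.05 with no
  multiplicity correction, matching the source reporting convention.

Arm medians are summarized as median and IQR with type-7 (linear
interpolation) quantiles. Two sensitivity analyses mirror the published
post-hoc checks: recomputing intra/inter ICCs on the matched-cycle subset
(ΔICC and classification changes), and recomputing test–retest ICCs after
excluding subjects with a relative heart-rate difference above 10%
between scans.

```{r}
cohort <- generate_cohort(cohort_config(seed = 1, n_subjects = 12,
                                        chambers = "LV"))
report <- run_study(cohort)
subset(report$agreement, parameter == "ss",
       select = c(design, model, n, icc, ci_low, ci_high, p, koo_li_class))
```

## Numerical choices and degenerate inputs

* End-systole is the earliest frame attaining the global size minimum; a
  minimum at the first or last frame means the trace does not span a full
  cycle and is rejected, as are cycles whose size excursion is below 1% of
  EDV.
* Grid interpolation is linear with constant extrapolation at the grid
  ends; because frames sample the half-open cycle `[0, 1)`, the diastolic
  limb ends one frame short of EDV and its top grid point carries an
  `O(1/n²)` residual — visible only in analytic tests at 1e-6 tolerances.
* Exact uncoupling recovery is impossible by construction: the limbs share
  the ES point, so the limb difference is pinned to zero at the first grid
  point and the early-half mean of a hard offset recovers at most 50/51 of
  it (≈ 98%); with the default taper the onset and crossfade ramps cost
  another ≈ 8%, which the cohort generator's attenuation calibration
  compensates at the population level.
* ICC confidence limits fall back to the exact `df → ∞` limit when the
  Satterthwaite df overflows numerical accuracy; perfect-agreement tables
  (`MSE = MSC = 0`) report a degenerate CI of `[1, 1]`.
* All simulations run from a single seeded stream per cohort, consumed in
  a fixed subject/chamber/arm order, so equal seeds give bit-identical
  cohorts, reports and figures.

## Problem sizes used in the test suite

The packaged tests run cohorts of 3–29 subjects, 2000-replicate ICC
recovery at n = 29, a 200-seed hierarchy check, and 1000-table oracle
comparisons; these sizes make every statistical check decisive at its
stated tolerance while keeping the default suite fast on a single CPU.

## Known limitations

* The generator's loop morphology and error model are stylized; absolute
  agreement with measured reliability coefficients is out of scope (the
  underlying patient data of the motivating study are not public).
* Only complete n × 2 designs are analysed; average-rater ICC forms
  (ICC(A,k)), consistency ICCs and REML-based variance-component
  estimation are intentionally not provided.
* Multi-beat exports, segmental (per-wall) loops and strain-rate
  parameters are out of scope; one trace file holds exactly one cycle.
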