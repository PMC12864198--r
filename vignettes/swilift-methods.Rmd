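---
title: "Scoring the size-weight illusion from lifting studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the size-weight illusion from lifting studies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swilift)
```

## The scientific problem

In the size-weight illusion (SWI), the smaller of two equally heavy objects
feels heavier. The illusion indexes how strongly prior expectations (larger
objects should weigh more) shape perception, which makes it a useful probe
for comparing perception between physical reality and virtual environments:
if priors carry less weight in VR, the illusion should shrink there.

`swilift` implements the full analysis chain for a two-condition
(real vs. virtual), within-participant lifting study of four cylinders
crossing two diameters (5 and 10 cm) with two masses (355 and 490 g, plus a
75 g motion tracker on every object), where each lift yields (i) an
open-scale verbal heaviness rating (absolute magnitude estimation), (ii)
90 Hz wrist and object tracker streams, and, once per participant, (iii) a
six-item presence questionnaire. Because the package must be fully testable
without access to any particular dataset, it ships a synthetic-data
generator with the same statistical structure the analysis assumes.

## The SWI score

For each participant and condition, raw ratings from the 32 test lifts are
regressed on total lifted mass $m$ (grams) and cylinder volume $v$
(cm$^3$):

$$\text{rating} = b_0 + b_W\, m + b_V\, v + \varepsilon,$$

and the score is

$$\text{SWI} = -\frac{b_V}{b_W} \quad [\text{g/cm}^3],$$

the grams of perceived weight change per cm$^3$ of volume change, signed so
that a larger score means a larger illusion. The ratio cancels any positive
rescaling of the participant's idiosyncratic rating scale, and the shift
moves only $b_0$, so the score is invariant to positive affine transforms of
the scale. In the orthogonal 2x2 stimulus design the OLS slopes equal
cell-mean difference quotients; in particular $b_W$ is identical whether
base mass (355/490) or total lifted mass (430/565) is used, because only the
135 g contrast enters a two-level slope. We use total lifted mass, since the
tracker is attached in both conditions; intercepts are therefore not
comparable with analyses that used base mass, but scores are.

Group-level rating analyses use per-participant z-scores instead of raw
ratings. Standardisation pools each participant's test trials across *both*
conditions: z-scoring within condition would remove exactly the condition
main effect under test. Washout lifts (five lifts of a medium 7.5 cm, 490 g
cylinder at the start of each block, included to stabilise expectations) are
excluded from every analysis.

Presence is scored as the number of the six questionnaire items answered 6
or 7 on the 1-7 scale, an integer in 0..6.

## Kinematic extraction

Raw positions are smoothed with a dual-pass (forward-backward, zero net
phase) Butterworth low-pass filter, cutoff 10 Hz. The per-pass order is not
fixed by convention everywhere; we use 2nd order per pass (a common
motion-analysis choice, 4th-order-equivalent magnitude response) and apply
no cutoff correction for the double pass; both are configurable. Edges are
padded by point reflection about the end samples (pad length three times
the filter order) and each pass starts from steady state at its first
padded sample, so constant signals pass through exactly and edge transients
are suppressed.

Velocity is obtained by differentiating position with respect to time
(central differences, one-sided at the edges); "speed" below is the 3-D
resultant. The reach begins at the first run of three consecutive frames
with hand speed strictly above 50 mm/s and ends at the next run of three
consecutive frames strictly below it. The lift begins where both hand and
object speed begin such above-threshold runs (the later of the two run
starts) and ends at the object's maximum vertical position at or after
onset. Maximum reach velocity (MRV) and maximum lift velocity (MLV) are the
speed maxima inside those windows, and their timing is expressed as a
percentage of the respective phase duration; argmax ties resolve to the
earliest frame. All indices are 1-based (R convention); times are in
seconds, positions mm, speeds mm/s, with velocity contrasts also reported
in m/s.

Choices worth making explicit, since verbal method descriptions rarely pin
them down: thresholding uses the 3-D resultant speed (a vertical-axis
option exists at the segmentation layer); threshold crossings are strict
inequalities; the consecutive-frame count applies to the filtered series;
reach and lift are normalised separately (the 2 s hold between them belongs
to neither phase). Trials that cannot be segmented are flagged with a
reason (`no_reach_onset`, `no_reach_offset`, `no_lift_onset`,
`apex_before_onset`, `too_few_samples`), excluded from condition means, and
counted in the report; they never raise errors.

## Statistical toolkit

* **Winsorisation.** Values more than 3.29 SD from the mean are replaced by
  the boundary `mean +/- 3.29 sd`, with mean and sample SD computed once
  from the original vector (single pass). Applied per variable within
  condition before each contrast; the winsorised count is reported.
* **Paired contrasts.** Two-tailed paired t with 95% CI and Cohen's
  $d_z = \bar d / s_d = t/\sqrt n$. Differences are first screened with a
  Shapiro-Wilk gate (alpha 0.05); when the gate rejects, the frequentist
  test is the Wilcoxon signed rank (V = sum of positive-difference ranks,
  zeros dropped, exact p for n <= 25 without ties, otherwise normal
  approximation with continuity correction). A Bayes factor from the t
  formulation is reported alongside either route.
* **Within-subjects ANOVA.** Z-scored ratings are aggregated to one cell
  mean per participant per size x weight x condition cell; each effect is
  tested against its own participant-by-effect interaction stratum, with
  partial eta squared $SS_e/(SS_e + SS_{err})$. Correctness is defined by a
  sums-of-squares decomposition oracle in the test suite, not by matching
  any particular published denominator df, since aggregation units differ
  across reports.
* **Bayes factors.** The paired-test BF10 is the default
  Jeffreys-Zellner-Siow Bayes factor: a Cauchy(0, 0.707) prior on the
  standardised effect against the point null. The Cauchy prior is handled
  through its normal/inverse-gamma mixture representation; the effect
  integrates out analytically and the remaining one-dimensional marginal
  over the relative prior variance g is evaluated by adaptive quadrature
  after the bounded substitution g = u/(1-u), which tames the heavy tail
  (relative tolerance 1e-8, tighter than the 1e-6 the results require).
  The regression BF10 uses the Zellner-Siow mixture-of-g-priors integral
  with prior scale $\sqrt2/4$ on standardised coefficients (the common
  default for a continuous covariate; configurable). Both are checked in
  the test suite against a Monte-Carlo marginal-likelihood estimate with
  10^6 prior draws.
* **Power.** `required_n_paired_t()` searches upward from n = 3 using exact
  noncentral-t power (noncentrality $d_z\sqrt n$). At $d_z = 0.7$,
  $\alpha = .05$, 90% power it returns 24, matching standard power
  software.

No multiple-testing correction is applied anywhere; every p is reported
raw. All tests are two-tailed.

## The synthetic-data generator

The generator emulates the study conditions end to end: 25 participants,
counterbalanced condition order (odd-numbered participants lift in the real
condition first), and per block 5 washout lifts followed by 32 test lifts
in one of four fixed pseudo-random orders (each object eight times, never
more than twice consecutively), assigned cyclically by participant. The
four orders are package constants so fixtures are reproducible.

**Ratings** follow the same linear model the analysis fits, with
participant-level coefficient heterogeneity and i.i.d. Gaussian trial
noise. This is a deliberate design choice over a Bayesian-observer model:
the analysis identifies only linear slopes, and the linear generative form
makes parameter recovery exact in the noise-free limit, which anchors the
whole downstream pipeline (`swi_scores()` recovers $-\beta_V/\beta_W$ to
machine precision when all noise terms are zero). Ratings are floored at
1e-6 to respect the strictly positive magnitude-estimation scale.

Default calibration, chosen once from the study's design quantities and
then left alone: with $\beta_W = 1$ (a "perceived grams" scale) the mean
volume slope is -0.20 in the real and -0.15 in the virtual condition, i.e.
mean SWI scores of 0.20 and 0.15 g/cm$^3$ and a paired difference of
0.05 g/cm$^3$. The noise terms (shared volume-slope deviation SD 0.06,
condition-specific deviation SD 0.08, mass-slope SD 0.1, trial residual SD
30) were derived analytically so the standardised paired difference is
$d_z \approx 0.42$: the target SD of the paired difference is
$0.05/0.42 = 0.119$, of which the regression measurement noise contributes
$\sqrt{2\sigma^2/S_{vv}}$ with $S_{vv} = 32\,(220.9)^2$, leaving
betaV_condition_sd $= \sqrt{(0.119^2/1.03 - 2\sigma^2/S_{vv})/2} \approx
0.08$ (the 1.03 factor accounts for the $1/\beta_W$ ratio variance). A
small caveat of specifying heterogeneity on the slope rather than on the
ratio: the mean recovered score exceeds the slope-implied 0.20 by
$\approx \beta_W$-relative variance ($\sim$1%), which the recovery tests
accommodate inside their stated tolerance.

**Tracker streams** are minimum-jerk composites: a still start, a reach of
300 mm whose displacement follows $x(\tau) = A(10\tau^3 - 15\tau^4 +
6\tau^5)$ (peak speed $1.875A/T$ at mid-movement), a grasp pause, a 100 mm
minimum-jerk lift of wrist and object together, a 2 s hold, and a
minimum-jerk replace, sampled at 90 Hz with isotropic 0.5 mm Gaussian
tracker jitter. Reach durations (0.60 s real, 0.67 s virtual) imply peak
reach speeds near 0.94 and 0.84 m/s -- the 0.10 m/s slowing reported for
virtual lifting -- while lift parameters are condition-neutral. Lognormal
tempo factors at the participant (SD 0.10), participant-by-condition
(SD 0.065, sized so the MRV contrast lands near $d_z \approx 1.2$) and
trial (SD 0.05) levels supply realistic between- and within-participant
variability.

**Presence** items come from a latent-normal model with unit-spaced
cutpoints (`round(latent + noise)` clamped to 1..7). The participant's
latent presence is linearly tied to their shared volume-slope deviation
with a positive default slope, so stronger illusions co-occur with *lower*
presence, reproducing the direction of the reported presence-SWI
relation; setting `assoc_slope = 0` decouples them.

What the generator does **not** emulate: learning or drift across trials,
trial-order effects, rating discretisation (humans say "500", not
"497.3"), skewed or heteroscedastic rating noise, hand-path curvature,
grip-specific kinematics, broken or dropped tracker frames, and any
simulator-sickness or demographic structure. Passing tests therefore
demonstrate that the pipeline correctly recovers the quantities it defines
under its assumed noise structure -- not that those assumptions hold for
any particular real dataset.

## Numerical and degenerate-input conventions

* All randomness flows from one config seed; stages draw from fixed
  sub-seeds (offsets of the master seed), so datasets are byte-identical
  across runs and stages can be regenerated independently. Simulation
  restores the caller's RNG state.
* Zero rating variance (z-scores undefined) and zero-variance paired
  differences are errors naming the participant; zero variance in
  winsorisation returns the input unchanged with a note.
* A numerically perfect regression fit reports `bf10 = Inf` rather than
  failing the quadrature.
* Filter cutoffs at or above Nyquist are configuration errors; series
  shorter than the reflection pad are rejected.
* Segmentation ties (equal speed maxima, flat object-height plateaus)
  resolve to the earliest sample.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on generated data: 200
replicates of the 25-participant design for score recovery and for the
powered contrast, 1,000 replicates for the null rejection rate of the
end-to-end SWI contrast, 1,000 random series for the segmentation
brute-force oracle, and single full pipeline runs (ratings, streams,
presence) at 25 participants. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
cfg <- swi_config(n_participants = 25, seed = 42)
report <- run_pipeline(cfg)
print(report)
report$anova
```

`run_pipeline()` simulates (or loads) the study, validates it, extracts
per-trial kinematics, computes SWI and presence scores, and runs every
comparison; `write_study()` / `read_study()` round-trip the CSV layout, and
`scripts/acceptance.R` at the repository root recomputes the headline
quantities from scratch.

## Known limitations

* The four shipped trial orders are internally generated stand-ins with the
  documented constraints, not any particular study's orders.
* The regression Bayes factor reproduces the default-prior value only up to
  the prior-scale convention and input rounding; treat third-decimal
  agreement with published values as coincidence.
* The Shapiro-Wilk gate is itself a pretest; its alpha is configurable but
  the two-stage procedure's joint error rate is not modelled.
* Kinematic segmentation assumes one reach and one lift per trial; multiple
  movement bouts will be segmented at the first qualifying runs.
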