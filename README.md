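# swilift

Analysis tools for **size-weight illusion (SWI) lifting studies** that
compare perception and movement between physical and virtual environments.

In the SWI, the smaller of two equally heavy objects feels heavier -- a
signature of the prior expectation that bigger things weigh more. Studies
probing whether this prior transfers into VR have participants lift
cylinders crossing two sizes with two masses in counterbalanced real and
virtual blocks, rate each object's heaviness on a free numerical scale,
and record wrist/object positions with 90 Hz trackers plus a six-item
presence questionnaire. `swilift` implements the full chain from those raw
measurements to the statistical comparisons, along with a synthetic-data
generator so that every stage is testable without any deposited dataset.

## The core quantities

Per participant and condition, raw heaviness ratings from the 32 test
lifts are regressed on total lifted mass (g) and cylinder volume (cm^3):

    rating = b0 + bW * mass + bV * volume + error

and the illusion is scored as

    SWI = -(1/bW) * bV        [g/cm^3]

-- grams of perceived weight change per cm^3 of volume change, signed so
larger scores mean larger illusions, and invariant to each participant's
arbitrary rating scale. Kinematics are summarised per trial by maximum
reach velocity (MRV) and maximum lift velocity (MLV) and their timing (% of
movement phase), extracted from dual-pass zero-phase 10 Hz Butterworth
smoothed, centrally differentiated trajectories segmented by a
50 mm/s x 3-consecutive-frame threshold rule. Presence is the count of the
six questionnaire items answered 6 or 7. Group comparisons use winsorised
(3.29 SD) paired t tests with Cohen's d_z (routed to Wilcoxon signed rank
when a Shapiro-Wilk gate rejects normality), a size x weight x condition
within-subjects ANOVA on per-participant z-scored ratings with partial eta
squared, Jeffreys-Zellner-Siow Bayes factors (Cauchy prior, scale 0.707
for t tests; Zellner-Siow g prior for regression), and exact noncentral-t
power analysis for the paired design.

## Worked example

```r
library(swilift)

# design-stage power analysis: how many participants for a paired t test
# to detect d_z = 0.7 with 90% power at alpha = .05 (two-tailed)?
required_n_paired_t(d_z = 0.7, alpha = 0.05, power = 0.90)
#> [1] 24

# evidence for an effect given t(24) = 2.05 across 25 participants
jzs_bf_ttest(2.05, 25)
#> [1] 1.252851

# simulate a 25-participant study and run the whole analysis
report <- run_pipeline(swi_config(n_participants = 25, seed = 42))
print(report)
#> SWI analysis report (synthetic, seed 42)
#> participants: 25 | rating trials: 1850 | invalid kinematic trials: 0
#>
#> SWI real - virtual: mean diff 0.05622 g/cm3, t(24) = 2.15, p = 0.0417, d_z = 0.43, BF10 = 1.48
#> mrv_mm_s (paired_t): diff 83.33, p = 9.98e-05, d_z = 0.93
#> t_mrv_pct (paired_t): diff -0.1554, p = 0.377, d_z = -0.18
#> mlv_mm_s (paired_t): diff -5.861, p = 0.411, d_z = -0.17
#> t_mlv_pct (paired_t): diff 0.4656, p = 0.48, d_z = 0.14
#> presence -> SWI (virtual): beta = -0.02139, R^2 = 0.164, p = 0.0447, BF10 = 1.77
```

Reading the report: the illusion is present in both conditions and about
0.06 g/cm^3 weaker in VR for this simulated dataset (a small effect,
d_z = 0.43, with only anecdotal Bayesian evidence, BF10 = 1.48); reaches
are ~0.08 m/s slower in VR while reach timing and lift kinematics do not
differ; and participants reporting more presence show smaller illusions.
The generator's defaults produce exactly this pattern on average --
mean SWI 0.20 vs 0.15 g/cm^3, a 0.10 m/s reach slowing, null lift
contrasts -- so individual seeds scatter around it.

Lower-level entry points: `simulate_study()` / `write_study()` /
`read_study()` for data, `trial_metrics()` for kinematics,
`zscore_ratings()`, `swi_scores()`, `presence_scores()` for scoring, and
`paired_t()`, `wilcoxon_signed_rank()`, `rm_anova_ratings()`,
`simple_regression()`, `jzs_bf_ttest()`, `jzs_bf_regression()`,
`required_n_paired_t()`, `winsorize()` for the statistics. A thin CLI over
these functions ships at `inst/cli/swilift.R` (subcommands `simulate`,
`kinematics`, `score`, `validate`, `run`).

## File formats

* `ratings.csv`: `participant_id, condition (real|virtual), object,
  trial_index, phase (washout|test), rating` -- ratings positive, 5 washout
  + 32 test rows per participant x condition, 8 per test object.
* `streams.csv`: `trial_id, time_s, wrist_x_mm, wrist_y_mm, wrist_z_mm,
  obj_x_mm, obj_y_mm, obj_z_mm`, ~90 Hz, strictly increasing time; trial
  ids follow `p<participant>_<condition>_t<trial_index>`.
* `presence.csv`: `participant_id, item1..item6`, integers 1-7.

`validate_inputs()` checks all of this and returns a machine-readable
issue list.

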