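---
title: "From robotic kinematics to clinical scales: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From robotic kinematics to clinical scales: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robokin)
```

## The problem

Clinical upper-extremity scales after stroke — the Fugl-Meyer Assessment
(FMA-UE, 0–66), the Wolf Motor Function Test (WMFT), the Barthel Index (BI,
0–100) and the Medical Research Council motor power sum (MRC) — are ordinal,
rater-dependent and coarse. Planar rehabilitation robots record every
evaluation movement at high resolution, and summary metrics of those
recordings correlate strongly with the clinical scales. `robokin`
implements the full analysis chain that establishes and exploits that
correlation:

1. **Macro kinematic/kinetic metrics** per movement segment (aim, duration,
   deviation, dwell time, mean/peak speed, speed shape, dimensionless jerk;
   ellipse fits and shoulder–elbow joint independence for circle drawing;
   displacement/aim under resistance; scatter/offset during isometric
   holds; per-direction shoulder strength and its mean, `deltaz`).
2. **Micrometrics** from a support-bounded lognormal submovement
   decomposition of each segment's speed profile (number, duration,
   overlap, peak, interpeak interval).
3. **Session feature table**: metrics mean-aggregated per (patient,
   session), joined with that session's clinical scores.
4. **Feature selection**: keep metrics with |R| > 0.5 against the target
   scale, then prune mutually dependent metrics (|R| > 0.85 among
   themselves), keeping the most interpretable (an explicit keep-list) or
   the strongest.
5. **Models**: ordinary least squares, and a multilayer perceptron with one
   hidden layer of 2 sigmoid units and a linear output. Features (and, for
   the network, the target) are rescaled by their training maxima.
6. **Validation**: 4-fold cross-validation sampled patient-wise — all of a
   patient's sessions stay on one side of every split — with a Mann-Whitney
   check that train and test outcome distributions match, and the fold-mean
   Pearson R as the headline statistic. Variance inflation factors
   (VIF = 1/(1−R²ⱼ)) diagnose multicollinearity of the selected metrics.

Because the underlying trial data are not publicly deposited, the package
ships a synthetic-cohort generator with full ground truth; every stage is
validated against quantities that are known by construction.

## The synthetic cohort

`simulate_cohort()` draws one latent impairment $z \in [0,1]$ per patient
(truncated normal, mean 0.5, sd 0.25 — a broad impairment spectrum), lets it
drift slightly downward over the four evaluation sessions (two baselines,
discharge, follow-up; mean recovery 0.04 per post-baseline session), and
derives *both* sides of the analysis from it:

* **Trajectories.** Each point-to-point movement is a sum of lognormal
  speed pulses: one primary pulse plus `Poisson(3z)` corrective pulses,
  which blend less (onset overlap `0.5(1−z)` of the preceding duration) and
  last longer as impairment grows; path curvature noise and movement
  duration also grow with $z$, and strength falls as $1 - 0.8z$. At $z = 0$
  every reach is a single clean pulse. These dependencies reproduce the
  recovery signatures reported in the submovement literature (fewer,
  larger, more blended submovements as patients recover). Task geometry
  follows the evaluation protocol: 8 reach targets on a 14 cm circle,
  wrist targets on a 60°×30° ellipse, forearm targets at ±30°, five
  strength trials per direction (F/E/AB/AD), four circle-drawing
  conditions. Sampling is 200 Hz by default, but all metrics integrate
  against explicit timestamps, so no fixed rate is assumed.
* **Scores.** Each scale maps $z$ monotonically onto its range (linear by
  default, logistic optionally), plus Gaussian observation noise, clipping
  and rounding to the scale's granularity. With zero noise and rounding
  disabled, scores are exact affine images of $z$ — the property tests use
  this.

What the generator does *not* emulate: biomechanical forward dynamics,
fatigue or learning within a session, EMG, 3-D shoulder kinematics, and any
treatment effect. Passing tests therefore demonstrate that the pipeline
recovers known structure from data *shaped like* the trial's, not that the
trial's effect sizes are reproduced; the printed correlations of the paper
this design emulates are not recomputable without the original data.

`simulate_score_cohort()` is a second, score-level generator used to test
the modelling stage in isolation: a feature with *exact* population
correlation $\rho$ to the target
($y = \rho x + \sqrt{1-\rho^2}\,\varepsilon$), optionally through a
sigmoidal link that only the network can fit — giving closed-form oracles
for cross-validation recovery and for the linear-vs-nonlinear ordering.

## Numerical choices

**Derivatives and jerk.** Speed uses second-order finite differences on the
timestamp grid after optional Savitzky-Golay smoothing (window 5, order 3 by
default; third derivatives of raw clinical data are noise-dominated, and the
window is configurable). Jerk is computed *directly* as a third derivative
with sliding 7-point Fornberg stencils rather than by differentiating three
times: repeated first differences lose an order of accuracy per application
at the segment boundaries, exactly where squared jerk peaks, which biases
the integral by ~0.5% at realistic sampling rates. The discrete smoothness
measure is $\int \|j\|^2 dt \cdot D^5/A^2$ ($D$ duration, $A$ path length),
which equals 720 for an ideal minimum-jerk reach; the rhythmic variant is
$\int \|j\|^2 dt \cdot D^3/\bar v^2$ — the $D^3$ power is required for a
dimensionless quantity.

**Ellipse fitting** uses the direct least-squares conic fit with the
ellipse constraint $4ac - b^2 = 1$ (Fitzgibbon/Halíř–Flusser reduction)
after centring and scaling for conditioning; orientation is reported in
$(-\pi/2, \pi/2]$. Collinear input is an error, and a circle's orientation
is accepted as arbitrary.

**Inverse kinematics** fixes the elbow-down branch (elbow angle in
$[0,\pi]$), appropriate for a right arm in front of the body; consistency
across a session matters more than the branch itself, since joint
independence is a correlation of angle time series.

**Submovement decomposition.** A pulse is a lognormal density in
normalized support time $\tau = (t-t_0)/D \in (0,1)$, truncated to the
support and renormalized by its truncation mass `plnorm(1, mu, sigma)` so
it integrates exactly to the amplitude $A$. Two design points deserve
emphasis:

* *Gauge fixing.* When the density at the support end is negligible — the
  physiological case; real speed pulses end at rest — the family has an
  exact flat direction: $D \to cD$, $\mu \to \mu - \log c$ changes the
  pulse only in an invisible tail, so onset-relative duration and $\mu$ are
  jointly unidentifiable (we verified machine-precision fits with >1%
  parameter discrepancies). The package therefore fixes the gauge: the
  support is defined to contain 99.5% of the untruncated lognormal's mass,
  i.e. $\mu = \sigma\,\Phi^{-1}(0.005)$ (`gauge_mu()`). The generator and
  the fitter share the convention, making "duration of a submovement"
  well-defined and the fit a well-posed 3-parameter-per-pulse problem.
* *Fitting.* Greedy add-and-refit matching pursuit: initialize a pulse at
  the largest residual peak (duration from its full width at half maximum),
  refit all pulses jointly by bounded Levenberg-Marquardt with amplitudes
  profiled out linearly (variable projection), and stop when the residual
  RMSE falls below `rmse_tol` (default 2%) of the profile's peak speed or
  `max_n` (default 8) pulses are reached. Stalled stages get a Nelder-Mead
  escape cycle, seeded perturbation restarts, and two alternative
  initializations (splitting the widest fitted pulse; one pulse per
  prominent profile maximum) that rescue configurations where one fitted
  pulse absorbs two generating ones. Bounds: $D \in [0.05\,s, 2\times$
  segment span$]$, $\sigma \in [0.05, 2]$. Everything is deterministic
  under the `seed` argument via a self-contained jitter stream.

**Aim** is measured at the first local speed maximum (conventional in this
metric family); the macro metric is the unsigned angle to the target line,
while the resistance task's *overall aim* averages **signed** aims
circularly, so opposite errors cancel rather than accumulate. **Deviation**
defaults to the RMS perpendicular distance from the start→target chord
(`deviation_stat = "max"` is available). **Dwell** uses a 5%-of-peak speed
threshold inside the target radius, matching the segmentation fallback.

## Modelling decisions

* **|R| thresholding.** Selection nominally keeps features with R > 0.5,
  but worse-is-larger metrics (deviation, offset, scatter, submovement
  number) legitimately anti-correlate with the scales, so the absolute
  value is thresholded by default (`signed = TRUE` restores the literal
  reading). When nothing passes, the strongest `top_k` (default 4) are
  returned and flagged sub-threshold — the behaviour the BI analysis needs.
* **Dependency pruning** at |R| > 0.85 among selected features (the
  threshold is exposed; "high dependency" has no canonical value), keeping
  the keep-list member or the feature strongest against the target within
  each connected component of the dependency graph.
* **Selection scope.** Selection runs once on the full table (matching the
  fixed printed feature lists such a study reports) rather than per fold;
  scaling, by contrast, is always re-learned inside each training fold —
  test-fold statistics never leak into it.
* **The network** is `nnet` with `size = 2`, `linout = TRUE`, no decay,
  trained full-batch (BFGS) from 10 seeded random initializations, best
  training RMSE kept; a two-unit network is small enough that multi-start
  handles local minima. Inputs are max-rescaled to about [0, 1] and the
  target by its training maximum, with predictions mapped back.
* **R aggregation.** The reported R is the arithmetic mean of the four
  test-fold correlations; a pooled-prediction R is carried as a secondary.
  The p-value uses the t-transform of the mean R at the pooled test size —
  the conventional test when none is stated.
* **Unbalanced partitions** (any fold's Mann-Whitney p < 0.05) trigger a
  full redraw of the patient partition, up to 20 times, then proceed with a
  warning. Fold sizes differ by at most one patient.
* **Severity strata** (e.g. FMA-UE 1–38 vs 39–66) filter rows by the
  session's score by default; restricting the target's variance typically
  lowers attainable correlations, which the stratified tests demonstrate.
* The two pre-intervention baselines are kept as distinct rows; averaging
  them is a documented option rather than a default, since pooling
  evaluation sessions is the convention this analysis family follows.

## Problem sizes used in the shipped checks

The validation suite and the acceptance script generate everything at run
time at sizes chosen to exercise each property well inside a desktop
budget: cohorts of 8–16 patients with 2–8 reaches per task for
trajectory-level checks, 60–80 patients × 3 sessions for score-level
cross-validation oracles (100 replications for the 0.85-recovery check),
50–100 seeded profiles per decomposition suite, and 500–1000 replications
for calibration rates. The statistics of interest are scale-free
correlations and rates, so these sizes measure the same quantities a
full-size cohort would, with correspondingly wider Monte-Carlo bands that
the stated tolerances account for.

## Known limitations

* The decomposition assumes non-negative speed profiles of terminated
  movements; heavily overlapped pulses (> ~50% of the preceding duration)
  merge into one recovered pulse by design of the stopping rule.
* The WMFT scoring variant is ambiguous in the field (functional-ability
  sum capped at 75 vs time-based scores exceeding it); the type accepts any
  non-negative value and the simulator uses the 0–75 variant.
* VIF above 10 among selected metrics does not invalidate prediction — it
  only voids coefficient-level interpretation; the report flags it rather
  than pruning further.
* Trajectories are phenomenological (speed pulses + curvature noise), not
  forward-dynamic; metric *values* are realistic in scale but their joint
  distribution is simpler than real patient data.
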