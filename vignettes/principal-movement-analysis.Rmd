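---
title: "Principal movement analysis of postural control: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal movement analysis of postural control: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturePMA)
```

## The problem and the model

Quiet-stance balance is controlled across many degrees of freedom at once.
Center-of-pressure summaries collapse whole-body kinematics into a single
2-D signal, which makes it impossible to tell *which* movement strategy an
experimental manipulation (such as a concurrent working-memory task)
affects. posturePMA instead analyzes postural control in the coordinates of
the movement strategies themselves.

Every time sample of a motion-capture trial is treated as a point in
posture space: the concatenated vector of 28 marker positions x 3 axes =
84 coordinates, after each trial has been centered (mean posture removed),
normalized by the participant's height (to remove anthropometric scale),
and each marker weighted by its relative segment mass (so that trunk
markers count for more than toe markers). A PCA of the concatenated
cohort-level matrix yields an orthonormal basis of this space. Each
eigenvector defines a *principal movement* (PM) — a correlated whole-body
movement pattern such as anteroposterior ankle sway — and the trial-specific
score series along PM *k* is the *principal position* PP~k~(t). Central
differences give principal velocities PV~k~(t) and accelerations PA~k~(t).
The relative eigenvalue EV~k~ is the fraction of posture-space variance a
PM explains.

Because each of the 84 input columns contributes on average 1/84 = 1.2 % of
the total information, only PMs with EV~k~ strictly above that threshold are
analyzed further. Robustness of the retained eigendirections is checked by
leave-one-subject-out cross-validation: the basis is refit with each
subject's rows removed, components are matched by eigenvalue rank (a greedy
max-|cosine| matcher is available for near-degenerate spectra), and a PM
counts as robust when the worst-case angle between the full-data and
leave-one-out vector stays below 15 degrees. Near-degenerate eigenvalue
pairs rotate freely under resampling; the package reports this honestly as
a failed robustness flag rather than stabilizing the vectors artificially.

## Outcome measures per principal movement

Four quantities are computed per trial and retained PM:

* **SaEn^PP^** — sample entropy of the low-passed, detrended PP series:
  irregularity of the sway along that movement component.
* **SaEn^PA^** — sample entropy of the low-passed PA series: irregularity
  of the neuromuscular control signal driving the component.
* **N** — number of zero crossings of the filtered PA: how often the
  control system intervenes (reverses the accelerating action).
* **sigma** — SD of the times between successive PA zero crossings:
  variability of the intervention timing. N and sigma together express
  *control tightness* (tight control = many interventions, regular timing).

Sample entropy uses a delayed embedding
u~i~ = [x(i), x(i+tau), ..., x(i+(m-1)tau)]: with B the number of template
pairs within Chebyshev tolerance r at dimension m and A the same at m+1
(self-matches excluded, both counted over the common index range),
SaEn = -ln(A/B). Defaults are the field-typical m = 2, r = 0.2 x SD of the
analyzed series, and tau = 12 samples = 100 ms at 120 Hz — a physiologically
meaningful correction timescale. Because r scales with the SD of the series
as passed in, SaEn is invariant to affine scaling; r is computed *after*
filtering/detrending since that conditioned series is what enters the
template comparison. Degenerate cases are surfaced, not hidden: a constant
series (r = 0) raises an error, no m-matches returns NA with a warning, no
(m+1)-matches returns an Inf sentinel. Undefined cells propagate as NA
through the measure table and are removed listwise (per subject, with a
logged count) by the statistics layer.

## Processing order and numerical choices

* **Pipeline order (fixed, logged):** fill gaps -> trim 10 s from each end
  (settling-in and end-anticipation) -> downsample 240 to 120 Hz -> mirror
  left-foot-in-front trials -> select the 28 symmetric markers -> center +
  height-normalize per trial -> mass-weight -> concatenate.
* **Gap filling** uses iterative low-rank (PCA) reconstruction initialized
  by linear interpolation (rank 5, tolerance 1e-8 RMS, max 100 iterations);
  observed samples are never altered, a fully-missing marker is an error,
  and more than 50 % missing data is refused. On noiseless low-rank data
  the completion is exact to 1e-6 (verified by test).
* **Downsampling** is plain decimation (every 2nd frame). No anti-alias
  prefilter is applied because the downstream 7 Hz low-pass bounds any
  aliased high-frequency noise, and decimation keeps the operation exactly
  reproducible.
* **Mirroring** negates the mediolateral axis and swaps L/R marker labels
  so all trials describe the same (right-foot-front) stance. The package
  declares lab X as mediolateral; this is a convention, not a measurement,
  and is overridable. Mirror twice = identity (tested).
* **Mass weighting** multiplies all three axes of a marker by its relative
  segment mass w (Winter proportions, each segment's mass split equally
  over that segment's retained markers, renormalized over the keep-list).
  Weighting by w matches established mass-weighted-coordinate practice;
  note that only a sqrt(w) weighting would make the PCA variance itself a
  mass-weighted quantity — the configuration accepts a custom table, so a
  sqrt(w) variant is a one-line change for users who prefer it.
* **Centering is per trial**, not per subject: it removes inter-trial
  stance drift and is the stricter reading of "subtracting the mean
  posture". PCA is computed on the covariance of the weighted matrix with
  no per-column re-standardization — the height and mass normalizations
  *are* the intended scaling. Eigenvector signs follow a deterministic
  convention (largest-magnitude loading positive).
* **Differentiation before filtering:** PA is the central difference of
  the unfiltered PP, then low-passed. Central differences are exact for
  quadratics and have zero phase error.
* **Filtering** is a 6th-order Butterworth low-pass at 7 Hz applied
  forward-backward (zero phase), because crossing times and entropy
  templates must not be phase-shifted; the effective magnitude response is
  the squared single-pass response, and a single-pass option exists. The
  implementation pads with an odd reflection long enough for the
  zero-initial-condition transient to decay below numerical noise, so a
  constant series passes through unchanged to 1e-8. A spectral check
  (`powerFraction()`) confirms PP content is concentrated at low
  frequencies before trusting the 7 Hz cutoff.
* **Detrending** of PP subtracts a 501-point (about 4 s at 120 Hz)
  centered moving average; within the first/last 250 points the subtracted
  value is the nearest fully-defined average. The window must be odd.
* **N and sigma are computed on the filtered PA** by default (the
  unfiltered path is exposed as an option): the blanket filtering rule is
  read as applying to all PA-derived variables. Exact zeros inherit the
  preceding nonzero sign (leading zeros the following one), so a zero run
  contributes at most one crossing; sigma needs at least 3 crossings.

## Statistics layer

Each variable x PM is analyzed with a split-plot repeated-measures ANOVA:
age group (young/old) between subjects, dual-task condition (ST, DT1..DT4)
within subjects, with separate error strata (subjects-within-group for the
group effect; condition x subjects-within-group for condition and the
interaction). For 41 subjects in 2 groups and 5 conditions this gives df
(1, 39) between and (4, 156) within. With unequal group sizes the
condition effect uses Type III sums of squares (unweighted marginal
means), matching SPSS output conventions common in this literature.

Sphericity is tested with Mauchly's W, using the second-order chi-square
refinement that SPSS/SAS (and car) print. When Mauchly rejects at 0.05,
degrees of freedom are scaled by the Greenhouse-Geisser epsilon if
eps~GG~ < 0.75, else by the Huynh-Feldt epsilon (capped at 1); a
config flag can force always/never. Reported alongside p are partial eta
squared, eta~p~^2^ = F df1 / (F df1 + df2), and observed power from the
noncentral F distribution with lambda = F df1 — the convention of standard
statistics packages, using the *corrected* dfs when a correction was
applied (the choice is flagged in the output; the convention reproduces
printed (F, df) -> (eta~p~^2^, power) pairings such as F(1,39) = 8.74 ->
0.18 / 0.82). Post-hoc contrasts are paired t tests over all 10 condition
pairs with Sidak adjustment p' = 1 - (1 - p)^10^; the family size is
logged and configurable because published reports often leave it implicit.
Normality (Lilliefors-corrected KS — the estimated-parameter null — and
Shapiro-Wilk) and variance homogeneity (Levene, center = mean) are
advisory: the pipeline warns and proceeds.

## The synthetic cohort generator

The study's recordings are not redistributable, so the package ships a
generator whose defaults emulate the study design: 23 + 18 subjects
(young 1.7 m / old 1.6 m), five conditions, 28 markers at 240 Hz for 80 s,
and a leading eigenspectrum of 51.1, 26.5, 9.7, 3.9, 2.6, 1.9 % with the
residual 4.3 % spread geometrically over trailing components.

Each PP series is a sum of 2-3 sinusoids (0.2-2 Hz, random phases) mixed
with 1/f-filtered Gaussian noise and scaled to its exact target variance
share. The noise-mixing weight in [0, 1] is the regularity dial: it maps
monotonically to sample entropy (verified over replicates), which gives
every entropy-related claim a controllable ground truth. Condition effects
modulate the weight multiplicatively along an "n"/"monotone"/"flat"
template; group effects add a scalar offset. Effect amplitudes are free
parameters (the emulated study reports only directions and percent changes
on its own cohort); the default peak modulation of 0.3 was chosen once as
a moderate, realistic effect. Marker noise is added in posture-space units
and occlusions are planted as contiguous runs (geometric lengths, mean
0.25 s) because real marker dropouts cluster in time. Trials are assembled
by inverting the normalization chain (scores -> basis -> un-weight ->
un-normalize by height -> add mean posture), so running the pipeline on a
noiseless cohort must recover the planted spectrum — the acceptance suite
requires agreement within 2 percentage points and observes errors around
0.01-0.05.

What the generator does **not** emulate: biomechanically consistent joint
constraints (markers move along planted linear modes, not limbs), muscle
dynamics, non-stationarity across a trial, or realistic inter-subject
eigenstructure variability. Passing parameter-recovery tests therefore
demonstrates that the estimators are correct and calibrated, not that the
scientific conclusions of any particular cohort would replicate.

## Problem sizes used by tests and the acceptance script

Simulation sizes were chosen as the smallest that make each check sharp:
unit tests use cohorts of 4-8 subjects with 10-15 s trials at 120 Hz;
parameter-recovery and leave-one-out checks use 8 subjects x 5 conditions
x 10 s; ANOVA calibration uses 1000 null and 500 powered replicates of a
20 + 20 x 5 measure table, where the type-I error must land in
[0.03, 0.07] and the Monte-Carlo power within 3 points of the noncentral-F
prediction; the entropy implementation must agree with an exhaustive
enumeration oracle on 200 random series (n <= 400) to 1e-12.

## Known limitations

* PMs are linear components; individual PMs only approximate real,
  nonlinear movement strategies, and interpretation of single components
  should be cautious. Time-resolved or nonlinear decompositions are out of
  scope.
* C3D files are not read directly; trials enter as wide CSV + JSON sidecar
  (the exporter writes doubles at full precision, so round trips are
  bit-exact).
* The exact symmetric 28-marker subset and segment-mass source table are
  configuration, not ground truth; defaults follow Plug-in-Gait labels and
  Winter mass proportions.
* Absolute values of SaEn, N and sigma depend on the filter cutoff and
  entropy parameters; comparisons are meaningful within a fixed
  configuration, which the pipeline records in its provenance output.
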