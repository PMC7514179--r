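# posturePMA

Principal movement analysis of postural control under cognitive dual-tasking.

## What it does, and for whom

Balance researchers who record whole-body marker kinematics of quiet
stance (e.g., tandem stance with a concurrent auditory n-back task) need to
know *which* movement strategies a manipulation affects — not just how a
collapsed center-of-pressure trace changes. posturePMA implements that
analysis end to end:

1. **Preprocessing** — PCA-based gap filling, trimming (10 s off each
   end), decimation 240 → 120 Hz, mirroring of left-foot-in-front trials,
   reduction to a 28-marker symmetric set, per-trial centering,
   height normalization, and segment-mass weighting; all trials are
   concatenated into one posture matrix (28 markers × 3 axes = 84
   columns).
2. **Kinematic PCA** — the eigenvectors PC_k of the posture covariance
   define principal movements PM_k; trial scores give principal positions
   PP_k(t), with principal velocities PV_k(t) and accelerations PA_k(t) by
   central differences. PMs are retained when their relative eigenvalue
   EV_k exceeds the average information content of one input column,
   1/84 = 1.2 %; retained directions are validated by leave-one-subject-out
   cross-validation (robust if the PC orientation shifts < 15°).
3. **Control measures** — per trial and PM: sample entropy of the 7 Hz
   low-passed, moving-average-detrended PP (sway irregularity); sample
   entropy of the low-passed PA (control irregularity); the number of PA
   zero crossings N_k and the SD of inter-crossing times σ_k (control
   tightness). SaEn uses the delayed embedding u_i = [x(i), x(i+τ), …]
   with m = 2, r = 0.2·SD, τ = 12 samples (100 ms at 120 Hz):
   SaEn = −ln(A/B), the conditional probability that templates matching at
   dimension m still match at m + 1.
4. **Statistics** — split-plot repeated-measures ANOVA per variable × PM
   (group between, condition within; two error strata), Mauchly's
   sphericity test with Greenhouse–Geisser / Huynh–Feldt df corrections
   (GG below ε = 0.75, HF above), partial eta squared
   η_p² = F·df1/(F·df1 + df2), observed power from the noncentral F with
   λ = F·df1, and Sidak-corrected pairwise condition contrasts.
5. **Synthetic cohorts** — a generator with known eigenspectrum, an
   entropy-controlling regularity dial, planted n-shaped condition
   effects, measurement noise and realistic occlusion gaps, so the whole
   pipeline is testable by parameter recovery.

## Worked example

```r
library(posturePMA)

spec <- cohortSpec(n_subjects_per_group = c(4L, 4L), sampling_rate = 120,
                   duration = 20, seed = 1L)
cfg  <- runConfig("synthetic", spec = spec, cut_s = 2, target_rate = 120)
run  <- runPipeline(cfg)

run$basis
#> PMBasis: 84 principal movements over 84 posture coordinates
#>   relative EV (%): 50.7 26.9 9.7 3.9 2.6 1.9 1.8 1.1 ...

run$retained
#> [1] 1 2 3 4 5 6 7

head(run$measures, 3)
#>   subject_id group condition pm  saen_pp   saen_pa   n      sigma
#> 1        Y01 young        ST  1 1.524827 0.9691373 183 0.02775268
#> 2        Y01 young        ST  2 1.504368 0.9939626 154 0.05315399
#> 3        Y01 young        ST  3 1.591440 1.2659699 172 0.04158529
```

The generator planted EVs of 51.1, 26.5, 9.7, 3.9, 2.6, 1.9 % for its six
leading components; the fitted spectrum above recovers them to a fraction
of a percentage point on this 8-subject cohort, and the trailing residual
components fall around the 1.2 % retention threshold. Each measure row is
one subject × condition × PM cell: `saen_pp`/`saen_pa` are irregularity in
nats, `n` counts control interventions in the 16 s analyzed window, and
`sigma` (s) is the intervention-timing variability.

```r
subset(run$stats$anova, variable == "saen_pp" & pm == 1,
       select = c(effect, F, df1_corr, df2_corr, p, eta_p2, power, correction))
#>            effect         F df1_corr df2_corr          p     eta_p2      power
#> 1           group 0.5452502        1        6 0.48813081 0.08330471 0.09616995
#> 2       condition 2.7009944        4       24 0.05462581 0.31042364 0.65773227
#> 3 condition:group 0.8206821        4       24 0.52475865 0.12032258 0.22310549
```

With 8 subjects in 2 groups and 5 conditions the error strata have
(1, 6) and (4, 24) degrees of freedom; at the full study size (23 + 18
subjects) the same layout yields (1, 39) and (4, 156). The effect-size and
power conventions reproduce published pairings:

```r
round(partialEtaSq(8.74, 1, 39), 3)   # 0.183
round(observedPower(8.74, 1, 39), 3)  # 0.822
```

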