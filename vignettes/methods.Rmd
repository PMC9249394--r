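---
title: "Models and methods behind hippo2p"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hippo2p}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippo2p)
```

hippo2p implements the quantitative analysis stack of a transverse-plane
two-photon hippocampal imaging experiment: optical resolution
characterization, calcium-trace post-processing, floating circular-track
behavior, place- and speed-cell classification, spatial-information
profiles along the DG-to-CA1 axis, dendritic-spine morphometrics and
turnover, and glial-density statistics. Every module can be exercised on
synthetic data with known ground truth; this vignette describes the
models, the tunable parameters, and the design decisions that were
genuinely open.

## Track geometry and behavior processing

The arena is an annular track between a 250 mm outer wall and a 140 mm
inner circle. Positions are linearized along the midline circle, whose
circumference is `pi * (250 + 140)/2 / 10 = 61.26` cm, divided into 72
equal bins of ~0.85 cm.

Tracker samples arrive faster than the stored 10 Hz imaging frames; all
samples within a frame interval are reduced to their median, with the
polar angle reduced by a *circular* median (the minimizer of summed
absolute circular deviation; antipodally symmetric pairs resolve to the
circular mean of the tied minimizers, so {350°, 10°} gives 0°).

Movement filtering smooths speed with a 0.5 s moving average, keeps
periods longer than 1 s above 20 mm/s, and dilates each period by 0.5 s
on both sides. A lap is a full 2π of *net* accumulated rotation since
the previous lap boundary, so direction reversals must be made up before
a lap completes; partial laps at the session edges are unassigned. Laps
whose mean instantaneous speed exceeds 180 mm/s are dropped: at such
speeds the slow calcium signal cannot be attributed to ~0.85 cm bins.

## Calcium-trace post-processing

Neuropil correction subtracts a scaled, mean-centered neuropil trace,
`F_corr(n) = F_soma(n) - alpha (F_np(n) - mean(F_np))`, with `alpha` the
grid-plus-golden-section minimizer over [0, 1] of the **absolute**
Pearson correlation between the corrected and neuropil traces. Signed
minimization would run to the boundary, so the absolute value is the
only self-consistent reading; a degenerate flag marks cells whose
corrected trace collapses (soma trace equal to the neuropil).

The dF/F baseline `F0` is the location of the first (lowest-valued)
mode of a Gaussian kernel-density estimate (Silverman bandwidth) of the
corrected trace. For tonically active cells the density mode sits above
resting fluorescence; this compresses their dF/F and is the reason some
such cells fall below the event-recovery regime discussed below.

Spike inference inverts the AR(2) generative model of the calcium
kernel. With poles given by the sensor's rise (~0.1 s) and decay
(~1.5 s) constants at the frame rate, the innovation
`s(n) = y(n) - g1 y(n-1) - g2 y(n-2)` recovers the event train exactly
on noiseless input; nonnegativity clamping plus a sparsity threshold at
3 noise-sd suppress noise. The noise sd is estimated from the
*negative* innovations only (noise is symmetric, true events are
strictly positive), which keeps the threshold honest for densely firing
cells. Advisory QC flags mark cells whose mean inferred rate during
movement is above 10/s or below 1/s.

## Place- and speed-cell classification

Per-lap spatial tuning curves divide binned activity by per-bin
occupancy time on moving frames of kept laps; unoccupied bins are
missing, and the session curve averages across laps ignoring them.

**Consistency test.** 500 random half-splits of the laps give the real
distribution of split-half tuning-curve correlations; the null repeats
this after circularly permuting each lap's curve by an independent
uniform shift of 1–71 bins (fresh permutation and fresh split each
iteration). A cell passes when the two-sample Kolmogorov–Smirnov test
rejects at alpha = 0.01 **and** Cohen's D between the distributions
exceeds 0.5 **and** the mean real correlation exceeds the 99th
percentile of the shuffled values. The third gate is a deliberate
addition: the real distribution is conditional on the one observed
session mean curve while the shuffle is marginal, so the KS statistic
rejects for structureless data on width alone and the null spread of
Cohen's D is set by the bin count (not the lap count, and roughly
independent of it). Measured on independent-noise sessions, KS + D
alone pass ~20% of structureless cells; adding the percentile gate —
the standard form of a shuffle test — brings the false-positive rate of
the full classifier to 0% on lap-time-shuffled sessions, which is the
operating characteristic the procedure is supposed to have.

**Gaussian field fit.** The session curve is circularly recentered on
its maximum and fit with `R = A0 + A exp(-((x-B)/C)^2)` by
Levenberg–Marquardt least squares; `FWHM = 2 C sqrt(ln 2)`. A place
cell must be consistent and satisfy all of: adjusted R² > 0.375;
2.5 cm < FWHM < 30.63 cm (half the track); A > 0; A/A0 > 0.5 (A0
clamped to 1e-6 when the fitted offset is non-positive, flagged). The
field center is the fitted peak mapped back to track coordinates.

**Speed score.** Pearson correlation of the full dF/F trace with speed,
gated at the 99th/1st percentile of 100 circular shuffles with shifts
of at least 10 frames; the two one-sided 1% gates give a ~2% chance
rate on independent noise.

**Spatial information** follows the occupancy-weighted formula
`SI = (1/abar) * sum_k p(k) a(k) log2(a(k)/abar)` over the 72 bins on
the *deconvolved* rate, in bits per inferred spike; zero-rate bins
contribute nothing and zero-rate cells are excluded.

A note on parameter recovery: the dF/F tuning curve is the spatial
field convolved with the causal indicator kernel along the trajectory,
so its fitted FWHM is wider than the generative field (by roughly
`speed x decay time` ≈ 16 cm at 110 mm/s) and its peak sits downstream
of the true center. Recovery of generated field centers (≤ 1 bin) and
widths (≤ 15%) therefore holds for tuning curves computed on the
deconvolved rates, which undo the kernel; the dF/F-based classification
itself is unaffected.

## Synthetic sessions

The behavior sampler runs at 40 Hz (4× the stored rate) so per-frame
median aggregation is non-trivial. Run epochs of 15–35 s draw lognormal
mean speeds around 110 mm/s; with probability 0.15 an epoch is a 4–6 s
sprint at 190–240 mm/s, calibrated so that roughly 7% of laps trip the
180 mm/s fast-lap filter; rests last 2–6 s. Place fields are von Mises
bumps (avoiding wrap artifacts of a plain Gaussian) parameterized by
their FWHM (default 15 cm), with in-field event rates peaking at
2.5 events/s over a 0.2 events/s floor; speed cells are affine in speed
with both signs of slope; traces convolve Poisson event trains with the
AR(2) kernel (per-event dF/F 0.5), ride on a baseline of 100, and
receive a shared low-pass neuropil signal (sd 0.2, mixed in with gain
0.3) plus white noise (sd 0.05). The real-data features this generator
does **not** emulate — drifting baselines, motion artifacts, remapping,
reward modulation — mean that passing tests demonstrate correctness of
the algorithms, not performance bounds on arbitrary recordings. The
trace noise level and transient amplitude are configuration, not claims:
the source experiment does not report them.

Problem sizes used in the shipped tests (chosen to exercise every code
path at comfortable statistical power): sessions of 100 cells × 600 s
for classifier operating characteristics, 40 cells for module tests,
12-bead stacks, 16-spine dendrites over 5–6 days.

## Optics

Bead detection thresholds the stack (median + 5 MAD with a floor at 10%
of the dynamic range), labels 3-D components, and drops components
smaller than 8 voxels, any bead with a neighbor nearer than 25 px, and
any bead touching the first or last plane. Each surviving bead is
sub-pixel registered at its intensity centroid by trilinear resampling;
XY and XZ profiles are peak-normalized and averaged across beads, and
the FWHM of the central row/column is measured by linear interpolation
at half maximum after subtracting the profile-border median.

The theoretical two-photon 1/e half-widths are
`w_xy = 0.320 λ / (sqrt(2) NA)` for NA ≤ 0.7 (else
`0.325 λ / (sqrt(2) NA^0.91)`) and
`w_z = (0.532 λ / sqrt(2)) [1/(n - sqrt(n² - NA²))]`, converted to FWHM
by `2 sqrt(ln 2)`. The published lateral formula is discontinuous at
NA = 0.7 by under 2%; the implementation switches branches at 0.7 and
documents the jump rather than smoothing it. The effective NA of a
periscope prism is modeled as beam clipping through the glass path:
`NA = min(n_glass sin(atan(aperture/2 / path)), objective NA)`. With
the v1 (1.0 mm / 2.0 mm) and v2 (1.5 mm / 2.5 mm) geometries this gives
theoretical axial FWHMs of 11.4 and 8.0 μm against the published 10.9
and 7.7 μm — agreement within ~5%, retained as-is because the exact NA
derivation behind the published values is not stated.

## Dendritic spines

Composite images are Gaussian-weighted averages of translation-
registered planes (phase correlation with parabolic sub-pixel peak).
Binarization subtracts a large-kernel Gaussian background (high-pass),
applies Otsu's global threshold, optionally unions in components above
user-listed lower thresholds (the automated replacement for manual
rescue), fills holes, and removes objects below 1 μm². The shaft is
isolated by a morphological opening that erases the thin spines, then
thinned to a 1-px skeleton (Zhang–Suen).

Spines are the components of mask-minus-shaft-corridor that touch the
corridor. Length runs from the base midpoint to the most distant pixel;
the base-to-tip axis is divided into three equal segments, the head
being the distal third. Head circularity is `4 π A / P²` with the
perimeter estimated by Cauchy's mean-breadth formula (π times the mean
projection breadth over directions), which is exact for convex shapes
and, unlike edge counting, does not degenerate on heads a few pixels
across. Aspect ratio is length over the maximal width perpendicular to
the axis. Neck length defaults to the along-axis extent where the width
falls below half the head width; the literal thirds reading
(neck = length/3) collapses the published thresholds (every spine would
have neck > 0.2 μm exactly when length > 0.6 μm) and is available via
`neck_mode = "thirds"`.

Classification applies the published thresholds verbatim in the
precedence stubby → mushroom → filopodium → thin (the published
categories overlap; unmatched records fall back to thin, flagged). Two
published rules are mutually inconsistent as printed: a "head
circularity < 0.8 μm" carries units on a dimensionless quantity, and
the > 1 μm² inclusion area cannot be met by any spine shorter than the
0.7/0.8 μm thin/filopodium length bounds. The thresholds are kept
verbatim and the area rule is a parameter; the synthetic four-class
round-trip runs with a permissive area threshold for that reason.

Cross-day matching is greedy nearest-neighbor on arc position along the
shaft within 1 μm; chained matches assign stable identities, a lost
spine that reappears counts as new, and a curation table can override
any match. Synthetic day series share the shaft exactly, so identity
registration satisfies the ≥ 50% shaft-overlap contract; the generator
places added spines away from both days' positions so added/subtracted
events remain identifiable. Turnover per day pair is
`N_added-or-lost / mean(N) × 100`; per-class turnover is normalized to
the pair's total cumulative turnover; survival
`S(t) = N_retained(t)/N(day 1) × 100` is non-increasing by
construction.

## Axis profile and histology

The cell-body layer is fit by rotating centroids over a 1° grid on
[0, 180) and least-squares fitting `y = a(x-b)² + c` at each rotation,
keeping the rotation with maximal R²; the inflection is the de-rotated
vertex. A cell's axis coordinate is the arc length (closed form for a
parabola) from the vertex to the nearest curve point, signed by the
rotated x direction. The sliding-window SI profile (window 200 μm, step
50 μm over ±600 μm — the source experiment does not print its values,
so these are configuration) reports per-window means with a
cells-resampled bootstrap s.e.m. and flags windows outside the
2.5–97.5% envelope of SI-permuted controls. The flatness test is the
general linear F-test of per-bin means (5 equal bins, matching the
published F(4, ·) degrees of freedom) against the grand mean — a
one-way ANOVA F computed from its RSS definition and cross-checked
against `lm`/`anova`.

Glial density uses minimal Euclidean distance from each centroid to
the implant-face segment, binned at 50 μm, with percent change relative
to the mirrored contralateral control and a 1000-resample bootstrap
that resamples whole distance vectors (the within-bin alternative is
not what "randomly sampled distances" describes).

## Known limitations

- The consistency test's extra percentile gate changes the literal
  two-gate rule; without it the published false-positive rate is not
  attainable (measured ~20% on structureless data). Disable with
  `mean_gate_q = NA` to study the two-gate behavior.
- Registration is translational; non-rigid warps are out of scope and
  synthetic data does not generate them.
- dF/F-based field widths inherit indicator smearing; compare widths
  across conditions, not against generative truth, unless computed on
  deconvolved rates.
- The effective-NA model reproduces published theoretical axial widths
  only to ~5–10%; the published derivation is unspecified.
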