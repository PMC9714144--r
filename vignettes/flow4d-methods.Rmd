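---
title: "Methods: intracardiac flow components, kinetic energy and the cohort statistics"
author: "flow4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intracardiac flow components, kinetic energy and the cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models, the numerical choices behind them, what the synthetic data do
and do not emulate, and the design decisions taken where the method left
room.

## The measurement problem

Time-resolved three-directional phase-contrast cardiovascular magnetic
resonance (4D flow CMR) samples the blood velocity vector in every voxel of
the heart at every cardiac phase. Two families of quantities summarize what
that field says about a ventricle:

* **Flow components.** Blood occupying the ventricle at end diastole (ED)
  is partitioned by where it came from and where it goes within one beat:
  *direct flow* entered during the preceding diastole and is ejected in the
  following systole; *retained inflow* entered but is not ejected; *delayed
  ejection flow* was already in the chamber and is ejected; *residual
  volume* resides for more than a full cycle. In pulmonary arterial
  hypertension the right-ventricular direct-flow fraction falls and the
  residual fraction rises, and the direct/residual ratio (the *fractional
  flow ratio*) compresses.
* **Kinetic energy.** The blood pool's kinetic energy per frame,
  `KE(t) = sum over voxels of 1/2 rho V_voxel |v|^2`, indexed to
  end-diastolic volume (KEI_EDV, uJ/ml), summarized at peak systole,
  averaged over systole, and at the early-diastolic (E-wave) filling peak.
  The RV/LV ratio of average systolic KEI_EDV is the *KE discordance*.

Around these sit the cine-derived indices (RV/LV end-diastolic volume ratio
as a remodelling index with a control-derived `mean + 3 SD` adverse cutoff,
ejection fraction, TAPSE, inter-ventricular synchrony, right-atrial area,
strain at end systole, pulmonary-artery relative area change), the exercise
metrics (peak VO2, percent of predicted, VE/VCO2 slope, default imputation
and threshold stratification), composite risk grading, and the statistical
battery used to relate imaging to exercise capacity.

## Pathline tracing

The velocity field is interpolated trilinearly in space and linearly in
time between the two bracketing cardiac phases; the cycle is periodic
(frame `T` wraps to frame 0), which is what lets particles be traced
backward through "the preceding diastole". The grid is voxel-centered:
voxel `(i, j, k)` (0-based) sits at `(i, j, k) * voxel_size` mm, so the
interpolation geometry is unambiguous, and the interpolant reproduces
stored vectors exactly at voxel centers on frame times and is exact for
fields affine in space and time.

Particles are advected with the classic fourth-order Runge-Kutta scheme at
a fixed sub-step of one fifth of the frame interval (`dt_fraction = 0.2`,
configurable). A fixed step keeps the integration deterministic and, at the
20-40 ms frame intervals typical of gated acquisitions, resolves the flow
comfortably: the observed convergence order on a rigid-rotation field is
4.00, closed orbits return to their seeds within one part in 10^7 of the
radius over a full cycle, and forward-then-backward integration returns
smooth-field particles to within 10^-6 of the grid extent. Positions are
recorded at every frame time crossed.

A particle whose integration leaves the grid bounding box is frozen at its
last computed position and flagged; classification treats leaving the grid
as having left the chamber, which is the correct reading both in the
analytic phantoms (the outflow region continues beyond the grid) and in
clinical fields (leaving the imaged volume implies leaving the chamber).
Velocity inside the grid but outside any mask is used as stored — particles
must traverse the atria and outflow tracts to register entry and exit.

## Component classification

Seeds are placed at every labelled voxel center of the seeding ventricle at
the ED frame (optionally on a coarser lattice). Each seed is traced forward
over the systolic interval `[ED, ES]` and backward over the preceding
diastolic interval `[previous ES, ED]`; ED and ES are the argmax/argmin of
the ventricular volume curve (earliest frame on ties, for determinism), or
are supplied explicitly for static-mask phantoms. Membership in the
seeding ventricle is evaluated at each recorded frame against the
frame-matched mask by nearest-voxel, nearest-frame lookup — labels are
categorical, and interpolating them would manufacture fractional membership
that the classification rules do not define. Entry and exit are detected
purely by mask membership, not by explicit valve planes: the method
operates on segmented blood pools, and one outside frame suffices to count
as entered/ejected (a `min_outside_frames` dwell parameter is exposed for
sensitivity analysis). The four labels follow the truth table
entered x ejected, fractions are percentages of seeded particles (summing
to 100 by construction), and the fractional flow ratio is reported as
missing — not infinity — when the residual fraction is zero.

## Kinetic energy

Velocities are stored in cm/s (the phase-contrast convention) and converted
to SI at the single point of use: with `v` in m/s, `rho` in kg/m^3 and
voxel volume in m^3 the per-frame sum is in joules, reported in uJ. Blood
density defaults to 1060 kg/m^3 (standard haemorheology value,
configurable). Note the convenient identity `1 J/m^3 = 1 uJ/ml`: a
uniform-speed pool whose mask volume equals its EDV has
`KEI_EDV = 1/2 rho |v|^2` exactly, which the uniform phantom verifies to
machine precision.

Phasic summaries use the closed systolic interval `[ED, ES]` (well-defined
even for short cycles): peak systolic is the maximum, average systolic the
arithmetic mean. The E-wave peak is searched in the first half of diastole,
frames `(ES, ES + ceil(0.5 * n_diastolic_frames)]`; restricting to the
first half excludes the late-diastolic A-wave by construction. Whether the
original core-lab window excludes late diastole is not stated anywhere, so
the fraction is exposed as `e_wave_fraction` (default 0.5).

## Cine, CPET and risk conventions

* The adverse-remodelling cutoff is `mean + 3 * sample SD` (n-1
  denominator, the cohort-summary convention) of the control indices,
  rounded to 2 decimals for reporting; control summary statistics 0.97 and
  0.10 give the published 1.27.
* TAPSE is the systolic maximum of the lateral tricuspid displacement
  curve, which the tracking convention pins to 0 at frame 0. The synchrony
  index is reported as the absolute tricuspid-mitral peak-time difference,
  with the signed (RV minus LV) value alongside, since the source
  convention is ambiguous.
* Areas use the shoelace formula with a pairwise segment-intersection
  validity check; strain is read at end systole with the input's sign
  convention preserved.
* Peak VO2 is the highest 10-s-averaged exercise sample (a binning helper
  averages raw breaths); the VE/VCO2 slope is the OLS slope of VE on VCO2
  from exercise start to the first sample achieving peak VO2. Incomplete
  tests are imputed with the conventional defaults (14 ml/kg/min, 46%, 45).
  Stratification thresholds are inclusive as printed: abnormal peak VO2 at
  <= 15 ml/kg/min; exercise risk at % predicted <= 65 and/or slope >= 36.
* Composite risk averages the available per-variable grades (recording how
  many contributed, since a missingness rule is not specified) and rounds
  to the nearest integer; half-point means round up, toward higher risk —
  the conservative clinical choice, configurable.

## The statistical battery

Two-group comparisons gate on Shapiro-Wilk at 0.05 per group (the source
states the parametric/nonparametric dichotomy but not the gate): Welch's t
when both groups look normal, Mann-Whitney U otherwise. Bonferroni family
levels are computed as the literal `0.05 / m` and displayed at 3 decimals;
for families of 7 and 9 this gives 0.007 and 0.006, not the 0.0065 and
0.0045 printed in some summaries of the same rule — the package computes,
it does not transcribe.

The regression pipeline mirrors the conventional two-stage screen:
univariate linear fits keep candidates at P < 0.05, then stepwise selection
(forward with backward elimination, entry 0.05, removal 0.10 — conventional
defaults, configurable) among the survivors, on natural-log-transformed
outcomes where flagged. ROC analysis is empirical over all observed
cut-points with AUC by the rank (Mann-Whitney) formula — the AUC therefore
*equals* U scaled by `n1 n2`, an identity the tests verify exactly — and
the Youden-optimal threshold breaks ties toward higher specificity.
Correlated AUCs are compared with the DeLong structural-components
estimator (identical predictors return a zero difference with P = 1 rather
than a 0/0); incremental value uses nested binary logistic models, with
each model's chi-square being twice its log-likelihood gain over the
intercept-only model and the increment tested on 1 df. Separation is
flagged from boundary fitted probabilities (penalized refits are out of
scope). Bland-Altman reports bias, 1.96-SD limits of agreement, and a
coefficient of variation with the grand mean of all measurements as
denominator (the most common convention; the source does not state one).

ROC directionality defaults to "higher predictor = positive class"; an
`auto` mode picks the direction with AUC >= 0.5 per predictor. The null
simulations use the fixed direction, since flipping each curve adaptively
under the null would bias the size of the DeLong test.

## Synthetic data: what it emulates, and what it does not

**Phantoms.** The plug-transit phantom is a static channel chamber of
length `L` voxels: plug inflow advances blood `a` voxel lengths over
diastole, plug outflow `b` over systole, so per unit length direct
= `max(0, a + b - L)`, retained = `a - direct`, delayed = `b - direct`,
residual = the rest — exact for the voxel-center seed lattice at integer
`a`, `b`. The systolic frames are sampled at constant speed so the forward
displacement is exactly `b`; because the interpolant is linear in time, the
diastolic samples blend with the systolic value over the two boundary
frame intervals, and the generator solves the diastolic plateau speed from
`a = dt (u_d (T_d - 1) + u_s)` so the backward displacement is exactly `a`.
The two-channel variant adds an equal-volume static channel, guaranteeing
all four components are nonzero, with ground truth the volume-weighted
average with (0, 0, 0, 100). The default test-scale phantom (chamber
20 voxels, two 20x10-voxel channels, 30 frames of 30 ms, 2.5 mm voxels,
8000 seeds) recovers (15, 15, 20, 50)% exactly at the default integrator
settings; the test matrix spans `L` in {8, 10, 16} and direct fractions
from 0 to 50%, all within the 2-percentage-point recovery bound.

The rotation phantom (rigid rotation, one revolution per cycle) exercises
orbit closure and integrator order; since every orbit is closed its ground
truth is 100% residual volume. One discretization subtlety: a closed orbit
at radius `r` can round to a voxel center at radius up to `r + 0.7` voxels,
so a voxelized disc flickers at its boundary under categorical membership.
The generator therefore dilates the labelled disc by 1.5 voxels at every
frame except the seeding frame, making the voxelized membership agree with
the continuous chamber. The uniform phantom provides the kinetic-energy
closed forms.

Phantom chamber walls do not move, so ED/ES are declared in the ground
truth rather than inferred from a flat volume curve; the volume-curve
inference path is exercised separately by a deforming mask with programmed
per-frame voxel counts.

**Cohorts.** The cohort generator reproduces the summary statistics of a
51-control / 45-patient contrast: normal marginals (truncated to physical
ranges via CDF mapping) for variables reported as mean +/- SD, log-normal
marginals solved from the median and IQR (`sdlog = asinh(IQR / 2 median) /
z_0.75`) for the skewed ones, tied through a Gaussian copula whose single
nonzero entry is the remodelling-index/RV-direct-flow correlation -0.624.
Component percentages are sampled as marginals — their medians sum to
about 100 but individual rows need not, so the generator tests the
statistics stage, not the partition invariant (the tracing pipeline owns
that). Patient risk grades are drawn 0.40/0.45/0.15 over low/intermediate/
high, male fractions 17/51 and 7/45, matching the cohort description. A
`null_effects` switch samples both groups from the control marginals for
size studies. Given a seed, generation is bit-reproducible.

None of the synthetic data models acquisition physics: no velocity noise
beyond an optional Gaussian, no phase wraps, no eddy-current offsets, no
wall-motion interplay with flow. Passing the phantom suite shows the
numerics are right, not that segmentation-quality effects in real data are
small.

## Problem sizes and calibration results

The shipped tests and the acceptance script run the two-channel phantom at
its full 20x20x40x30 size (8000 seeds), 2000 null simulations each for the
DeLong and nested-logistic size checks at n = 96 (both land near 5%), 500
stepwise-selection seeds, 200 planted-contrast cohorts, and 100
random-table AUC/U identity checks — sizes chosen so the whole battery
re-runs in a few minutes on one core.

One calibration result deserves honesty rather than adjustment: with
planted standardized effects 0.6 and 0.2 among 5 decoys at n = 96, the
probability that stepwise selection returns *exactly* the two planted
variables is capped near 0.87-0.90 regardless of the noise level, because
the univariate screen tests the weaker signal against a residual inflated
by the stronger one (power at most `Phi(0.2 sqrt(96) / 0.6 - 1.96) ~ 0.90`
even at zero noise), and decoy false inclusion multiplies in. At the
frozen benchmark noise (SD 0.25) the measured exact-support rate is about
81%, with both true signals recovered in ~83% and coefficient bias well
under 10%. The corresponding test asserts a 90% target and is expected to
fail; it is retained deliberately as a statement about the selection
procedure's attainable operating characteristics, not softened to pass.

## Known limitations

* Entry/exit detection is mask-based; chambers whose segmentation clips
  the valve planes will misattribute boundary-grazing particles.
* Fixed-step RK4 with frame-resolution recording can miss sub-frame
  excursions shorter than one frame interval; the dwell parameter operates
  at frame resolution.
* The stepwise procedure inherits the known biases of p-value-driven
  selection (overfit R^2, post-selection CIs without adjustment); it is
  provided to mirror the conventional analysis, not as best practice.
* Log-normal marginals matched to median/IQR are a modelling choice for
  skewed variables; real distributions may be heavier-tailed.
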