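---
title: "Phase-cycled bSSFP sodium MRI of the inner ear: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-cycled bSSFP sodium MRI of the inner ear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodiumear)
```

## The problem

Endolymphatic hydrops (EH) — the expansion of the inner ear's endolymphatic
space into the surrounding perilymph — is the pathological hallmark of
Ménière's disease. The two fluid compartments differ enormously in sodium
content: endolymph carries about 1.3 mM of sodium against roughly 141–148 mM
in perilymph. A sodium (^23^Na) MRI sequence sensitive enough to read the
inner ear should therefore see a hydropic ear as *darker* than its normal
partner, without any gadolinium contrast.

`sodiumear` implements that analysis chain end to end as testable code:
a digital temporal-bone phantom, a phase-cycled balanced steady-state free
precession (bSSFP) acquisition model with a non-Cartesian readout,
frequency-offset-sweep reconstruction with F-state combination,
landmark-based thin-plate-spline fusion to structural imaging, and ROI
quantification with an ordinal (Likert) laterality decision rule and
inter-observer agreement statistics. Everything runs from seeds; no patient
data is required or used.

## The phantom

`build_phantom()` voxelises two mirror-symmetric ears: an ellipsoidal
vestibule, a conical-spiral cochlea and an elongated fluid-filled internal
auditory meatus (IAM) per side, embedded in bone with a midline brain slab.
Geometry is parametric solid modelling rather than anatomical meshes: at the
2 mm acquisition resolution only ROI-scale statistics are observable, so
surface fidelity buys nothing. The default sizes put the cochlea mask near
99 mm³ and the vestibule near 33 mm³, inside the ranges human observers
reported when segmenting these structures (63–110 mm³ and 31–59 mm³).

Each tissue class takes its sodium concentration from a versioned
compartment table (`compartment_table()`): endolymph 1.3 mM, perilymph and
CSF 145 mM (midpoint of the physiological 141–148 mM range), brain 40 mM,
bone and air 0. No ^23^Na relaxation times for inner-ear fluid have been
published, so the T1/T2/T2* columns are declared assumptions, chosen so that
fluid T2* (50 ms) is much longer than the 2 ms readout while brain-tissue
T2* (3 ms) is comparable to it — the regime in which readout decay visibly
broadens the point spread function.

The hydrops model is a single per-side fraction `h` in [0, 1]: the fraction
of that side's inner-ear fluid voxels (cochlea + vestibule) assigned to
endolymph, growing outward from each structure's endolymphatic core. The
assignment conserves the total fluid voxel count exactly, so `h` moves
*composition*, not volume — which is the physiology of hydrops. A normal ear
defaults to `h = 0.25`; `h = 1` is complete replacement of the inner-ear
fluid by endolymph, which the severe cases in this disease category show in
the vestibule. The left-side selection is computed on the right-side masks
and mirrored, so equal fractions give exactly mirror-symmetric maps — the
property several tests lean on.

The off-resonance (B0) map is a seeded low-order random polynomial (60% of
the amplitude bound, default 150 Hz) plus a Gaussian-blurred perturbation at
bone–fluid boundaries, clamped to the bound. The ±150 Hz default spans the
reconstruction sweep range (−100 to +200 Hz) and, against the 1/TR ≈ 70 Hz
banding period, guarantees several bands cross the field of view.

## The acquisition model

`bssfp_signal()` is the standard bSSFP steady state with the RF
phase-cycling increment folded into the effective per-TR precession angle

$$\theta = 2\pi f\,\mathrm{TR} - \Delta\varphi,$$

evaluated at the echo with T2 decay and off-resonance phase accrued to TE.
The closed form was validated against a brute-force Bloch iteration (3000
TRs of rotation matrices) to ~10⁻¹³ relative in magnitude; the test suite
keeps a 1% tolerance version of that oracle. Banding follows from the
magnitude's periodicity in `f` with period 1/TR; incrementing the RF phase
by Δφ per cycle displaces the band minima by (Δφ/360)/TR Hz, which is the
property phase cycling exploits: five cycles at 72° increments spread the
nulls uniformly across one period.

Sequence defaults are the study protocol: TR 14.26 ms, TE 1.06 ms, flip 25°,
1 ms RF pulse, 2 ms readout, 2 mm isotropic resolution, 240 mm field of
view, 5 phase cycles. The number of readouts per cycle is not published;
`scan_time()` reports the implied count for a given cycle duration (≈26,000
readouts for a 6.24 min cycle) without asserting it.

`make_trajectory()` supports three kinds. `cones` approximates a 3D cones
readout — cone polar angles uniform in cos θ, an Archimedean spiral-out from
k = 0 within each cone, samples uniform in time over the readout — since the
published sequence cites the trajectory family without parameters. `radial`
is a golden-spiral-direction kooshball, and `cartesian` enumerates the full
grid with zero timestamps, serving as the exact-FFT oracle path. Density
compensation is analytic |k|²-proportional weighting for both non-Cartesian
kinds (their sample density scales as 1/|k|² for uniform-in-time centre-out
readouts), with a small floor at k = 0 and global normalisation so the
adjoint of a point source gives a unit centre peak; a Voronoi-cell weighting
was considered and set aside because no computational-geometry backend is
part of the package's dependency set and the analytic weights already pass
the point-response criterion.

`sample_kspace()` is the forward model: per cycle, the voxelwise steady
state with the voxel's off-resonance; during the readout, phase evolution
exp(+i2πft) and T2* decay, implemented by time-segmenting the readout into
`n_time_bins` bins (default 4) and transforming each bin's modulated image
only at that bin's samples. Complex Gaussian noise is added per sample from
an explicit seed. Linearity in m0, conjugate symmetry for offres-free real
phantoms, and agreement with a direct Fourier-sum oracle are tested.

## Reconstruction

The nonuniform transform is Kaiser–Bessel gridding at 2× oversampling with
a width-6 kernel (Beatty's β), with the apodization correction computed
numerically as the DFT of the sampled kernel; accuracy against a direct
nonuniform DFT is ~10⁻⁵ relative, and exact FFT evaluation is used whenever
every coordinate lies on the image's DFT grid (Cartesian trajectories). The
spreading/interpolation inner loops are C++; FFTs are R's.

`reconstruct_cycle()` first demodulates the samples by exp(−i2πf₀t) using
the per-sample timestamps — the demodulation must act in k-space, because
readout-time phase evolution is what blurs off-resonant structures, and a
post-hoc image phase cannot undo it — then applies either the
density-weighted adjoint or conjugate gradients on the
density-weight-preconditioned normal equations (defaults: tolerance 10⁻⁶,
20 iterations, both unspecified by the source protocol; non-convergence
attaches a visible warning status). The CG path is single-coil: the
32-channel receive hardware of the original study is out of scope, and a
uniform sensitivity keeps the operator self-adjoint.

`combine_fstates()` computes, per order n, the discrete Fourier sum over
cycles Σ data_Δφ e^(−iΔφn) with **no** 1/N normalisation — matching the
combination expression as printed. With N cycles and all N orders the
transform is invertible (Parseval: Σₙ|Fₙ|² = N·Σ|data|², tested to machine
precision). The composite is the root sum of squares of the retained orders
{−1, 0, +1}. The per-offset order of operations (reconstruct cycles →
F-states → composite, per offset, then stack) is not stated by the source;
it is fixed here as described and the stack's fourth dimension is ascending
offset in Hz.

`select_offset()` automates the subjective per-ear choice of the sharpest
sweep frame: the score is the sum of squared finite differences over the
(one-voxel-dilated) ROI normalised by the squared ROI mean, with ties broken
toward the lowest offset index. On a phantom with uniform off-resonance the
argmax falls on the true frequency.

`psf_probe()` reconstructs a centred point source with readout T2* decay
and reports the interpolated FWHM of the central profile. With ideal
Cartesian sampling and no decay it returns the nominal 2 mm; finite T2*
broadens it monotonically. The study's own 2.88 mm estimate cannot be
recomputed without the unpublished T2* assumption and exact cones
parameters, so only the direction and monotonicity are asserted.

## Registration

`fit_tps()` is an interpolating 3D thin-plate spline (kernel |r|, zero
regularisation — the workflow being mirrored interpolates rather than
approximates) fitted to 9–16 landmark pairs in world millimetres; duplicate
or coplanar/colinear source points raise named errors. The fitted map takes
fixed-space (structural) coordinates to moving-space (sodium) sample
locations, i.e. pull-back resampling; the reverse direction is available
for transferring structural-grid masks to the sodium grid. `resample()`
interpolates trilinearly for intensities and nearest-neighbour for labels,
zero-filling outside the field of view; `transfer_masks()` reports voxel
counts and mm³ before/after and warns when a structure leaves the FOV — at
2 mm the vestibule survives as only a handful of voxels, matching the
observers' experience.

## Quantification and the laterality rule

`roi_stats()` gives mean/SD/median over a mask (even-count medians are the
midpoint of the central pair). `scale_to_iam()` divides an inner-ear median
by the adjacent IAM median; the quotient is invariant under any global gain,
which is the point of IAM scaling. `between_ear_ratio()` averages the
observers' medians per ear *before* forming the normal:hydropic quotient and
rounds half-up to 1 decimal, the convention of the published tables
(`round_half_up()`, since R's own rounding is to-even).

`classify_laterality()` encodes the ordinal decision rule: visibility of
each inner-ear structure relative to the ipsilateral IAM fundus, compared
between sides; a relative-visibility difference of ≥2 grades gives definite
laterality, exactly 1 gives possible, and the structure must have anatomical
compatibility ≥2 *on its better-seen side* to be eligible. The printed rule
text asks for compatibility ≥2 "on both sides", but that reading contradicts
several of the published calls (definite calls where the contralateral
structure is invisible with compatibility 0); the better-seen-side gate
reproduces all 16 published calls and is therefore the implemented
interpretation. Eligible structures indicating opposite sides at equal
certainty return "none" — a conservative tie-break the published data never
exercises.

`icc_agreement()` is the two-way random-effects absolute-agreement ICC from
the mean-squares decomposition, with both single-measures and
average-measures forms exposed because the source analysis does not name its
form. On the printed 1-dp medians the average-measures form gives 0.689
(single 0.526), within rounding distance of the published 0.70 computed from
unrounded data; the implementation itself is pinned to a from-scratch ANOVA
oracle at 10⁻¹⁰ on random matrices. The ICC's 95% confidence interval is an
explicit non-goal (the interval method is unstated).

`grade_visibility_auto()` closes the simulation loop that human observers
close in practice: grade 0 below the reference noise floor (background mean
+ 2 SD), otherwise 1/2/3 for ROI:reference median ratios <0.8 / 0.8–1.25 /
>1.25 ("decreased / similar / increased"). Simulated masks are exact, so
the automatic assessments set compatibility 3 for any visible structure,
making the laterality rule visibility-driven.

## Study conditions and what the simulations show

The end-to-end experiments (`lateralisation_experiment()`) run at an
inner-ear ROI SNR of about 5 — SNR defined as the normal-side inner-ear
median composite over the background composite SD, with the k-space noise
calibrated per phantom by `calibrate_noise_sd()` (background composite noise
is exactly linear in the k-space noise SD, so one unit-noise probe
reconstruction fixes the scale). Under those conditions, severe left-sided
hydrops (fractions 0.7–1.0) reads darker on the left in 10/10 seeds, the
automatic grade of the hydropic side never exceeds the contralateral one,
and the right:left median ratio rises monotonically with the hydrops
fraction (0.77, 1.06, 1.50 at fractions 0, 0.5, 1 under the default
configuration — below 1 at fraction 0 because the "normal" right ear itself
carries 25% endolymph).

Problem sizes: the test suite and the analysis drivers voxelise the phantom
at 2 mm over a 96 mm field of view (48³ truth grid, matching the
acquisition resolution) with 1,500 radial readouts — sizes chosen so the
whole suite runs in minutes while leaving every mechanism (banding,
off-resonance blurring, PSF bleed between the tiny inner ear and the bright
IAM, noise-floor grading) active. The phantom defaults remain 96³ at 1 mm,
separating truth from acquisition resolution, and are used where geometry
fidelity matters (volume checks, segmentation).

What the synthetic data does **not** emulate: participant motion (the
dominant artefact in the original studies), coil-array sensitivity
structure, quadrupolar/biexponential sodium relaxation, scanner drift, and
observer variability in mask drawing (masks are transferred exactly).
Passing tests therefore demonstrate that the *pipeline* recovers the
engineered contrast under realistic noise, banding and resolution — not that
the method is clinically validated.

## Numerical choices and degenerate inputs

* Gridding: 2× oversampling, width-6 Kaiser–Bessel, numerical apodization;
  exact-FFT path on on-grid coordinates (tolerance 10⁻⁶ grid units).
* CG: relative-residual tolerance 10⁻⁶, 20 iterations, warning (not
  silence) on non-convergence.
* Sharpness ties break to the lowest offset index; `which.min`-style
  determinism throughout.
* Endolymph assignment ties break by voxel index; fractions are rounded to
  whole voxels.
* Degenerate ICC input (zero variance everywhere) returns 1 with a warning;
  empty masks, non-positive IAM medians, invalid grades, unknown
  configuration keys and missing upstream stage artifacts are all hard
  errors.
* Seeds: one global seed expands into per-stage substreams through a fixed
  linear-congruential map (`stage_seed()`), keeping every derived seed below
  2³¹.

## Known limitations

The cones trajectory is a documented approximation to an unpublished
design; absolute signal units are arbitrary (only ratios and
IAM-scaled quantities are interpreted); the automatic visibility grading is
a stand-in for human perception and is deliberately coarse; and the
IAM-scaled between-ear ratios recomputed from rounded per-observer values
need not match ratios computed from unrounded data, so only the unscaled
ratio columns are asserted against the published tables.
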