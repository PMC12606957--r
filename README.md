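# sodiumear

Simulation and analysis of phase-cycled bSSFP sodium (²³Na) MRI of the
inner ears, for lateralising endolymphatic hydrops (EH) in unilateral
Ménière's disease.

Endolymph contains ~1.3 mM sodium; perilymph ~141–148 mM. When hydrops
expands the endolymphatic space into the perilymph, the affected inner ear
should return *less* ²³Na signal than its partner — a contrast-agent-free
signature of the disease. This package implements the full chain needed to
study that idea quantitatively, driven entirely by a seeded digital
temporal-bone phantom (no patient data):

* **phantom** — parametric cochlea/vestibule/IAM geometry per side, a
  compartmental sodium/relaxation table, a per-side hydrops fraction that
  converts perilymph to endolymph at constant fluid volume, and a smooth
  seeded off-resonance (B0) map;
* **acquisition** — bSSFP steady state with RF phase cycling folded into the
  effective precession θ = 2π·f·TR − Δφ (TR 14.26 / TE 1.06 ms, flip 25°,
  2 mm, 5 cycles at 72°), 3D cones / radial / Cartesian trajectories with
  per-sample timestamps, T2* decay and off-resonance phase during the
  readout, seeded complex noise;
* **recon** — Kaiser–Bessel gridding NUFFT (plus conjugate-gradient
  solution of the normal equations), per-offset demodulation over the
  −100…+200 Hz sweep (20 Hz steps, 16 frames), F-state combination
  data(Fₙ) = Σ_Δφ data_Δφ·e^(−iΔφn), root-sum-of-squares composite, 4D
  `[X Y Z offset]` NIfTI stacks, automated sharpest-offset selection, and a
  point-spread-function probe;
* **registration** — interpolating 3D thin-plate-spline (kernel |r|) fitted
  to 9–16 landmark pairs in world mm, pull-back resampling, mask transfer
  with volume reporting;
* **quantify** — ROI statistics, inner-ear medians scaled to the adjacent
  internal auditory meatus (IAM), observer-averaged normal:hydropic ratios
  (half-up 1-dp rounding), the Likert-grade laterality decision rule,
  two-way random-effects absolute-agreement ICC, cohort summaries,
  threshold segmentation and automatic visibility grading.

The published grade and median tables of the motivating study ship as
plain-text fixtures under `inst/extdata/` and are reproduced exactly by the
code (see below).

## Worked example

The numbered drivers under `analysis/` run the whole workflow on a severe
left-sided hydrops phantom (complete endolymphatic replacement on the left,
a normal 25%-endolymph right ear, inner-ear ROI SNR ≈ 5):

```sh
Rscript analysis/01_build_phantom.R
Rscript analysis/02_acquire_kspace.R
Rscript analysis/03_reconstruct_sweep.R
Rscript analysis/04_register_fuse.R
Rscript analysis/05_quantify_lateralise.R
Rscript analysis/06_report_tables.R
```

`05_quantify_lateralise.R` prints, for the default seed:

```
ROI statistics (composite, sharpest frame per ear):
  structure  side mean    sd median voxel_count volume_mm3
1 inner_ear  left  172  51.2    179          17        136
2       iam  left  455 108.6    440          59        472
3 inner_ear right  336  68.7    353          17        136
4       iam right  475  86.2    491          59        472
IAM-scaled medians: left 0.41, right 0.72
Normal:hydropic (right:left) median ratio: 1.97
Laterality call: possible / left (deciding structure: cochlea)
```

The hydropic left inner ear returns roughly half the median composite
signal of the right (ratio 1.97, inside the 1.9–2.9 range the study reports
for severely hydropic vestibules), its IAM-scaled median drops to 0.41
versus 0.72 on the normal side, and the automatic Likert grading calls the
left side hydropic. The ten-seed parameter-recovery table that follows
shows the hydropic side darker in 10/10 seeds and the between-ear ratio
rising monotonically (0.77, 1.06, 1.50) as the left hydrops fraction moves
through 0, 0.5, 1.

`06_report_tables.R` re-derives the published-table analyses from the
bundled fixtures:

```
  lateralised by both observers post-registration: 3/4 (A, C, D)
  lateralised by both observers pre-registration:  1/4 (C)
  wrong-side calls: 0
  cochlea ratios:   1.5, 0.8, 1.2, 1.3
  vestibule ratios: 2.1, 0.8, 1.9, 1.1
  ICC: average-measures 0.689, single-measures 0.526
  Cohort: n=4, mean age 60.3 y, mean symptom duration 16 y
```

See `vignettes/sodium-mri-hydrops.Rmd` for the models, parameter defaults,
numerical choices and limitations.

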