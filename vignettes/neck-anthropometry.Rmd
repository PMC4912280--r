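---
title: "Volumetric neck anthropometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric neck anthropometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neckct)
```

# The measurement model

`neckct` treats a neck CT as a scalar Hounsfield-unit (HU) field on a
regular anisotropic lattice. All anatomy enters through a
`landmark_set`: physical axial levels (mm, cranial = increasing z) of
the orbit roof, sternal angle, hard palate, first tracheal ring, the two
cross-sectional-area levels (soft-palate tip, thyroid cartilage), the
lateral mid-clavicular bounds, and one seed point inside the airway
lumen. Landmarks are *inputs* — read from a phantom manifest or a
human-annotated JSON; automatic landmark detection is out of scope.

Three tissue definitions do all the work:

**Adipose voxels** are those with HU in the closed window
$[-150, -30]$ whose centers lie inside the crop box. The window is
stated in the literature as a "width" of −150 and −30 HU with center
−90; a width cannot be two numbers, and the only reading consistent
with both values is the closed interval $[-150,-30]$, whose midpoint is
−90. Boundaries are inclusive — a voxel at exactly −150 HU is fat — so
tests can be bit-exact. NATV is the voxel count times the physical
voxel volume (1 cc = 1000 mm³).

**The airway** is the 26-connected component of $\{HU \le -500\}$
containing the seed, computed inside the axial clip
$[z_{\text{tracheal ring}}, z_{\text{hard palate}}]$ (slice centers at
the bounds included, so "until and including the first tracheal ring"
holds). −500 HU is far from both the lumen (≈ −1000) and any soft
tissue (≥ −150): under 20-HU noise a misclassified voxel would need a
25-sigma excursion. Restricting the component search to the clip also
realizes the oropharynx exclusion purely as a z-clip, and keeps ambient
air outside the patient from being annexed through slices beyond the
clip. The clinical workflow this automates was semi-automatic (manual
seed regions with manual correction); the escape hatch we preserve is
that any externally produced NIfTI mask can be loaded with
`load_mask()` and combined with the automatic one before
`mask_volume_cc()`.

**The body contour** of a slice is the largest 8-connected component of
$\{HU \ge 0\}$ with interior holes filled. Hole-filling makes the area
invariant to internal air — the airway lumen counts toward neck area —
and taking the largest component drops disconnected satellites,
operationalizing the manual exclusion of ear cartilage. Whether a real
tracing counts internal air is not stated in the source description;
the filled-contour semantics is our fixed choice. NCSA on a 5-mm slab
is the **mean** per-slice area (an areal quantity from a thick slice),
over all slices whose centers fall in the closed slab interval.

`quantify_scan()` composes the three stages and fails whole — a stage
error aborts the scan with the stage named, because a silently partial
row would corrupt a cohort table.

# The phantom: a stated world

Every structure in a `phantom_spec` has a closed-form volume: ellipsoid
$\frac43\pi abc$, elliptic cylinder $\pi a b h$, annular shell
$\pi(a_ob_o - a_ib_i)h$ scaled by the kept sector, and a tube of
per-slice circular cross-section $\pi r^2 L$ (exact even when the
centerline bends sinusoidally, because each axial section remains a
disc). Voxel membership is decided by voxel-center inclusion with no
partial-volume weighting, so the voxelized mask volume differs from the
analytic value only by a surface term that shrinks with spacing; at
1 mm isotropic spacing and structure radii ≥ 20 mm the relative error
stays well under 1.5% (measured: ≤ 0.6% for fat, ≤ 0.9% for the airway,
≤ 0.15% for NCSA across ten phantom seeds).

`default_cohort_spec()` encodes the reference cohort as the stated
world: analytic fat volume within ±10% of the class anchors 444 / 689 /
864 cc (median NATV of the normal-or-underweight, overweight and obese
WHO classes), airway volume near the cohort mean 23.6 cc, body
semi-axes chosen so the upper NCSA is of the order of the reported
22,579 mm² mean, and default spacings mirroring the two scan protocols
(sub-millimetre in-plane; 2 mm and ~1 mm slice variants). Fat is split
across the three infrahyoid compartments — subcutaneous shell 55%,
posterior ellipsoid 27%, perivertebral ellipsoid 18% — with all
compartment radii ≥ 20 mm. The subcutaneous shell carries a 35° sector
gap at the posterior midline: a closed fat annulus would disconnect the
skin from the deep tissues and make the "largest component" body
contour degenerate, which real necks avoid by myofascial bridges; the
gap keeps the analytic shell volume exact (sector measure) and the
phantom topologically realistic.

Noise is additive Gaussian, clipped to the CT range [−1024, 3071] HU
(nothing in the source describes noise; 20 HU is the level the
validation suite uses, ≥ 3 SD from both window edges for −90 HU fat).
Noise never alters the ground-truth masks, which are geometric.
`accuracy_phantom_spec()` is the same construction with a 20-mm airway
tube: the tube radius is the one structure whose realistic size
(~7–8 mm) is below the 20-mm radius bound of the voxelization-accuracy
statement, so the accuracy family trades airway realism for a uniform
bound; the realistic tube's ±2% recovery is tested separately.

What the phantom does **not** emulate: partial-volume blur at tissue
interfaces, beam hardening, metal and motion artifacts, contrast
enhancement, anatomic curvature of the neck axis, and inter-slice
overlap of thick-slice reconstructions. A green phantom suite therefore
establishes that the *geometry and arithmetic* of the pipeline are
right — not that the HU window generalizes to scanner data.

# Statistical conventions

- **ICC** is fixed to ICC(A,1) — two-way random effects, absolute
  agreement, single measures — the standard form for two
  interchangeable observers, computed from the two-way ANOVA mean
  squares with the F-based 95% CI. An all-identical table is degenerate
  and reports ICC 1 with a warning.
- **Bland–Altman**: bias = mean(obs1 − obs2), limits bias ± 1.96·SD, a
  one-sample t test for fixed bias (p = 1 at zero variance and zero
  bias, p = 0 at zero variance and nonzero bias, both documented
  conventions). The percent discrepancy is 100·|bias| / grand mean; the
  source reports two mutually inconsistent pairs of percentages without
  a formula, so this definition is fixed here and neither printed value
  is asserted anywhere.
- **Spearman** uses midranks and the large-sample t approximation;
  **Mann–Whitney** uses the exact distribution when tie-free and small,
  otherwise the tie-corrected normal approximation without continuity
  correction; **Kruskal–Wallis** is tie-corrected.
- **Quartile split**: type-7 (linear interpolation) 75th percentile,
  upper group inclusive of the threshold.
- **BMI**: right-open WHO intervals, 25.0 → overweight, 30.0 → obese.
- **Cox**: Breslow tie handling, Wald CI and p. A monotone likelihood
  in a small cohort is reported as a per-fit error entry in the cohort
  report rather than aborting the remaining analyses.
- **ICC sample size** uses the Bonett (2002) expected-CI-width
  approximation; at ICC 0.9, width 0.1, k = 2 it returns n = 57. The
  reference analysis reports 61 from closed-source software whose
  formula is unpublished; the method name is carried in the output so
  the discrepancy is attributable, and no test asserts 61.
- α = 0.05 two-sided is recorded in every report and never used to
  suppress output. No multiple-testing correction is applied, matching
  the analysis being reproduced.

The cohort simulator plants effects on the *upper-quartile membership*
hazard (exponential event times, administrative censoring staggered
over 300–670 days, baseline rate solved in closed form from the target
null mortality of 6.9%). For parameter-recovery studies,
`simulate_survival_data()` offers binary and standard-normal covariate
designs: with 40% events at n = 1000 the binary design leaves
SE(β) ≈ 0.10, so a ±0.15 recovery band is only ~1.5 SE and would fail a
correct implementation half the time over 20 seeds; the normal design
(SE ≈ 0.05) makes the same band a sound acceptance check. Both are
exposed; the validation suite uses the normal design for the 20-seed
recovery criterion and the binary design for single-seed unit checks.

# Numerical and I/O choices

- NIfTI-1 is the canonical interchange format (hand-written reader and
  writer; no NIfTI package exists in the supported dependency set).
  Volumes default to float32 on disk — exact for integer HU — with a
  float64 option for arbitrary values; masks are uint8. Scale
  slope/intercept are applied once on load and written back as 1/0, so
  calibration is idempotent. Header spacing is float32 by the format,
  so a 1.2-mm spacing round-trips to ~1e−7 relative.
- DICOM reading supports explicit/implicit-VR little-endian
  uncompressed 16-bit series; slices are sorted by the patient-space z
  of ImagePositionPatient (cranial = increasing), and missing rescale
  tags are a calibration error, not a silent default.
- Axis convention: axis 3 is cranio-caudal, increasing = cranial;
  voxel indexing is 1-based in R with physical centers
  `origin + (index − 1)·spacing`; slab and crop intervals are closed.
- Connectivity: 26-connected in 3-D, 8-connected in 2-D foreground with
  4-connected background for hole filling — fixed for determinism.
- Reports are serialized with fixed JSON digits and no timestamps, so
  identical inputs give byte-identical outputs; every output carries an
  md5 hash of the canonical config JSON.

# Known limitations

Landmarks must be supplied; there is no automatic detection. The HU
window is a fixed global threshold — contrast-enhanced vessels, partial
volume at fat/muscle interfaces and beam-hardening streaks will bias
NATV on real data in ways the phantom cannot reveal. The lower NCSA
level is a single configurable landmark (`z_thyroid_cartilage`); the
source alternates between naming the hyoid and the thyroid cartilage
for it, and the package does not adjudicate. DICOM support is
read-only and deliberately minimal; compressed transfer syntaxes must
be converted to NIfTI upstream.
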