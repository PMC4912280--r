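# neckct — volumetric neck anthropometry from CT

Neck adipose tissue accumulation is a marker of metabolic syndrome and
cardiovascular risk, but neck circumference is a poor proxy for it:
the tape measure encircles muscle, bone and airway along with fat, and a
single axial slice cannot represent a structure whose fat shifts with
posture. `neckct` implements a reproducible 3-D alternative on
multidetector CT: it quantifies the **neck adipose tissue volume (NATV)**,
the **airway volume (AWV)**, their prognostic ratio **NATV:AWV**, and the
**neck cross-sectional area (NCSA)** at two anatomic levels, then runs the
full cohort-level statistical analysis that such a study requires —
interobserver agreement, correlation with BMI, and survival stratification.

## Method

All quantities are computed inside anatomic margins given as physical
landmark positions (mm):

- **NATV** — voxels with HU in the closed adipose window
  **[−150, −30]** (center −90 HU), cropped cranio-caudally from the roof
  of the orbit to the sternal angle and laterally between the
  mid-clavicular bounds:

  `NATV = |{v : −150 ≤ HU(v) ≤ −30, v ∈ crop}| · vx·vy·vz / 1000` (cc)

- **AWV** — the 26-connected component of `{HU ≤ −500}` grown from a seed
  point in the lumen, clipped from the hard-palate level down to and
  including the first tracheal ring.
- **NCSA** — the filled body contour (largest 8-connected tissue
  component per slice, interior holes filled so the air lumen counts,
  disconnected ear-like satellites dropped) averaged over a 5-mm axial
  slab at the soft-palate and thyroid-cartilage levels (mm²).
- **NATV:AWV** — the dimensionless ratio; cohorts are stratified at its
  75th percentile and compared by Kaplan–Meier/log-rank and by crude and
  age/sex-adjusted Cox regression (Breslow ties). Interobserver
  reproducibility is summarized with ICC(A,1) (two-way random, absolute
  agreement, single measures) and Bland–Altman limits `bias ± 1.96·SD`.

Because no patient scans ship with the package, a **phantom generator**
builds neck-like CT volumes (soft-tissue body +40 HU, three fat
compartments at −90 HU, an air tube at −1000 HU, a bone column, optional
Gaussian noise) whose fat, airway and cross-sectional ground truth is
known in closed form (ellipsoid 4/3·π·abc, cylinder π·a·b·h, tube π·r²·L),
so every pipeline stage is validated against analytic truth.

## Worked example

```r
library(neckct)

spec <- default_cohort_spec("obese", seed = 7)   # analytic NATV ~864 cc class
ph   <- generate_phantom(spec)
quantify_scan(ph$volume, ph$truth$landmarks, run_config(),
              patient_id = "obese-07")
#> <volumetric_result> obese-07: NATV 908.6 cc, AWV 23.4 cc, NATV:AWV 38.8
#>   NCSA upper 20817 mm^2, lower 20817 mm^2
ph$truth$fat_volume_cc      # analytic truth: 897.8 cc  (error ~1.2%)

cohort <- simulate_cohort(n = 519, upper_quartile_hr = 2, seed = 11)
pairs  <- simulate_observer_pairs(cohort$natv_cc[1:70], seed = 12)
run_cohort_analysis(cohort, list(natv = pairs))
#> <cohort_analysis> n = 519
#>   median NATV 668 cc, AWV 24.0 cc, NATV:AWV 27.8
#>   agreement[natv]: ICC 0.9988 (0.9979-0.9993), bias 4.21 cc
#>   NATV~BMI Spearman rho 0.667 (p 3.97e-68)
#>   upper quartile: 130 of 519; deaths 13 vs 21; log-rank p 0.0504
#>   upper-quartile HR 1.97 (95% CI 0.99-3.93, p 0.0549)
```

The NATV of the measured phantom lands within the voxelization bound of
its analytic value; the simulated cohort, generated with a true
upper-quartile hazard ratio of 2, returns an estimate (1.97) whose 95%
confidence interval covers the truth. `icc_sample_size(0.9, 0.1, 2)`
plans the agreement substudy (n = 57 with the Bonett expected-width
approximation).

A command-line wrapper covers the same pipeline:

```sh
Rscript inst/cli/neckct.R phantom  --out ph1 --size-class obese --seed 7
Rscript inst/cli/neckct.R quantify --ct ph1/volume.nii.gz \
    --landmarks ph1/landmarks.json --out results.csv
Rscript inst/cli/neckct.R analyze  --cohort cohort.csv --pairs pairs.csv \
    --out report/
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch: it generates a
phantom cohort, quantifies every scan from the written NIfTI files,
simulates a 519-patient cohort with a 70-scan observer-pair substudy, and
runs the complete agreement/correlation/survival analysis, writing the
target report to `--out`.

See `vignettes/neck-anthropometry.Rmd` for the model assumptions,
parameter choices, numerical conventions and known limitations.
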