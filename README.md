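# handquant

Quantification of hand muscle volume and intramuscular fat from MRI.

Inflammatory joint diseases — rheumatoid arthritis in particular — are
accompanied by loss of skeletal muscle that standard anthropometry misses:
most patients keep a normal BMI because muscle is replaced by fat
(rheumatoid cachexia). Quantitative imaging of the hand, the region these
diseases attack first, offers a sensitive window on that process.
`handquant` implements a complete, deterministic analysis pipeline for
paired T1-weighted and two-point Dixon hand MRI, aimed at researchers in
musculoskeletal imaging and imaging biomarker development, together with
synthetic phantom and cohort generators so that every stage can be
validated without patient data.

## Pipeline

For each subject, starting from a T1-weighted volume `I` (and optionally a
Dixon water/fat pair `I_water`, `I_fat`):

1. **Bias-field correction.** MRI intensities are modulated by a smooth
   multiplicative field `b`: `I = b * I_true`. The field is estimated in
   the log domain as a low-order polynomial surface fitted over the
   dominant tissue by iterative robust reweighting, then divided out
   (normalised so the global mean is preserved).
2. **Hand cross-sectional area.** Per slice: automatic threshold (Otsu
   scaled to capture dark tissue above the air floor), morphological
   closing, hole filling, minimum-area filtering. The union over slices is
   the hand mask.
3. **Muscle segmentation.** A random-forest classifier labels every hand
   voxel muscle/background from neighbourhood features (intensity, local
   mean/SD, multi-scale smoothed intensity, gradient magnitude, distance to
   the hand boundary, slice position). The voxels classified as muscle form
   the muscle volume of interest (VOI).
4. **Gaussian cleanup.** A Gaussian is fitted to the VOI's intensity
   histogram; voxels outside `mean ± 2 SD` are removed. This strips
   hypointense tendons/ligaments and hyperintense vessels that leak into
   the VOI.
5. **Fat fraction.** `I_ff = I_fat / (I_water + I_fat) * 1000`, an integer
   map where 1 grey value = 0.1 % fat.
6. **VOI transfer.** A 6-degree-of-freedom rigid transform maximising
   mutual information between the T1 hand and `I_ff` maps the muscle VOI
   onto the Dixon grid (nearest-neighbour resampling).
7. **Output parameters**, accumulated between user-defined proximal/distal
   bounds of the third metacarpal: hand volume `V_H`, muscle volume `V_M`,
   relative muscle volume `V_M_rel = V_M / V_H`, fat volume
   `V_F = sum(voxel_volume * I_ff / 1000)` over the VOI, and relative fat
   content `V_F_rel = V_F / V_M`.

Reliability is quantified as reanalysis precision: per dataset the SD and
CV of repeated analyses, aggregated as root-mean-square averages (RMS-SD,
RMS-CV). Cohort statistics comprise linear models of `V_H` and `V_M_rel`
in age (or age³), BMI and diagnosis, adjusted group differences Δ averaged
over an age window, percent change across an age span, and decade-wise
one-way ANOVA with Tukey HSD.

## Worked example

```r
library(handquant)

clf <- train_phantom_classifier()           # RF trained on labelled phantoms
ph  <- generate_hand_phantom(phantom_spec(seed = 301))
res <- run_subject(ph$t1, clf, water = ph$water, fat = ph$fat,
                   seed = 2, scan_id = "demo")
res$metrics
#> <hand_metrics> V_H 60258.0 mm^3, V_M 16752.0 mm^3, V_M_rel 0.2780,
#>   V_F 1750.4 mm^3, V_F_rel 0.1047 [slices 6..17]
ph$truth$v_m_rel
#> [1] 0.2938863
```

The phantom's true relative muscle volume is 0.294; the pipeline estimate
(0.278) sits within the expected envelope: the ± 2 SD histogram cleanup by
construction removes the ~4.6 % intensity tails of genuine muscle, and the
recovered intramuscular fat content (10.5 %) matches the construction value
of 10 %. (Bounds were derived automatically from the hand mask here; they
can be supplied explicitly as `analysis_bounds(proximal, distal)`.)

Cohort-level analysis on a synthetic cohort mirroring a three-diagnosis
outpatient population:

```r
co  <- generate_cohort(cohort_spec(seed = 1))
fit <- fit_model(co, model_spec(response = "vmrel", sex = "male"))
group_difference(fit, c("RA", "Pso"))
#> <group_difference> RA - Pso: delta = -0.03996 (p = 9.37e-08), ages 20-80,
#>   adjusted for age
```

## Conventions

- Arrays are indexed `[slice, row, col]`; `spacing = (dx, dy, dz)` mm with
  `dz` the slice thickness. Slice indices are 0-based; analysis bounds are
  inclusive on both ends.
- All volumes and masks are read/written as NIfTI-1 (`.nii`/`.nii.gz`);
  masks use an integer datatype.
- See `vignettes/handquant-methods.Rmd` for the full methods description,
  parameter defaults and limitations.
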