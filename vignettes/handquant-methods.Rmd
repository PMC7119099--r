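---
title: "Methods: hand muscle and fat quantification from MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hand muscle and fat quantification from MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`handquant` quantifies hand muscle volume and intramuscular fat from paired
T1-weighted and two-point Dixon MRI. This vignette describes the model
behind each stage, the parameters that matter, the synthetic data the
package validates itself on, and the limits of that validation.

## Image model and bias-field correction

A T1-weighted acquisition measures `I(x) = b(x) * mu_t(x) + noise`, where
`mu_t` is the tissue-specific mean signal and `b` a smooth, strictly
positive multiplicative bias field caused by coil and B1 inhomogeneity.
Intensity-based segmentation needs `b` removed.

`correct_bias_field()` estimates `log b` as a polynomial surface (total
degree 3 by default) over normalised coordinates, fitted by least squares
to the log intensities of the *dominant* tissue. Dominance is established
by iterative robust reweighting: starting from all foreground voxels
(Otsu threshold), the field estimate is refined while the inlier set
shrinks to voxels within 2.5 MAD of the median corrected log intensity
(configurable via `bias_correction_config()`). Restricting the fit to one
tissue class is what prevents genuine tissue contrast from being absorbed
into the field — the standard failure mode of naive smooth-surface fits.
Two further numerical choices:

- The fitted log field is *clamped* to the range it attains over the
  foreground. A polynomial has no data support outside the hand and can
  extrapolate wildly at grid corners; correction only matters where tissue
  is.
- The field is normalised to unit mean and the corrected image rescaled to
  preserve the global mean exactly, so downstream intensity statistics are
  comparable before/after correction.

The correction is idempotent in practice (a second pass estimates a field
within 2% of unity) and leaves within-tissue variation at the noise floor.
A consequence worth knowing: dividing by a spatially varying field makes
the *noise* spatially varying, so corrected tissue histograms have
slightly heavier-than-Gaussian tails. This matters for the cleanup stage
(below).

## Hand cross-sectional area

The hand mask is built per slice: threshold, morphological closing (disc,
radius 3 voxels), hole filling, and removal of connected components below
50 mm². The automatic threshold is Otsu's value scaled by 0.25: Otsu on a
fat-suppressed hand slice locates the split between bright muscle and
everything darker; the scaled value keeps dark tissues (subcutaneous fat,
cortical bone, tendon) that still sit above the air floor. Because Otsu's
threshold transforms linearly with the intensities, the automatic mask is
exactly invariant to global intensity rescaling, and re-running the
extraction on the masked image reproduces the mask (both properties are
tested). A volume whose foreground/background Otsu split shows less than a
3:1 mean contrast is rejected as containing no segmentable signal rather
than silently producing a noise mask.

## Muscle segmentation

A random forest (100 trees, unlimited depth, class-balanced per-tree
sampling; `randomForest`) classifies every hand voxel from features of its
neighbourhood, computed in-plane per slice: raw intensity, box-filter
local mean and SD at radii 1–2 voxels, Gaussian-smoothed intensity at 1
and 2.5 mm, gradient magnitude, distance to the hand boundary, and the
normalised slice index. The feature set is configurable
(`feature_config()`); the classifier stores a fingerprint of the
configuration and refuses to predict under a different one, so a model can
never be silently applied to mismatched features. Training requires
labelled scans; `train_phantom_classifier()` builds a model from synthetic
phantoms with ground-truth labels.

The voxels classified as muscle form the muscle VOI. A final cleanup fits
a Gaussian to the VOI's intensity histogram (nonlinear least squares on
Freedman–Diaconis-binned counts, `minpack.lm`; median/MAD fallback if the
fit fails) and removes voxels outside the fitted `mean ± 2 SD`. The fitted
parameters — not the sample moments — define the band, since the operation
is defined by the Gaussian fit; with contaminated VOIs the fit locks onto
the muscle mode and the sample moments would not. The band retains 95.4%
of a perfect Gaussian, so on an *ideally* segmented VOI the cleanup itself
removes ≈4.6% of true muscle — plus a little more in real corrected
images because of the heavy-tail effect noted above. Muscle volume
estimates therefore carry a structural downward bias of roughly 5%; the
package documents rather than hides this, because the band is the
operation's definition. A VOI with fewer than 50 voxels is refused
(unreliable fit); a VOI with numerically zero spread is returned unchanged
and flagged.

## Dixon fat quantification and VOI transfer

The two-point Dixon pair yields the fat-fraction map
`I_ff = I_fat / (I_water + I_fat) * 1000`, an integer image on a 0–1000
scale (1 grey value = 0.1% fat). Air voxels (`water + fat = 0`) become 0
and are flagged in a validity mask instead of NaN, keeping the image
integer-valued.

The muscle VOI is determined on the T1 grid and must be transferred to the
Dixon grid. `register_rigid()` estimates the 6-parameter rigid transform
by maximising mutual information (32-bin joint histogram) between the
moving T1 volume and the fixed fat-fraction image. Design choices that
proved load-bearing:

- The metric's sample positions are the *fixed image's* hand voxels and
  never change with the parameters; out-of-volume moving samples read as
  zero. This keeps the objective smooth — re-selecting samples by overlap
  at every step creates discontinuities that trap the optimiser.
- The moving image is sampled unmasked. The hard zero edge of a masked
  volume biases the optimum along the slice direction by a substantial
  fraction of the (thick) slice spacing.
- Optimisation is multi-resolution (sample strides 4/2/1) with
  Nelder–Mead and simplex restarts, initialised by intensity-centroid
  alignment followed by a coarse joint sweep over in-plane rotation
  (±6°) and translation (±3–4 mm) — the dominant degrees of freedom for
  an axial stack.

On phantoms with known transforms the recovery error is below half a
voxel per axis and 1°. The VOI is resampled with nearest-neighbour
interpolation (masks must stay binary; linear interpolation is
deliberately rejected). `V_F_rel` uses the muscle volume recomputed on the
Dixon grid, so numerator and denominator share a grid.

## Output parameters and precision

`V_H` and `V_M` accumulate voxels between the proximal and distal bound
slices (0-based, inclusive on both ends — the simplest testable reading of
an interval marked on the third metacarpal). All volumes are exactly
voxel-count × voxel-volume representable. Reanalysis precision follows
densitometry practice: per dataset the SD (n−1 denominator, which matters
at 3 repeats) and CV of repeated analyses, aggregated as root-mean-square
averages across datasets; datasets with zero mean flag their CV as
undefined. Because the pipeline is deterministic, repeats are generated by
`perturb_for_reanalysis()` (small intensity noise plus a sub-voxel
in-plane shift), standing in for operator-to-operator variability.

## Cohort statistics

`fit_model()` fits OLS of `vh`/`vmrel` (or fat responses) on an age term
(age or age³ — the cubic variant reflects the association of grip strength
with age³), optional BMI and the diagnosis factor, with Pso as the default
reference level (the control condition). Records lacking BMI are dropped
only when BMI is in the model — the complete-case subset is explicit,
never silent. The adjusted group difference Δ is the difference of
model-predicted group means averaged over the age window; in the default
parallel-slopes model (chosen because a single age-averaged difference per
contrast is reported) this reduces to the factor-coefficient difference,
and its p-value comes from the corresponding linear contrast. Percent
change over an age window is anchored at the window's lower endpoint:
`100 * (pred(b) - pred(a)) / pred(a)`.

`decade_anova()` partitions ages into `[40,50)`, `[50,60)`, `[60,70)`,
`[70,80]` — left-closed with the final decade closed, a convention that
had to be fixed and is tested — and runs a one-way ANOVA across diagnoses
per decade with Tukey HSD pairwise comparisons (`stats::aov`,
`stats::TukeyHSD`). Decades without at least two groups of two or more
records are reported as not testable rather than erroring. The
significance threshold is 0.05 with no correction beyond Tukey.

## Synthetic phantoms

`generate_hand_phantom()` builds a schematic hand: a palm slab (ellipse
tapering from wrist to knuckles) containing four metacarpal "bones",
hypointense tendon rods, hyperintense vessel rods and a subcutaneous fat
rim, continued by four finger cylinders. The geometry is deliberately
schematic — the pipeline needs intensity contrast, slice-wise
connectivity and distractor structures, not anatomy. Two geometric choices
matter:

- The taper makes the cross-section change monotonically along the slice
  axis; without it the slab is extrusion-symmetric and the
  slice-direction translation of the rigid registration is nearly
  unidentifiable at 3 mm slice thickness.
- The tissue proportions give a relative muscle volume of ≈0.29 within
  the analysis bounds, in the physiological range for a hand.

Intensities are `tissue mean × bias field + Gaussian noise`; the bias
field is `exp(P)` for a random quadratic `P` scaled to a configurable
peak log-amplitude (default 0.25), matching the multiplicative model the
correction assumes. The Dixon pair is generated on its own coarser stack
(half the slices, centred on the palm, mirroring the shorter Dixon
coverage of clinical protocols) displaced by a configurable rigid
transform (default 2 mm/3°; the registration tests use 4 mm/5°). Dixon
truth labels are the nearest-neighbour resampling of the voxelised T1
labels under the stored transform — the two grids image the same discrete
object, so transfer oracles are exact. Water/fat satisfy
`fat/(water+fat) = true fat fraction` exactly before noise (muscle
default 10%).

The default grid is 96 × 96 × 24 at 1 × 1 × 3 mm — the clinical 320 × 320
× 64 at 0.5 × 0.5 × 3 mm geometry scaled down so a full phantom run takes
about two seconds; full-size generation is available through
`phantom_spec()`. Tissue intensity means and noise are free parameters
with arbitrary-unit defaults chosen for realistic contrast ordering
(tendon < fat < bone < muscle < vessel on fat-suppressed T1).

What the phantom does *not* emulate: partial-volume averaging beyond
nearest-neighbour voxelisation, relaxometry, motion, water–fat swaps and
coil-specific noise correlation. Consequently, passing phantom tests
demonstrates the pipeline's correctness — contracts, invariances,
recovery of known ground truth under the stated image model — not its
clinical accuracy on patient scans, which would require annotated real
data.

## Synthetic cohorts

`generate_cohort()` draws six sex-by-diagnosis groups with sizes
63/38/61/76/41/51 and age means 48/54, 56/56, 62/60 (SD 12/15, 14/11,
12/14), ages truncated to 20–80 years, mirroring a three-diagnosis
outpatient population. Responses follow linear-in-age models with
sex- and diagnosis-specific intercepts (stated at age 40) and slopes plus
i.i.d. Gaussian residuals; BMI is normal (26 ± 4) and observed for a
configurable fraction (default 206/330). Default effect sizes are of the
magnitude reported for inflammatory arthritis hands (RA about 0.04 lower
relative muscle volume than Pso in males; age-related losses of 13–30%
over four decades; residual SD 0.035). The generating coefficients are
attached to the table so estimator validation (coefficient recovery, CI
coverage, ANOVA type-I error) closes the loop against the truth.

## Problem sizes used in validation

The test-suite and acceptance properties run on: 10 default-geometry
phantom seeds for end-to-end volume recovery; single phantoms for
bias-correction and registration checks; 10⁵-sample histograms for the
cleanup oracle; 100 cohort replicates for CI coverage and 1000 for the
ANOVA null. These sizes were chosen so the full validation completes in a
few minutes on one CPU while keeping Monte-Carlo error well inside the
asserted bands.

## Known limitations

- The cleanup's structural ≈5% muscle-volume bias (see above) is inherent
  to the ±2 SD rule; comparisons across subjects analysed identically are
  unaffected.
- Manual editing of segmentations, part of clinical workflows, is out of
  scope; the automated path is the tested surface.
- Registration assumes the hand is rigid between the T1 and Dixon
  acquisitions; finger repositioning violates this and is not modelled.
- Fat-fraction values are not corrected for T1/T2* bias of the Dixon
  signal model.
- The cohort model is cross-sectional; age coefficients describe
  between-subject differences, not longitudinal change.
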