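Package: handquant
Title: Hand Muscle and Fat Quantification from MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying hand muscle volume and
    intramuscular fat from magnetic resonance images. T1-weighted volumes are
    corrected for the multiplicative bias field, the hand cross-sectional area
    is extracted slice-wise, hand voxels are classified into muscle and
    background with a random-forest voxel classifier, and the muscle volume of
    interest is cleaned by Gaussian histogram filtering. Paired two-point Dixon
    water/fat volumes yield a quantitative fat-fraction map onto which the
    muscle VOI is transferred by rigid multimodal (mutual information)
    registration. The package computes hand volume, muscle volume, relative
    muscle volume and intramuscular fat metrics between user-defined
    metacarpal bounds, reanalysis precision errors (RMS-SD and RMS-CV), and
    cohort-level statistics (age/BMI-adjusted linear models, adjusted group
    differences, decade-wise ANOVA with Tukey HSD). Synthetic hand phantoms
    and cohort generators with known ground truth make every stage testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    randomForest,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
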