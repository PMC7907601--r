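Package: phenogs
Title: Multi-Trait Genomic Prediction with Spectral Reflectance Secondary Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic and phenomic prediction pipeline for plant breeding
    trials: spectral reflectance indices computed from multiband canopy
    reflectance, augmented-block-design adjustment of plot phenotypes to
    genotype-level BLUEs, marker quality control and VanRaden genomic
    relationship matrices, and ridge-regression BLUP, covariate and
    multi-trait GBLUP models with restricted maximum likelihood variance
    components (profiled spectral REML and EM-REML). Includes replicated
    k-fold cross-validation, across-environment validation, and a nested
    association mapping (NAM) population simulator with known ground truth
    for calibration and testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, yaml
Suggests: testthat (>= 3.0.0), vcfR, lme4, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
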