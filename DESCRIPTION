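Package: brainage
Title: Brain-Age Modeling of Alzheimer's and Lewy-Body Co-Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how Lewy-body co-pathology
    accelerates brain aging in Alzheimer's disease. Generates synthetic
    MRI-like cohorts whose morphology encodes age, performs multi-layered
    volume quality control (robust intensity screening, PCA plus Mahalanobis
    distance, Isolation Forest), classifies biomarker subgroups from the CSF
    p-tau181/Abeta42 ratio and alpha-synuclein seed-amplification status,
    builds age-stratified train/validation/test splits, trains a 3D DenseNet
    brain-age regressor implemented natively in R with staged optimization,
    applies linear bias correction to the brain-age gap, computes gradient
    saliency maps with Gaussian smoothing and group difference maps, and fits
    longitudinal linear mixed models with BIC order selection and
    FDR-corrected pairwise contrasts for brain-age gap, ICV-normalized
    regional volumes, and cognition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    RNifti,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
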