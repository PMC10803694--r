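Package: lungdeform
Title: Lung Deformation Analysis by Elastic Registration of Paired
    Respiratory-Phase Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies regional lung deformation from paired
    inspiration/expiration 3D volumes. Provides a synthetic breathing-lung
    phantom cohort with closed-form ground-truth displacement, isotropic
    resampling and threshold lung segmentation, a deterministic demons-style
    deformable registration with oracle and external backends, Jacobian
    determinant deformation maps with volume-ratio normalisation and log
    transform, common-space mapping, group-average maps, the Jac-mean
    statistic, marked-deformation segmentation with a healthy deformation
    template and Dice overlap, registration quality control (IoU, landmark
    distances) with test-retest repeatability statistics (ICC(2,1),
    Bland-Altman limits of agreement), and clinical correlation analyses
    (composite physiologic index, group comparisons, Spearman correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils-grid.R'
    'volumes.R'
    'preprocess.R'
    'registration.R'
    'jacobian.R'
    'qc.R'
    'clinical-stats.R'
    'deformation-model.R'
    'phantom.R'
    'cohort.R'
    'pipeline.R'
    'io.R'
    'lungdeform-package.R'
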