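Package: dlradiomics
Title: Deep-Learning Radiomics for Three-Class Liver Lesion Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully reproducible pipeline for differentiating
    hepatocellular carcinoma (HCC), dual-phenotype HCC (DPHCC) and
    intrahepatic cholangiocarcinoma (ICC) from dual-phase contrast-enhanced
    MRI. Provides a synthetic tumor phantom generator with planted class
    structure, NIfTI volume I/O and preprocessing (0-255 normalization,
    histogram equalization, isotropic resampling, gray-level discretization),
    a 3-D radiomics engine (first-order, shape and GLCM/GLRLM/GLSZM/GLDM/NGTDM
    texture features on original and filter-derived images), Max-ROI 2-D slice
    extraction, pluggable deep-feature embeddings, ICC reproducibility
    filtering, LASSO one-standard-error feature selection, radiomics + deep
    feature fusion with Spearman correlation pruning, and multiclass
    one-vs-rest ROC evaluation with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    png,
    quadprog,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
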