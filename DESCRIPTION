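Package: tetvol
Title: Physician-Guided Volumetric Assessment of Metastatic Thymic Epithelial Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for volumetric assessment of metastatic thymic epithelial
    tumors (TETs) on 3D CT. Implements the two physician-guided cropping
    strategies used to focus a segmentation model on lesions of interest
    (box crops around individual tumors and a lung-relative 5x5x5 grid with
    persistent cell selections for longitudinal follow-up), rule-based
    anatomical classification of lesions as parenchymal, mediastinal or
    pleural from lung-mask coordinate quartiles, and a component-matched
    segmentation evaluation suite (scan/crop/tumor Dice similarity
    coefficient, absolute and relative volume difference, rank-sum
    comparison of cropping strategies, RECIST-style axial axis
    measurements). A seeded synthetic thoracic phantom generator with known
    ground-truth lesion volumes and a reference threshold segmenter allow
    the whole pipeline to be exercised end to end without patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
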