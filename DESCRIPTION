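Package: oct3d2d
Title: 3D-to-2D Attention U-Net Segmentation of Geographic Atrophy in OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for automated en face segmentation of geographic atrophy
    (GA) from volumetric optical coherence tomography (OCT). Implements a
    U-Net-style network with a 3D residual encoder, attention-based axial
    collapse of the skip connections, and a 2D attention-gated decoder that
    emits an en face GA probability mask; a combined cross-entropy/Dice
    training recipe with AdamW and patience-based early stopping;
    subject-grouped k-fold cross-validation; and the agreement analysis used
    to validate such models (Dice similarity, lesion areas, Pearson r2,
    Bland-Altman limits of agreement, stratified t-tests, longitudinal area
    tracking). A device-parameterized synthetic OCT generator emulating
    Spectralis-like and Cirrus-like macular volumes with cRORA-style atrophy
    (RPE-band loss plus choroidal hypertransmission) makes the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    patchwork,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
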