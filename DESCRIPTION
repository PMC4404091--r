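Package: coilwatch
Title: Volumetric Sac-Growth and Coil-Compaction Analysis for Coil-Embolized Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal image-analysis pipeline for coil-embolized cerebral
    aneurysms imaged by 3D rotational angiography. Segments the vascular lumen
    from subtracted volumes and the coil mass from baseline (bone) volumes via
    grayscale opening, Otsu thresholding and a morphological level set; builds
    watertight surface models by marching tetrahedra; isolates the aneurysm sac
    with a non-planar neck by centerline tube subtraction; and measures sac and
    coil volumes, volumetric growth under four prioritized definitions, and the
    translation of the coil-mass center. Includes a synthetic phantom generator
    with programmed ground truth, exact one-tailed Wilcoxon signed-rank and
    Mann-Whitney tests, ROC/AUC with Youden cutoff selection, and cohort-level
    study orchestration with demographics summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
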