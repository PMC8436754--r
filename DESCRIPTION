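Package: lesionstack
Title: Stacked Regional and Voxelwise Detection of Covert Brain Lesions
    in Multimodal MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage detection of focal epileptogenic lesions from
    co-registered multimodal brain MRI. A gradient-boosted regressor
    scores each parcellated brain region by the fraction of its volume
    that is lesional, using volume and appearance features computed over
    the region core and 1 mm boundary shells; its rendered regional
    abnormality map is stacked into a gradient-boosted voxelwise
    classifier that combines local intensities (each voxel with its six
    face neighbours), atlas context, and cortical thickness into a
    probabilistic abnormality map. Includes a seeded synthetic phantom
    generator, a leave-one-out cross-validation and ablation harness
    with Dice, sensitivity and specificity scoring, and a structured
    concordance protocol against stereo-EEG electrode contacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
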