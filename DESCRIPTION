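Package: dsavm
Title: Temporal and Radiomic Analysis of Digital Subtraction Angiography
    for Arteriovenous Malformation Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cerebral hemodynamics in digital subtraction
    angiography (DSA) frame series. Per-frame detections of five vascular
    structures (internal carotid artery, circle of Willis, vein, venous
    vessel, venous sinus) are converted into a phase timeline and five
    binary temporal features describing the order of structure appearance;
    five key frames sampled in equal proportion over the developed span
    yield a 1,750-dimensional radiomic vector (intensity, texture and
    wavelet-subband feature groups). Features are ranked by iterative
    sparse representation and classified with a support vector machine
    under leave-one-out and split evaluation protocols, for arteriovenous
    malformation (AVM) diagnosis and grading. Includes a seeded synthetic
    DSA phantom generator with ground-truth bounding boxes and timelines,
    a reference phantom detector, and detection evaluation (IoU, average
    precision, mAP, precision-recall curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    glmnet,
    graphics,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
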