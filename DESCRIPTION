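Package: ramus3d
Title: Surface- and Voxel-Based Registration for 3D Assessment of Condylar
    Remodelling on the Mandibular Ramus
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for long-term three-dimensional assessment of condylar
    remodelling after orthognathic surgery. Provides ground-truthed synthetic
    hemimandible (ramus) phantoms with CBCT-like volumes, threshold/region-growing
    bone segmentation and smoothed, decimated isosurface reconstruction, masked
    rigid registration of pre- and postoperative rami by both the iterative
    closest point algorithm on bone surfaces and normalised mutual information
    on voxel intensities, partitioning of the ramus into the condyle, the
    coronoid process and twenty subregions by anatomical cutting planes derived
    from cephalometric landmarks, per-region surface-distance and volumetric
    discrepancy metrics with colour-coded distance-map export, and reliability
    and accuracy statistics (one-way random-effects intraclass correlation with
    exact confidence intervals, mean absolute differences, paired t-tests)
    comparing the two registration engines across simulated observers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, Registration, Segmentation, Visualization
RoxygenNote: 7.3.3
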