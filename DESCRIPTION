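Package: glenostab
Title: Glenoid Bone Density and Reverse Shoulder Arthroplasty Baseplate
    Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying glenoid bone density from clinical CT
    scans and relating it to the primary (time-zero) fixation stability of
    reverse shoulder arthroplasty baseplates. Implements patient-specific
    grayscale-to-bone-mineral-density calibration anchored on air, fat and
    muscle reference tissues, anatomical cylinder volumes of interest along
    the scapular axis, pixel-counting bone volume fraction (BV/TV), wedge
    augment planning geometry, rigid-body marker-tracking micromotion
    analysis for rocking-horse bench tests, and a gated statistical
    comparison pipeline. Synthetic voxel phantoms, marker recordings and
    cohorts with known ground truth make every stage testable without
    cadaveric data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    car,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    pracma,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
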