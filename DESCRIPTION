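Package: imatQuant
Title: Intramuscular Adipose Tissue Quantification from T1-Weighted and
    Two-Point Dixon MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Dual-modality quantification of intramuscular adipose tissue
    (IntraMAT) on 2-D mid-thigh MR cross-sections. Implements the
    T1-weighted route (N3-style multiplicative bias-field correction,
    reference-ROI histogram, Otsu thresholding averaged over repeated ROI
    placements, pixel-count IntraMAT percent and cross-sectional area) and
    the two-point Dixon route (ratio of mean water and fat channel
    intensities over a muscle mask), together with the agreement analyses
    used to diagnose inter-method discrepancy: Bland-Altman limits of
    agreement with proportional-bias testing, ICC(2,1) reproducibility,
    boundary-value threshold equivalence, and subtraction-method SNR. A
    parametric mid-thigh phantom generator with exact per-muscle ground
    truth makes every stage testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    RNifti,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, Segmentation, Preprocessing, StatisticalMethod
RoxygenNote: 7.3.3
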