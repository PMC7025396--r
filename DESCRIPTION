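Package: cvipwi
Title: Signal Variance-Based Collateral Vessel Index for DSC Perfusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a quantitative, rater-independent index of
    leptomeningeal collateralization in acute large-vessel stroke from
    dynamic susceptibility contrast (DSC) perfusion-weighted MRI source
    data. Per-voxel temporal coefficient-of-variation (CV) maps isolate
    pial vessels; the collateral vessel index (CVI) is the ratio of
    high-CV vessel volume in the affected versus the unaffected
    hemisphere. Also provides threshold-based ischaemic-core segmentation
    from ADC maps, time-to-peak (TTP) delay compartments, mismatch ratios
    and the hypoperfusion intensity ratio, rigid motion correction and
    coregistration, NIfTI input/output, and a synthetic 4D bolus-passage
    phantom generator with ground-truth compartments for end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
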