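Package: craniodef
Title: Quantifying Brain Deformation After Decompressive Craniectomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures external cerebral herniation from paired pre- and
    post-operative CT volumes of decompressive craniectomy patients.
    Implements skull-referenced rigid registration, slice-wise brain
    segmentation (statistical region merging with morphological contour
    cleanup), craniectomy-baseline fitting, the baseline-normal
    displacement field and its maximum, herniated volume from brain-mask
    differencing, two craniectomy-area estimators, parabolic-cap and
    cylindrical geometric volume models, and the comparison statistics.
    Ships a synthetic head-phantom generator with analytic ground truth
    so the whole chain is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
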