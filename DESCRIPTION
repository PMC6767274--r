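Package: vfssdetect
Title: Pharyngeal Phase Detection in Videofluoroscopic Swallowing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-stage cascade for locating the pharyngeal phase of
    swallowing in untrimmed videofluoroscopic swallowing study (VFSS)
    video: dense TV-L1 optical flow with vertical-motion voting proposes
    short candidate clips, a 3D convolutional network classifies each
    20-frame clip as pharyngeal phase or other motion, and a sliding
    window over the classifier scores recovers event intervals from long
    recordings. Includes the temporal-IOU greedy matching evaluation
    protocol (precision, recall, F1, detection time error, miss rate),
    annotator ground-truth merging, and a seeded synthetic fluoroscopy
    generator so the full pipeline can be exercised and validated
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
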