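Package: idtp
Title: Positive-Unlabeled Identification of Drug Target Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies likely drug-target proteins hidden inside a contaminated
    non-target set using positive-unlabeled (PU) learning. Mixed
    continuous/nominal physicochemical protein properties are z-normalized and
    one-hot encoded, embedded with a greedily pretrained stacked auto-encoder,
    and classified with a biased support vector machine whose asymmetric slack
    penalties (C+ for labeled positives, C- for unlabeled-as-negative) relieve
    the class imbalance. Includes Kolmogorov-Smirnov property screening, a
    repeated stratified hold-out experiment driver with F1/recall/precision
    summaries, doubtful-target retrieval, and a contamination-mixture simulator
    with hidden ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    readxl,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
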