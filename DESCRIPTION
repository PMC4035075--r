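Package: mirduplex
Title: Evaluation and Characterization of Plant miRNA Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A benchmark pipeline for plant microRNA target prediction.
    Aligns miRNA:mRNA duplexes with a penalty scheme that distinguishes
    Watson-Crick matches, G:U wobbles, mismatches and gaps (seed positions
    weighted double), provides a self-contained penalty-based target
    scanner, and evaluates predictors against validated interaction sets:
    precision/recall threshold sweeps with optimal-score selection at the
    precision-recall crossing, ROC/AUC, and union/intersection combination
    of predictors. Characterizes true-positive versus false-negative
    interactions through duplex features (longest complementary stretch,
    first stretch, match/mismatch ratio, miRNA GC content), positional
    Shannon entropy profiles, alignment-vector clustering, and the free
    energy versus transcript length trend. Includes a synthetic-data
    generator that implants target sites with controlled seed-window edit
    profiles and full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
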