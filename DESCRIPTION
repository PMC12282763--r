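Package: chipmeta
Title: Sensitive Discovery of Clonal-Hematopoiesis Mutations by Meta-Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects clonal hematopoiesis of indeterminate potential (CHIP)
    mutations from standard-depth whole-exome or whole-genome alignments.
    Implements a permissive pileup-based variant tracker, merging of multiple
    caller call sets with a per-variant calling status, consequence annotation
    and feature extraction, three-class machine-learning classification
    (CHIP / GERMLINE / ARTIFACT) with gradient-boosted trees or random
    forests, rule-based rescue and cohort-level filtering, and hierarchical
    Bayesian credible intervals for clone size. A spike-in read simulator
    generates ground-truth benchmarks at controlled variant allele fractions
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    vcfR,
    xgboost,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
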