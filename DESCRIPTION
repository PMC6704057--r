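Package: memflex
Title: Control-Theory Modelling of Memory Strengthening, Forgetting, and
    Sequential-Learning Interference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a control-theory model of hippocampal memory dynamics in
    which every learning experience drives a fast memory-strengthening and a slow
    memory-weakening first-order signalling process in parallel. Their saturated
    difference ("pathway activity") draws on a finite pool of downstream
    effectors, so strong retention of one experience can interfere with encoding
    of the next. The package evaluates the model in closed form and numerically,
    runs single-task and sequential-learning protocols for wild-type and
    WT1-deficient parameterisations, sweeps the input magnitude, generates
    synthetic behavioural cohorts with parameter-recovery validation, and
    implements the companion transcriptomic scoring stages: read-count
    equalisation, differential-expression filtering with a pseudocounted
    fold-change rule, gene-set library preprocessing (homolog remapping,
    universe restriction), and right-tailed Fisher transcription-factor
    enrichment ranked by -log10 p.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    fgsea,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
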