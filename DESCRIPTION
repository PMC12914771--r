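Package: dmsdesign
Title: Sort-Seq Enrichment Analysis and Ensemble Neural Design of Selective Protease Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning sorted-library deep mutational scanning reads
    into per-variant enrichment ratios, training ensembles of small neural
    regressors of log2 enrichment ratio from one-hot encoded variant
    signatures, designing multi-mutant inhibitor candidates ranked by
    predicted selectivity across homologous target enzymes, and validating
    candidates with Morrison tight-binding inhibition kinetics. Includes a
    synthetic sort-seq and kinetics data generator with known ground truth so
    the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
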