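Package: cazymine
Title: Local Relational Mining of Carbohydrate-Active Enzyme Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a local, shareable, reproducible SQLite database of
    carbohydrate-active enzyme (CAZyme) records from a CAZy-style plain-text
    dump; enriches it with taxonomy, sequence, EC-number, genome-assembly and
    structure cross-references taken from offline snapshot files; and exposes
    filtered queries, FASTA export and family-survey statistics: species
    representation rates, chi-squared tests with Pearson-residual
    explained-variance decomposition, BLAST-Score-Ratio similarity matrices,
    redundant-sequence detection, greedy identity/coverage clustering and
    cluster-level structural-coverage reports. A deterministic synthetic
    fixture generator with full ground truth supports end-to-end testing
    without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    readr,
    tibble,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
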