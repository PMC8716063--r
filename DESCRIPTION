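Package: clonex
Title: Tests for Clonal Exclusivity and Co-Occurrence of Mutations in
    Tumour Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tests for detecting pairs of mutated genes that fall
    in different clonal lineages of the same tumour (clonal exclusivity) or in
    a common lineage (clonal co-occurrence) more often than expected under a
    tree-aware null model, across a cohort of patient clone trees. Implements
    a likelihood-ratio placement test with chi-squared, exact-enumeration and
    Monte-Carlo-smoothed p-values, a weighted-sampling occurrence test in the
    Fisher non-central hypergeometric sense, a combined test with an exact
    null over the count of exclusive trees, naive clone-level baselines for
    comparison, a synthetic cohort generator, and calibration and power
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
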