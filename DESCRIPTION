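Package: ffpecms
Title: Consensus Molecular Subtype Classification for Degraded FFPE RNA-Seq
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning colorectal-cancer consensus molecular
    subtypes (CMS1-CMS4) to expression profiles derived from degraded,
    formalin-fixed paraffin-embedded (FFPE) RNA. Implements entropy-based
    transcript integrity number (TIN) scoring from per-base read coverage,
    median-TIN filtering of candidate signature genes, z-normalized binary
    gene-pair feature encoding that is robust to per-gene platform effects,
    random-forest subtype prediction with per-class probability scores, and
    concordance evaluation (accuracy, contingency tables, per-class
    sensitivity/specificity, exact binomial concordance tests). Includes a
    synthetic paired fresh-frozen/FFPE cohort simulator with planted subtype
    structure and module-specific degradation so the whole pipeline can be
    exercised without external data, and a command-line interface tying the
    stages into a pipeline.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
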