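Package: ssrnet
Title: Seed-Guided Co-Expression Network Analysis of Sugar-Starvation
    Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs and interrogates sugar-starvation responsive (SSR)
    gene co-expression networks. Provides recursive seed-guided network
    expansion over an expression compendium using squared Pearson
    correlation, degree and hub classification with a scale-free summary,
    MCODE module detection, paired t-tests on two-color dye-swap log-ratios
    with pooled variance and Bonferroni control, promoter motif
    over-representation with exact binomial/hypergeometric and empirical
    k-mer nulls (Boyer-Moore counting), cross-examination of network
    membership with differential-expression calls, and seeded synthetic-data
    generators with planted ground truth so the whole pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
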