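Package: ensembleGSA
Title: Ensemble Gene Set Enrichment Analysis for Expression Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Runs a panel of gene set enrichment tests (over-representation,
    competitive parametric tests with inter-gene correlation correction,
    rotation tests, permutation tests and per-sample set-score models) over a
    log-expression matrix with a design/contrast specification, then combines
    the per-method p-values and rankings into consensus scores (combined
    p-value, average/median/vote rank, significance score) per contrast and
    across contrasts. Includes a count-to-log-expression path (TMM
    normalisation, log-CPM, precision weights), GMT collection indexing, a
    seeded synthetic-experiment generator with planted enriched sets, plot
    data extractors and a static HTML report, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    edgeR,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
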