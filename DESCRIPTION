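Package: hepatodimorph
Title: Sex-Dimorphic Expression Screening and Weighted Co-Expression
    Networks for Hepatic Drug-Metabolism Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify sex-differentially expressed genes in human
    liver microarray data stored as log10 sample/reference ratios (pooled
    two-sample t-test plus fold-change thresholding), to build weighted gene
    co-expression networks from the screened genes (soft-threshold adjacency,
    scale-free topology fit, topological overlap, average-linkage module
    detection with colour labels), and to test modules for functional
    enrichment (one-sided Fisher's exact test with Bonferroni correction on
    user-supplied GMT gene sets).  Includes a latent-factor simulator that
    plants sex effects and correlated gene modules with known ground truth,
    and a bundled table of 77 drug-metabolizing-enzyme/transporter (DMET)
    genes with published sex-biased hepatic expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
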