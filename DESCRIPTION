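Package: codechron
Title: Phylogenomic Timelines of Protein Domains and the Origin of the Genetic Code
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrodicting molecular history from genomic censuses of
    protein domain structures. Abundance matrices of domains across proteomes
    are recoded as linearly ordered multistate characters and analysed by
    Wagner (ordered-state) maximum parsimony with Lundberg rooting, bootstrap
    resampling and tree statistics (CI, RI, g1). Rooted trees yield
    node-distance (nd) timelines that a molecular clock converts to geological
    ages, and phylogenetic constraint analysis measures the ancestrality of
    tRNA groups. Companion modules compute amino-acid and dipeptide
    composition signatures of fold families, hypergeometric enrichment of
    dipeptides in ancient proteins, Kyte-Doolittle hydropathy summaries,
    secondary-structure region biases from DSSP assignments, exchange-group
    analyses, and the vis-a-vis complementary-codon representation of the
    genetic code. A synthetic-data module generates censuses, sequence sets
    and tRNA character matrices with known ground truth so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    withr,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
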