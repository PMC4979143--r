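Package: corticompare
Title: Cross-Species Brain Transcriptome Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing bulk brain transcriptomes across mammalian
    species: RPKM quantification from gene-level read counts, ortholog joining
    with expression filters and signed fold-change ranking, gene-set
    overrepresentation testing (binomial tail with Bonferroni correction),
    marker-based glia/neuron composition correction with two-group testing,
    and expression-correlation phylogenies via an in-package neighbor-joining
    implementation with Newick and PHYLIP output. Includes a synthetic-data
    module that simulates multi-species expression under Brownian motion on a
    species tree, with fold-change spikes, cell-composition confounds, Poisson
    count noise, and gene-set annotations with a known enriched term, so every
    pipeline stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
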