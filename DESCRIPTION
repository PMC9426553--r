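Package: gecco
Title: Gene Coexpression Connectivity Analysis for Replicated Two-Time-Point Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies genes from replicated two-time-point transcriptome
    comparisons using variance-moderated log2 fold-change scores, builds a
    thresholded Pearson coexpression network over the classified genes,
    reduces it to the upregulated subnetwork, and ranks candidate genes for
    reverse engineering by degree centrality within percentile quadrants of
    degree and average fold change. Includes a synthetic-data generator with
    planted gene classes and planted coexpression modules so the whole
    pipeline can be validated against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
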