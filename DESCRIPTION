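Package: agios
Title: Gene-Based Average Genomic Identity for Bacterial Species Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the taxono-genomic comparison of bacterial genomes:
    affine-gap Needleman-Wunsch global alignment, reciprocal-best-hit
    orthology between gene sets, the AGIOS statistic (Average Genomic
    Identity Of gene Sequences, the mean nucleotide identity over
    orthologous gene pairs) with multi-genome comparison matrices,
    dual-threshold ORFan classification from tabular similarity hits,
    genome composition and COG functional-category summaries, a 16S rRNA
    identity species-delineation check, and a divergence simulator that
    generates gene-set pairs with a machine-readable truth table so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
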