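Package: spirotax
Title: Comparative Genomic and Phylogenetic Profiling of Spirochete Genomes
Version: 0.1.0
Authors@R: person("spirotax", "developers", role = c("aut", "cre"),
    email = "devel@spirotax.example.org")
Description: Tools for the comparative-genomic evidence used in spirochete
    taxonomy: high-scoring segment pair (HSP) discovery between genome pairs
    and the three genome-to-genome distance components (HSP coverage,
    within-HSP identity, whole-genome identity), COG functional-category
    count matrices with arcsine-square-root and log transforms and clustered
    heatmaps, Felsenstein phylogenetically independent contrasts with raw and
    through-origin correlations, BLAST-score-weighted 16S rRNA taxon and
    stemmed-keyword profiles, and genome summary statistics. A synthetic-data
    module generates Yule trees, bivariate Brownian traits, genome pairs with
    planted conserved segments, and multinomial COG gene tables so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    optparse,
    pheatmap,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
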