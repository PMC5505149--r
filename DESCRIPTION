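Package: pancore
Title: Core- and Pan-Genome Analysis of Bacterial Isolates by
    Bidirectional Best Hits, Homology Clustering and ANIb
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline for sets of closely related
    bacterial isolates. Builds core-genomes by pivot-anchored bidirectional
    best hits under end-gap-free (semi-global) protein alignment with
    similarity and length filters, pan-genomes by single-linkage clustering
    of local-alignment homology edges, species assignments by average
    nucleotide identity over genome fragments (ANIb) with the 95 percent
    rule, gene presence/absence partitions and per-gene identity reports,
    and a distance-based neighbor-joining tree from core-ortholog
    identities. Includes a seeded synthetic pan-genome simulator with full
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
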