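Package: copresence
Title: Coincident Gene Association and Dissociation Networks in Pangenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene families in a pangenome that associate (co-occur) or
    dissociate (avoid each other) across genomes more often than expected by
    chance, using a Bonferroni-corrected one-sided binomial exact test on
    presence/absence patterns. Each coincident gene's phylogenetic
    distribution is scored for lineage independence with the D statistic for
    binary traits, computed against tip-shuffle and Brownian-threshold null
    models on a user-supplied phylogeny. Results are assembled into an
    attributed network (GEXF v1.2 with colour, size and edge-thickness
    annotation), tabular outputs, and presence/absence heatmaps drawn next to
    the phylogeny. Includes a synthetic-data generator that plants known
    associating and dissociating gene pairs on simulated trees for
    benchmarking and calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    xml2,
    optparse,
    parallel,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
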