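Package: rhizonet
Title: Co-Occurrence Network Analysis of Rhizosphere Microbiomes
Version: 0.1.0
Authors@R: person("Rhizonet", "Maintainers", email = "maintainers@rhizonet.dev",
    role = c("aut", "cre"))
Description: A tested pipeline for building microbial co-occurrence networks
    from taxon-abundance tables: sample and taxon filtering, all-pairs
    Spearman correlation with Benjamini-Hochberg false-discovery-rate control,
    random-matrix-theory selection of the correlation threshold, construction
    of undirected weighted taxon networks with node- and network-level
    metrics, fast-greedy (Clauset-Newman-Moore) module detection, keystone
    taxon identification by centrality criteria, functional-category
    classification from predicted gene content, phylum connection shares and
    chord-diagram matrices, GEXF export, and group-comparison statistics
    (two-way ANOVA with Tukey HSD and compact letter displays). Includes a
    latent-factor synthetic data generator with planted modules, hub taxa and
    treatment-dependent network density for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
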