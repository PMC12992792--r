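Package: ppievo
Title: Cross-Species Yeast Two-Hybrid Scoring and Protein Interaction Evolution
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying the evolution of protein-protein
    interaction networks across related species. Provides replication scoring
    and interaction calling for matrix-format yeast two-hybrid screens with
    auto-activity quality control; assembly of cross-species ortholog
    interaction matrices and classification of evolutionary trajectories
    (conserved, coevolving, species-restricted); pairwise dN/dS estimation by
    Nei-Gojobori (1986) codon counting with Jukes-Cantor correction;
    differential enrichment statistics for co-immunoprecipitation
    mass-spectrometry protein-group tables; and seeded synthetic-data
    generators with ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
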