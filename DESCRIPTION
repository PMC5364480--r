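Package: pinflex
Title: Evolution of Protein Interaction Networks and Conformational Flexibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how protein-protein interaction networks of
    MADS-domain transcription factors rewire across whole-genome duplications,
    and how the conformational flexibility of hub proteins changes alongside.
    Provides quantitative yeast two-/three-hybrid interaction calling from
    beta-galactosidase (Miller unit) assay tables, polyploidy-aware network
    rescaling and cross-epoch comparison with gain/loss-rate statistics,
    Boltzmann conformer-ensemble entropy as a flexibility descriptor, and a
    structural geometry engine (Kabsch superposition, trajectory RMSD,
    Shrake-Rupley solvent accessibility, backbone dihedrals, beta/gamma/alpha
    turn classification, and polar-contact detection). A synthetic-data module
    generates evolving networks with known ground truth, assay tables,
    conformer ensembles, and backbone structures so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    bio3d,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
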