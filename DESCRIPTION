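Package: hicbeads
Title: Whole-Genome 3D Bead Models from Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers, refines, annotates and stress-tests whole-genome 3D
    bead models from binned Hi-C contact counts. Contact counts are modelled
    as negative binomial draws whose mean decays as a power of the
    inter-bead distance; coordinates are obtained by maximum likelihood from
    a shortest-path multidimensional-scaling start. Refinement interpolates
    interior missing beads with monotone cubic Hermite splines, discards
    terminal missing beads and filters geometric outliers. Models are
    exported as chromosome-annotated PDB and G3D files, can be painted with
    per-bin omics signal through the B-factor field, screened for assembly
    inversions by comparing spatial bead chaining with sequence numbering,
    and assessed for robustness to Poisson shot noise with
    superposition-based RMSD over a grid of noise intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
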