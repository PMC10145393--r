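Package: nibscreen
Title: Negative Image-Based Rescoring and Shape-Focused Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for negative image-based (NIB) virtual screening of
    docked ligand poses. Generates cavity negative images from a protein
    structure by FCC sphere packing, rescores docking poses in place by
    Gaussian shape overlap and electrostatic-potential (Hodgkin) similarity,
    optimizes cavity models by greedy point deletion against BEDROC
    enrichment (BR-NiB), filters poses with anchored pharmacophore points,
    runs a compound-selection funnel (top-fraction cut, logP, pattern and
    binding-energy thresholds), and computes 64-bit linear fingerprints with
    Tanimoto similarity for hit-novelty analysis. Includes deterministic
    synthetic fixtures (box pockets, plug poses, score sets) so the whole
    protocol is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    yaml,
    withr,
    bio3d,
    ChemmineR,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
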