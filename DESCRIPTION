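Package: chromo3d
Title: Hierarchical Multi-Scale 3D Models of the Physical Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds hierarchical four-scale 3D models of a physical genome
    (nuclear-scale giant-loop random walk, 30 nm chromatin fiber, nucleosome
    core particles, atomic-resolution DNA), stores the three coarse scales as
    compressed XML with lazy range loading, synthesizes atomic DNA coordinates
    on demand, projects UCSC BED and WIG annotation tracks onto model elements
    at any scale, and exports selections to PDB, PovRay and XYZ. All inputs can
    be generated by seeded synthetic-fixture functions, so analyses are fully
    reproducible offline.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    S4Vectors,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    bio3d,
    Biostrings,
    optparse,
    readr,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
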