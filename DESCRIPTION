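Package: gbscan
Title: Locating Glycosaminoglycan-Binding Sites on Protein Structures and
    Classifying Their Specificity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies glycosaminoglycan (GAG)-binding sites on protein
    structures from electrostatics alone. Computes the multi-body Coulomb
    potential manifested at basic (Arg/Lys) and neutral hydrogen-bond-donor
    (Asn/Gln and related) loci under configurable charge and dielectric
    models, projects loci onto 2D-Surface-Energy (2DSE) plots with
    exponential marker scaling, detects electrostatic hot spots by
    distribution statistics to call a site specific or nonspecific, and
    analyses mutant binding tables (Kd to free-energy conversion,
    electrostatics-versus-desolvation decomposition and regression). Ships
    a deterministic synthetic-structure generator with planted binding
    sites for validation, packaged antithrombin and thrombin mutant
    energetics tables, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
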