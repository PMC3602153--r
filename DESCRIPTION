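Package: pdzpred
Title: Structure-Based Prediction of PDZ Domain-Peptide Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts interactions between PDZ domains and C-terminal
    pentapeptides from domain structure. Encodes a ten-position core
    binding site with solvent accessibility, hydrogen bonding, backbone
    phi sign, per-residue accessible area, and surface electrostatic and
    hydrophobicity samples (240 values per domain), pairs it with a
    sparse binary peptide encoding (100 bits), and trains a cost-weighted
    radial-basis-function support vector classifier. Includes position
    weight matrix generation of artificial negative interactions,
    semi-supervised negative training-set expansion, leave-domain and
    leave-peptide cross-validation schemes, C-terminal proteome scanning,
    and a deterministic synthetic fixture generator for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
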