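Package: nucsite
Title: Template-Based Prediction of Nucleotide Binding Sites on Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts ATP/ADP/AMP binding sites on protein structures by
    matching a library of known binding-site templates onto the target
    surface. Candidate ligand-center points on a solvent grid are screened
    by local triangle similarity to each template site, the maximal common
    substructure between template and surface patch is found by backtracking
    clique search, the template ligand is placed by least-squares rigid
    superposition, poses are filtered with an AMBER-style nonbonded energy,
    and surviving poses are clustered into ranked predicted sites and
    per-residue binding scores. Includes evaluation utilities (center-distance
    success rates, residue precision/recall/MCC, homology-filtered template
    selection, capped paired-distance comparison) and a deterministic
    synthetic-complex generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
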