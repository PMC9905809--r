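Package: chimeraMHC
Title: Fixed-Backbone Design of Chimeric MHC Class I Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing chimeric human MHC class I (HLA) molecules
    that graft the peptide-binding groove of a template allele onto the
    T-cell-receptor (TCR) contact framework of a base allele. Classifies
    heavy-chain positions into peptide-binding, TCR-binding and dual
    surfaces from collections of pMHC-I and pMHC-TCR structures, defines
    the groove by heavy-atom proximity to the bound peptide, enumerates
    all combinations of base-to-template groove substitutions, scores
    each variant with a deterministic residue-class contact potential on
    fixed backbone geometry (with an adapter contract for external
    all-atom scorers), and ranks substitutions by enrichment among the
    lowest-energy variants. Includes peptide-specificity summaries
    (position-specific scoring matrices, information content) and
    TCR-surface phylogenetics, plus deterministic synthetic-structure
    generators so the whole workflow runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
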