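Package: dualfold
Title: Detection of Dual-Fold Coevolutionary Signatures in Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect residue-residue coevolution supporting two
    distinct folds of a single protein sequence. Implements Alternative
    Contact Enhancement (ACE): a deep superfamily alignment is pruned into
    nested subfamily alignments by sequence identity to the query,
    coevolution inference is run on every alignment, per-run z-scores are
    superposed onto one contact map, and the superposition is denoised by
    density-based clustering with an ROC-derived radius. Predicted contacts
    are categorized against dual-fold experimental contact maps
    (dominant/alternative/common/unobserved), enrichment of subfamily-derived
    contacts is scored with a one-tailed hypergeometric test, and a blind
    classification pipeline calls fold-switching candidates from pairs of
    predicted structures plus secondary-structure divergence. A synthetic
    family generator with planted couplings provides ground-truth fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    bio3d,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
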