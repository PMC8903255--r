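Package: pocketmotif
Title: Sequence-Order-Independent Structural Alignment of Protein
    Ligand-Binding Sites and Derivation of 3D Sequence Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the three-dimensional structures of protein
    ligand-binding sites independently of sequence order.  Each pocket
    residue is reduced to three labelled points (C-alpha, C-beta and the
    side-chain centroid); residue correspondences between two pockets are
    found by backtracking clique search over a correspondence graph of
    distance-compatible residue dyads, superposed with the Kabsch
    algorithm, and scored by matched-residue fractions (M-dist_min,
    M-dist_max) and a scaled BLOSUM-62 sequence score (M-seq).  Many
    pockets are placed into a common frame by all-vs-all comparison,
    similarity-network clustering (an MCODE-style procedure), star
    alignment onto a cluster representative, and consensus profiling,
    from which PROSITE-style structural motifs with variable gaps and 3D
    anchors are derived and scanned against pocket libraries.  Includes a
    synthetic-pocket generator and the position/residue-type
    perturbation sensitivity analyses used to validate the scores.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
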