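#' Build the per-pocket distance matrix
#'
#' For a pocket of N residues, computes the symmetric N x N x 3 array of
#' Euclidean distances between like points of every residue pair, channels
#' ordered (`ca`, `cb`, `cn`).  The off-diagonal entries of one channel are
#' the residue-dyad distances that drive seed generation.
#'
#' @param pocket a `Pocket` with at least 3 residues.
#' @return a `DistanceMatrix`: list with `pocket_id`, `n` and the array `d`.
#' @export
build_distance_matrix <- function(pocket) {
  stopifnot(is_pocket(pocket))
  n <- pocket_size(pocket)
  d <- array(0, dim = c(n, n, 3), dimnames = list(NULL, NULL,
                                                  c("ca", "cb", "cn")))
  d[, , 1] <- as.matrix(stats::dist(pocket$ca))
  d[, , 2] <- as.matrix(stats::dist(pocket$cb))
  d[, , 3] <- as.matrix(stats::dist(pocket$cn))
  structure(list(pocket_id = pocket$pocket_id, n = n, d = d),
            class = "DistanceMatrix")
}

#' Count ordered k-tuples of residues
#'
#' Number of ordered selections of `k` distinct residues out of `n`:
#' `n * (n-1) * ... * (n-k+1)`.  This is the size of the raw search space
#' for k-residue structural motifs (dyads `k = 2`, triads `k = 3`, tetrads
#' `k = 4`), and the reason seeding works on dyads: a 20-residue site
#' already has 380 dyads but 6840 triads and 116280 tetrads.
#'
#' @param n non-negative integer, number of residues.
#' @param k positive integer, tuple size.
#' @return the permutation count (0 when `k > n`).
#' @export
count_ktuple_permutations <- function(n, k) {
  n <- as.numeric(n); k <- as.numeric(k)
  stopifnot(length(n) == 1, length(k) == 1, n >= 0)
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  if (k > n) return(0)
  prod(seq(n, n - k + 1))
}

#' Are two residue dyads distance-compatible?
#'
#' Two dyads (one per pocket) are compatible when the RMSD between their
#' three-channel distance triplets (ca-ca, cb-cb, cn-cn) is below `tol`.
#'
#' @param t1,t2 numeric length-3 distance triplets (Angstrom).
#' @param tol tolerance in Angstrom (default 1.0).
#' @return logical.
#' @export
dyad_compatible <- function(t1, t2, tol = 1.0) {
  stopifnot(length(t1) == 3, length(t2) == 3)
  sqrt(mean((t1 - t2)^2)) < tol
}
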