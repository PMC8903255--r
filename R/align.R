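#' Generate seed alignments between two pockets
#'
#' Builds the correspondence graph of residue pairings between `P1` and
#' `P2` (a pairing `(i, j)` is connected to `(k, l)` when the dyads
#' `(i, k)` and `(j, l)` have distance triplets agreeing within `tol`, see
#' [dyad_compatible()]) and grows cliques from every compatible starting
#' dyad by bounded backtracking search.  Each maximal clique is a seed
#' alignment: an injective residue correspondence whose internal distances
#' agree between the pockets.
#'
#' @param D1,D2 `DistanceMatrix` objects from [build_distance_matrix()],
#'   built with the same channel convention.
#' @param aa1,aa2 one-letter residue types of the two pockets (used for the
#'   raw-BLOSUM tie-break between equal-length seeds).
#' @param tol dyad distance tolerance in Angstrom (default 1.0).
#' @param max_seeds maximum number of ranked seeds returned (default 10).
#' @param max_starts cap on the number of starting dyads explored
#'   (smallest-RMSD first; default 1000).
#' @param budget per-start backtracking expansion budget (default 100;
#'   exhaustion degrades gracefully to pure greedy growth).
#' @return list of `SeedAlignment` objects (fields `pairs` -- a two-column
#'   index matrix, `score_len`, `blosum_score`), ranked by decreasing
#'   length, ties by raw BLOSUM sum, then lexicographic pair order.  Empty
#'   list when no compatible dyad exists ("no alignment", not an error).
#' @export
generate_seeds <- function(D1, D2, aa1, aa2, tol = 1.0, max_seeds = 10,
                           max_starts = 1000, budget = 100) {
  stopifnot(inherits(D1, "DistanceMatrix"), inherits(D2, "DistanceMatrix"),
            length(aa1) == D1$n, length(aa2) == D2$n)
  node_blosum <- as.numeric(t(outer(aa1, aa2, raw_blosum)))  # u = (i-1)*n2+j
  res <- .cpp_seed_search(as.numeric(D1$d), as.numeric(D2$d), D1$n, D2$n,
                          tol, as.integer(max_seeds), node_blosum,
                          as.integer(max_starts), as.integer(budget))
  lapply(res, function(s) {
    structure(list(pairs = s$pairs, score_len = nrow(s$pairs),
                   blosum_score = s$blosum),
              class = "SeedAlignment")
  })
}

empty_alignment <- function(p1, p2) {
  structure(list(
    id1 = p1$pocket_id, id2 = p2$pocket_id,
    n1 = pocket_size(p1), n2 = pocket_size(p2),
    pairs = matrix(integer(), ncol = 2,
                   dimnames = list(NULL, c("i", "j"))),
    rotation = diag(3), translation = c(0, 0, 0),
    rmsd = NA_real_, n_matched = 0L,
    m_dist_min = 0, m_dist_max = 0, m_seq = 0), class = "PairwiseAlignment")
}

# Superpose the three points of P2's residues jj onto P1's residues ii.
superpose_on_pairs <- function(p1, p2, ii, jj) {
  A <- rbind(p1$ca[ii, , drop = FALSE], p1$cb[ii, , drop = FALSE],
             p1$cn[ii, , drop = FALSE])
  B <- rbind(p2$ca[jj, , drop = FALSE], p2$cb[jj, , drop = FALSE],
             p2$cn[jj, , drop = FALSE])
  kabsch_superpose(A, B)
}

#' Align a pair of pockets
#'
#' The full pairwise aligner: seeds from [generate_seeds()] are each
#' superposed (Kabsch on all three points of every seed pair), extended by
#' greedy mutual-nearest-neighbour matching of unmatched residues whose
#' post-superposition C-alpha distance is below `ext_cutoff` (alternating
#' extension with re-superposition until the correspondence stops
#' growing), and scored.  The candidate with the
#' most matches (ties: largest scaled-BLOSUM sum, then lexicographic pair
#' order) wins.
#'
#' Scores: `m_dist_max` = matches / max(N1, N2); `m_dist_min` = matches /
#' min(N1, N2); `m_seq` = mean scaled BLOSUM-62 score over matched pairs
#' ([scaled_blosum()]).  All three are 1 for identical pockets and 0 when
#' no seed exists.  Scores are symmetric in the pocket order by
#' construction (the computation runs in a canonical direction and is
#' mirrored back).
#'
#' @param p1,p2 `Pocket` objects.
#' @param tol dyad tolerance in Angstrom (default 1.0).
#' @param ext_cutoff post-superposition C-alpha extension cutoff in
#'   Angstrom (default 2.0).
#' @param max_seeds number of top-ranked seeds refined (default 10).
#' @param max_starts,budget search caps passed to [generate_seeds()].
#' @return a `PairwiseAlignment`: fields `pairs` (two-column matrix of
#'   residue indices, `i` into `p1`, `j` into `p2`), `rotation` /
#'   `translation` (rigid motion taking `p2` coordinates into the `p1`
#'   frame, row convention `x R + t`, det(R) = +1), `rmsd` (matched
#'   C-alpha), `n_matched`, `m_dist_min`, `m_dist_max`, `m_seq`.
#' @export
align_pair <- function(p1, p2, tol = 1.0, ext_cutoff = 2.0, max_seeds = 10,
                       max_starts = 1000, budget = 100) {
  stopifnot(is_pocket(p1), is_pocket(p2))
  swapped <- pocket_key(p2) < pocket_key(p1)
  a <- if (swapped) p2 else p1
  b <- if (swapped) p1 else p2
  aln <- align_pair_directed(a, b, tol, ext_cutoff, max_seeds, max_starts,
                             budget)
  if (swapped) aln <- invert_alignment(aln)
  aln
}

align_pair_directed <- function(p1, p2, tol, ext_cutoff, max_seeds,
                                max_starts, budget) {
  D1 <- build_distance_matrix(p1)
  D2 <- build_distance_matrix(p2)
  seeds <- generate_seeds(D1, D2, p1$residues$aa, p2$residues$aa, tol,
                          max_seeds, max_starts, budget)
  if (length(seeds) == 0) return(empty_alignment(p1, p2))
  n1 <- pocket_size(p1); n2 <- pocket_size(p2)
  best <- NULL
  for (seed in seeds) {
    ii <- seed$pairs[, 1]; jj <- seed$pairs[, 2]
    fit <- tryCatch(superpose_on_pairs(p1, p2, ii, jj),
                    error = function(e) NULL)
    if (is.null(fit)) next   # degenerate seed geometry (e.g. glycine dyad)
    # alternate extension and re-superposition until the correspondence
    # stops growing: each refit tightens the frame, which can bring further
    # true partners inside the extension cutoff
    repeat {
      # a correspondence of fewer than 3 residues leaves the frame's
      # third rotational degree of freedom pinned only by short side-chain
      # lever arms; extension from such a frame is unreliable and skipped
      if (length(ii) < 3) break
      ca2t <- sweep(p2$ca %*% fit$rotation, 2, fit$translation, `+`)
      ext <- extend_matches(p1$ca, ca2t, ii, jj, ext_cutoff)
      if (length(ext$ii) == length(ii)) break
      ii <- ext$ii; jj <- ext$jj
      refit <- tryCatch(superpose_on_pairs(p1, p2, ii, jj),
                        error = function(e) NULL)
      if (is.null(refit)) break
      fit <- refit
    }
    ca2t <- sweep(p2$ca %*% fit$rotation, 2, fit$translation, `+`)
    rmsd <- sqrt(mean(rowSums((p1$ca[ii, , drop = FALSE] -
                                 ca2t[jj, , drop = FALSE])^2)))
    sseq <- scaled_blosum(p1$residues$aa[ii], p2$residues$aa[jj])
    ord <- order(ii)
    cand <- list(ii = ii[ord], jj = jj[ord], fit = fit, rmsd = rmsd,
                 n = length(ii), sb = sum(sseq), m_seq = mean(sseq))
    if (is.null(best) || better_candidate(cand, best)) best <- cand
  }
  if (is.null(best)) return(empty_alignment(p1, p2))
  pairs <- cbind(i = best$ii, j = best$jj)
  structure(list(
    id1 = p1$pocket_id, id2 = p2$pocket_id, n1 = n1, n2 = n2,
    pairs = pairs, rotation = best$fit$rotation,
    translation = best$fit$translation, rmsd = best$rmsd,
    n_matched = best$n,
    m_dist_min = best$n / min(n1, n2),
    m_dist_max = best$n / max(n1, n2),
    m_seq = best$m_seq), class = "PairwiseAlignment")
}

better_candidate <- function(a, b) {
  if (a$n != b$n) return(a$n > b$n)
  if (a$sb != b$sb) return(a$sb > b$sb)
  # lexicographic pair order for full determinism
  ka <- paste(a$ii, a$jj, collapse = ";")
  kb <- paste(b$ii, b$jj, collapse = ";")
  ka < kb
}

# Greedy mutual-nearest-neighbour extension on post-superposition C-alpha
# positions; repeats until no unmatched mutual pair is below the cutoff.
extend_matches <- function(ca1, ca2t, ii, jj, cutoff) {
  repeat {
    un1 <- setdiff(seq_len(nrow(ca1)), ii)
    un2 <- setdiff(seq_len(nrow(ca2t)), jj)
    if (length(un1) == 0 || length(un2) == 0) break
    d <- outer(rowSums(ca1[un1, , drop = FALSE]^2),
               rowSums(ca2t[un2, , drop = FALSE]^2), `+`) -
      2 * ca1[un1, , drop = FALSE] %*% t(ca2t[un2, , drop = FALSE])
    d <- sqrt(pmax(d, 0))
    nn2 <- apply(d, 1, which.min)
    nn1 <- apply(d, 2, which.min)
    mut <- which(nn1[nn2] == seq_along(un1) &
                   d[cbind(seq_along(un1), nn2)] < cutoff)
    if (length(mut) == 0) break
    ii <- c(ii, un1[mut])
    jj <- c(jj, un2[nn2[mut]])
  }
  list(ii = ii, jj = jj)
}

invert_alignment <- function(aln) {
  R <- aln$rotation; t <- aln$translation
  pairs <- aln$pairs[, c(2, 1), drop = FALSE]
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(
    id1 = aln$id2, id2 = aln$id1, n1 = aln$n2, n2 = aln$n1,
    pairs = pairs,
    rotation = t(R), translation = as.numeric(-t %*% t(R)),
    rmsd = aln$rmsd, n_matched = aln$n_matched,
    m_dist_min = aln$m_dist_min, m_dist_max = aln$m_dist_max,
    m_seq = aln$m_seq), class = "PairwiseAlignment")
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat(sprintf(
    "PairwiseAlignment %s (n=%d) vs %s (n=%d): %d matched, rmsd %.3f\n",
    x$id1, x$n1, x$id2, x$n2, x$n_matched,
    if (is.na(x$rmsd)) NA else x$rmsd))
  cat(sprintf(" M-dist_min %.3f  M-dist_max %.3f  M-seq %.3f\n",
              x$m_dist_min, x$m_dist_max, x$m_seq))
  invisible(x)
}
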