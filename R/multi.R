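#' All-vs-all pairwise comparison of a pocket set
#'
#' Enumerates every ordered pocket pair including self-pairs (`N^2`
#' records for `N` pockets).  Each unordered pair is computed once with
#' [align_pair()] (scores are symmetric) and mirrored.  A failing pair is
#' recorded with its error message rather than aborting the run, and the
#' result is independent of the worker count and enumeration order.
#'
#' @param pockets list of `Pocket` objects (names ignored; pocket ids are
#'   taken from the objects and must be unique).
#' @param workers parallel worker count (forked processes; default 1).
#' @param compare_fun optional replacement comparison returning a list
#'   with elements `n_matched`, `rmsd`, `m_dist_min`, `m_dist_max`,
#'   `m_seq` for a pocket pair; defaults to [align_pair()].  Useful for
#'   enumeration-scale runs with stubbed scoring.
#' @param ... passed to [align_pair()] when `compare_fun` is NULL.
#' @return data.frame with one row per ordered pair: `id_a`, `id_b`,
#'   `n_a`, `n_b`, `n_matched`, `rmsd`, `m_dist_min`, `m_dist_max`,
#'   `m_seq`, `error` (`NA` or message), ordered by pocket index.
#' @export
all_vs_all <- function(pockets, workers = 1, compare_fun = NULL, ...) {
  n <- length(pockets)
  if (n < 1) pm_data_error("all_vs_all needs at least one pocket")
  ids <- vapply(pockets, function(p) p$pocket_id, "")
  if (anyDuplicated(ids))
    pm_data_error("duplicate pocket ids: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sizes <- vapply(pockets, function(p)
    if (is_pocket(p)) pocket_size(p) else NA_integer_, 0L)
  if (is.null(compare_fun)) {
    dots <- list(...)
    compare_fun <- function(pa, pb) {
      a <- do.call(align_pair, c(list(pa, pb), dots))
      list(n_matched = a$n_matched, rmsd = a$rmsd,
           m_dist_min = a$m_dist_min, m_dist_max = a$m_dist_max,
           m_seq = a$m_seq)
    }
  }
  # unordered pairs including self, in row-major upper-triangle order
  ia <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  ib <- unlist(lapply(seq_len(n), function(i) i:n), use.names = FALSE)
  npair <- length(ia)
  chunk_starts <- seq(1L, npair, by = 20000L)
  chunks <- lapply(chunk_starts, function(s)
    seq(s, min(s + 19999L, npair)))
  chunk_res <- parallel_map(chunks, function(idx) {
    m <- matrix(NA_real_, length(idx), 5)
    err <- rep(NA_character_, length(idx))
    for (q in seq_along(idx)) {
      i <- ia[idx[q]]; j <- ib[idx[q]]
      r <- tryCatch(compare_fun(pockets[[i]], pockets[[j]]),
                    error = function(e) conditionMessage(e))
      if (is.character(r)) err[q] <- r
      else m[q, ] <- c(r$n_matched, r$rmsd, r$m_dist_min, r$m_dist_max,
                       r$m_seq)
    }
    list(m = m, err = err)
  }, workers = workers)
  bad <- !vapply(chunk_res, `[[`, TRUE, "ok")
  if (any(bad))
    pm_data_error("all_vs_all chunk failure: ",
                  chunk_res[[which(bad)[1]]]$error)
  m <- do.call(rbind, lapply(chunk_res, function(x) x$value$m))
  err <- unlist(lapply(chunk_res, function(x) x$value$err))
  up <- data.frame(
    id_a = ids[ia], id_b = ids[ib], n_a = sizes[ia], n_b = sizes[ib],
    n_matched = m[, 1], rmsd = m[, 2], m_dist_min = m[, 3],
    m_dist_max = m[, 4], m_seq = m[, 5], error = err,
    stringsAsFactors = FALSE)
  lo <- up[ia != ib, c("id_b", "id_a", "n_b", "n_a", "n_matched", "rmsd",
                       "m_dist_min", "m_dist_max", "m_seq", "error")]
  names(lo) <- names(up)
  out <- rbind(up, lo)
  ord <- order(match(out$id_a, ids), match(out$id_b, ids))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the pocket similarity network
#'
#' Pockets are nodes; an undirected edge joins two distinct pockets whose
#' `m_dist_max` score reaches the threshold (default 0.4, the value at
#' which known site similarities are captured).  Edge weight is
#' `m_dist_max`.
#'
#' @param scores all-vs-all score table from [all_vs_all()].
#' @param threshold minimum `m_dist_max` for an edge (default 0.4).
#' @return a `SimilarityNetwork`: list with `nodes`, `edges` (data.frame
#'   `id_a`, `id_b`, `weight` with `id_a < id_b`), `threshold`.
#' @export
build_network <- function(scores, threshold = 0.4) {
  need <- c("id_a", "id_b", "m_dist_max")
  stopifnot(all(need %in% names(scores)))
  nodes <- sort(unique(c(scores$id_a, scores$id_b)))
  off <- scores[scores$id_a != scores$id_b & is.na(scores$error), ,
                drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  k <- key(off$id_a, off$id_b)
  chk <- tapply(off$m_dist_max, k, function(v) diff(range(v)))
  if (any(chk > 1e-6))
    pm_data_error("asymmetric score table: m_dist_max(a,b) != ",
                  "m_dist_max(b,a) beyond 1e-6")
  keep <- off[off$id_a < off$id_b & off$m_dist_max >= threshold, ,
              drop = FALSE]
  edges <- data.frame(id_a = keep$id_a, id_b = keep$id_b,
                      weight = keep$m_dist_max, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$id_a, edges$id_b, sep = "\r")), ,
                 drop = FALSE]
  edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "SimilarityNetwork")
}

#' @export
print.SimilarityNetwork <- function(x, ...) {
  cat(sprintf("SimilarityNetwork: %d nodes, %d edges (threshold %.2f)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

network_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges))
    g <- igraph::add_edges(
      g, rbind(match(net$edges$id_a, net$nodes),
               match(net$edges$id_b, net$nodes)),
      weight = net$edges$weight)
  g
}

# MCODE-style vertex weight: highest k-core number of the vertex's closed
# neighbourhood times the density of that k-core.
mcode_vertex_weights <- function(g) {
  n <- igraph::vcount(g)
  w <- numeric(n)
  for (v in seq_len(n)) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0) next
    kv <- which(core == k)
    subk <- igraph::induced_subgraph(sub, kv)
    nv <- igraph::vcount(subk)
    dens <- if (nv > 1) 2 * igraph::ecount(subk) / (nv * (nv - 1)) else 0
    w[v] <- k * dens
  }
  w
}

#' Cluster the similarity network (MCODE-style)
#'
#' The dense-complex detection procedure: (1) every vertex is weighted by
#' the highest k-core number of its closed neighbourhood times that
#' k-core's density; (2) complexes are seeded from the highest-weighted
#' unseen vertex and expanded outwards through neighbours whose weight is
#' at least `(1 - node_score_cutoff)` of the seed weight; (3) a haircut
#' removes complex members with fewer than two connections inside the
#' complex.  Vertices in no complex become singleton clusters, so the
#' result is a deterministic partition that never spans two network
#' components.
#'
#' @param net a `SimilarityNetwork`.
#' @param node_score_cutoff expansion tolerance (default 0.2).
#' @param haircut logical, prune degree-<2 complex members (default TRUE).
#' @return list of `Cluster` objects (fields `members`, `representative`),
#'   complexes first (in seeding order), then singletons sorted by id.
#' @export
cluster_network <- function(net, node_score_cutoff = 0.2, haircut = TRUE) {
  stopifnot(inherits(net, "SimilarityNetwork"))
  g <- network_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) return(list())
  w <- mcode_vertex_weights(g)
  nm <- igraph::V(g)$name
  seen <- rep(FALSE, n)
  complexes <- list()
  for (seed in order(-w, nm)) {
    if (seen[seed] || w[seed] <= 0) next
    seen[seed] <- TRUE
    members <- seed
    queue <- seed
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in sort(as.integer(igraph::neighbors(g, v)))) {
        if (seen[u]) next
        if (w[u] >= (1 - node_score_cutoff) * w[seed]) {
          seen[u] <- TRUE
          members <- c(members, u)
          queue <- c(queue, u)
        }
      }
    }
    if (haircut && length(members) > 1) {
      sub <- igraph::induced_subgraph(g, members)
      dsub <- igraph::degree(sub)
      keep <- dsub[match(nm[members], igraph::V(sub)$name)] >= 2
      dropped <- members[!keep]
      seen[dropped] <- FALSE        # pruned members fall back to singletons
      members <- members[keep]
    }
    if (length(members) >= 2)
      complexes[[length(complexes) + 1L]] <- sort(nm[members])
    else if (length(members) == 1)
      seen[members] <- FALSE
  }
  singles <- sort(nm[!seen & !(nm %in% unlist(complexes))])
  all_members <- c(complexes, as.list(singles))
  lapply(all_members, function(mem) {
    structure(list(members = mem,
                   representative = select_representative_members(mem, net)),
              class = "Cluster")
  })
}

#' @export
print.Cluster <- function(x, ...) {
  cat(sprintf("Cluster of %d (representative %s): %s\n", length(x$members),
              x$representative, paste(x$members, collapse = ", ")))
  invisible(x)
}

select_representative_members <- function(members, net) {
  if (length(members) == 1) return(members)
  e <- net$edges
  inc <- e[e$id_a %in% members | e$id_b %in% members, , drop = FALSE]
  wdeg <- setNames(numeric(length(members)), members)
  if (nrow(inc)) {
    for (q in seq_len(nrow(inc))) {
      if (inc$id_a[q] %in% members)
        wdeg[inc$id_a[q]] <- wdeg[inc$id_a[q]] + inc$weight[q]
      if (inc$id_b[q] %in% members)
        wdeg[inc$id_b[q]] <- wdeg[inc$id_b[q]] + inc$weight[q]
    }
  }
  members[order(-wdeg, members)][1]
}

#' Select a cluster representative
#'
#' The member with the highest weighted degree (sum of incident
#' similarity-edge weights in the network); ties go to the
#' lexicographically smallest pocket id.  For the dense complexes the
#' clustering produces, member edges lie almost entirely inside the
#' cluster, so this coincides with the induced-subgraph degree in
#' practice.
#'
#' @param cluster a `Cluster` (or list with a `members` character vector).
#' @param net the `SimilarityNetwork` the cluster came from.
#' @return the representative pocket id.
#' @export
select_representative <- function(cluster, net) {
  members <- if (is.list(cluster)) cluster$members else cluster
  stopifnot(length(members) >= 1)
  select_representative_members(members, net)
}

#' Build a consensus profile by star alignment onto the representative
#'
#' Every cluster member is pairwise-aligned onto the representative
#' pocket; each representative residue defines one profile column.  A
#' member mapped onto a column contributes its residue type, sequence
#' position and (representative-frame) C-alpha position there; columns a
#' member does not reach are gaps for that member.
#'
#' @param cluster a `Cluster` with at least 3 members.
#' @param pockets named list of `Pocket` objects covering the members.
#' @param net optional `SimilarityNetwork` (only used to re-derive the
#'   representative if the cluster lacks one).
#' @param ... passed to [align_pair()].
#' @return a `ConsensusProfile`: list with `rep_id`, `members`, `columns`
#'   (data.frame `col`, `chain`, `resseq`, `icode`, `aa` of the
#'   representative), `occupancy` (fraction of members per column),
#'   `counts` (columns x 20 amino-acid count matrix), `mean_ca` (mean
#'   representative-frame C-alpha per column), `map_index` /
#'   `map_resseq` / `map_chain` (members x columns matrices of the mapped
#'   residue index / sequence number / chain, `NA` where gapped).
#' @export
build_profile <- function(cluster, pockets, net = NULL, ...) {
  members <- if (is.list(cluster)) cluster$members else cluster
  if (length(members) < 3)
    pm_data_error("consensus profiles need clusters of at least 3 members; ",
                  "got ", length(members))
  if (!all(members %in% names(pockets)))
    pm_data_error("pockets missing for members: ",
                  paste(setdiff(members, names(pockets)), collapse = ", "))
  rep_id <- if (!is.null(cluster$representative)) cluster$representative
  else select_representative(list(members = members), net)
  rp <- pockets[[rep_id]]
  ncol_ <- pocket_size(rp)
  nm <- length(members)
  counts <- matrix(0L, ncol_, length(AA20), dimnames = list(NULL, AA20))
  map_index <- matrix(NA_integer_, nm, ncol_, dimnames = list(members, NULL))
  map_resseq <- map_index
  map_chain <- matrix(NA_character_, nm, ncol_,
                      dimnames = list(members, NULL))
  ca_sum <- matrix(0, ncol_, 3)
  ca_n <- integer(ncol_)
  for (m in seq_along(members)) {
    mp <- pockets[[members[m]]]
    aln <- align_pair(rp, mp, ...)
    if (aln$n_matched == 0) {
      pm_log("WARN", sprintf("member %s failed to align onto %s; all gaps",
                             members[m], rep_id))
      next
    }
    ca_t <- sweep(mp$ca %*% aln$rotation, 2, aln$translation, `+`)
    for (q in seq_len(nrow(aln$pairs))) {
      i <- aln$pairs[q, 1]; j <- aln$pairs[q, 2]
      map_index[m, i] <- j
      map_resseq[m, i] <- mp$residues$resseq[j]
      map_chain[m, i] <- mp$residues$chain[j]
      aa <- mp$residues$aa[j]
      if (aa %in% AA20) counts[i, aa] <- counts[i, aa] + 1L
      ca_sum[i, ] <- ca_sum[i, ] + ca_t[j, ]
      ca_n[i] <- ca_n[i] + 1L
    }
  }
  mean_ca <- ca_sum / pmax(ca_n, 1L)
  mean_ca[ca_n == 0, ] <- NA_real_
  structure(list(
    rep_id = rep_id, members = members,
    columns = data.frame(col = seq_len(ncol_), chain = rp$residues$chain,
                         resseq = rp$residues$resseq,
                         icode = rp$residues$icode, aa = rp$residues$aa,
                         stringsAsFactors = FALSE),
    occupancy = rowSums(!is.na(t(map_index))) / nm,
    counts = counts, mean_ca = mean_ca,
    map_index = map_index, map_resseq = map_resseq,
    map_chain = map_chain), class = "ConsensusProfile")
}

#' @export
print.ConsensusProfile <- function(x, ...) {
  cat(sprintf(
    "ConsensusProfile on %s: %d columns, %d members, %d columns >= 0.7 occupancy\n",
    x$rep_id, nrow(x$columns), length(x$members), sum(x$occupancy >= 0.7)))
  invisible(x)
}
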