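# Shared fixture builders and independent oracles.  Everything is built in
# code at test time; no binary fixtures.

# Fixed-column PDB ATOM/HETATM record for hand-written structure fixtures.
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1.0, alt = " ", icode = " ", type = "ATOM",
                     element = substr(trimws(name), 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, paste0(" ", name), alt, resname, chain, resno,
          icode, x, y, z, occ, 0.0, element)
}

# A minimal well-formed residue: backbone N, CA, C, O plus CB (except GLY),
# laid out near the given CA position.
residue_lines <- function(serial0, resname, chain, resno, ca,
                          icode = " ") {
  l <- c(
    pdb_line(serial0, "N", resname, chain, resno, ca[1] - 1.2, ca[2],
             ca[3], icode = icode),
    pdb_line(serial0 + 1, "CA", resname, chain, resno, ca[1], ca[2],
             ca[3], icode = icode),
    pdb_line(serial0 + 2, "C", resname, chain, resno, ca[1] + 1.2,
             ca[2] + 0.6, ca[3], icode = icode),
    pdb_line(serial0 + 3, "O", resname, chain, resno, ca[1] + 1.2,
             ca[2] + 1.8, ca[3], icode = icode))
  if (resname != "GLY")
    l <- c(l, pdb_line(serial0 + 4, "CB", resname, chain, resno, ca[1],
                       ca[2] + 1.0, ca[3] + 1.1, icode = icode))
  l
}

write_structure_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Build a Pocket directly from CA coordinates (CB/CN placed deterministically
# just off CA; glycine/alanine degeneracies respected).
pocket_from_ca <- function(id, ca, aa = NULL, resseq = NULL, chain = "A",
                           icode = "") {
  n <- nrow(ca)
  if (is.null(aa)) aa <- rep(c("L", "K", "F", "S", "D"), length.out = n)
  if (is.null(resseq)) resseq <- seq_len(n)
  offs <- matrix(c(1, 0.8, 0.6), n, 3, byrow = TRUE)
  offs <- offs / sqrt(rowSums(offs^2))
  cb <- ca + 1.53 * offs
  cn <- cb + 1.2 * offs
  gly <- aa == "G"; ala <- aa == "A"
  cb[gly, ] <- ca[gly, ]; cn[gly, ] <- ca[gly, ]
  cn[ala, ] <- cb[ala, , drop = FALSE]
  new_pocket(id, data.frame(chain = chain, resseq = resseq, icode = icode,
                            aa = aa, stringsAsFactors = FALSE),
             ca, cb, cn)
}

# Random proper rotation (uniform via QR decomposition).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(pocket, R, t) {
  tr <- function(m) sweep(m %*% R, 2, t, `+`)
  pocket$ca <- tr(pocket$ca); pocket$cb <- tr(pocket$cb)
  pocket$cn <- tr(pocket$cn)
  pocket
}

# Independent oracle: exhaustive maximum dyad-compatible clique over all
# injective residue mappings (depth-first with a simple bound).  Returns 0
# when no compatible dyad (= no edge) exists.
brute_max_clique <- function(p1, p2, tol = 1.0) {
  d1 <- build_distance_matrix(p1)$d
  d2 <- build_distance_matrix(p2)$d
  n1 <- dim(d1)[1]; n2 <- dim(d2)[1]
  compat <- function(i, j, k, l)
    sqrt(mean((d1[i, k, ] - d2[j, l, ])^2)) < tol
  best <- 0L
  grow <- function(pairs, next_i, used_j) {
    len <- nrow(pairs)
    if (len + (n1 - next_i + 1) <= best) return()
    if (len > best && len >= 2) best <<- len
    if (next_i > n1) return()
    for (i in next_i:n1) {
      for (j in seq_len(n2)) {
        if (used_j[j]) next
        ok <- TRUE
        if (len > 0) for (q in seq_len(len)) {
          if (!compat(pairs[q, 1], pairs[q, 2], i, j)) { ok <- FALSE; break }
        }
        if (!ok) next
        used_j[j] <- TRUE
        grow(rbind(pairs, c(i, j)), i + 1L, used_j)
        used_j[j] <- FALSE
      }
    }
  }
  grow(matrix(integer(), 0, 2), 1L, rep(FALSE, n2))
  best
}

# Hand-built similarity network from an edge table (for clustering tests).
manual_network <- function(edges, nodes = NULL, threshold = 0.4) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$id_a, edges$id_b)))
  swap <- edges$id_a > edges$id_b
  tmp <- edges$id_a[swap]; edges$id_a[swap] <- edges$id_b[swap]
  edges$id_b[swap] <- tmp
  edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "SimilarityNetwork")
}
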