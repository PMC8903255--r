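#' Derive PROSITE-style structural motifs from a consensus profile
#'
#' Profile columns with occupancy at or above `occ_threshold` become motif
#' elements; each element's residue set collects the amino acids occurring
#' in at least `aa_freq_threshold` of the occupying members.  Elements are
#' ordered by the representative's sequence; where consecutive motif
#' columns are separated in sequence, the separations observed across
#' members become a variable gap `x(min,max)` (nothing is written when
#' the columns are adjacent in every member).  A separation beyond
#' `max_gap` splits the motif into sequentially discontinuous parts --
#' spatially one site, several sequence blocks, as in the two-part
#' glutathione-site motif.  Each element carries a 3D anchor: the mean
#' C-alpha position of its column in the representative frame.
#'
#' @param profile a `ConsensusProfile` from [build_profile()].
#' @param occ_threshold minimum column occupancy (default 0.7).
#' @param aa_freq_threshold minimum within-column residue frequency for
#'   set membership (default 0.1).
#' @param max_gap sequence separation above which the motif splits
#'   (default 30).
#' @return list of `Motif` objects (possibly empty when no column passes
#'   the occupancy threshold).
#' @export
derive_motif <- function(profile, occ_threshold = 0.7,
                         aa_freq_threshold = 0.1, max_gap = 30) {
  stopifnot(inherits(profile, "ConsensusProfile"))
  if (length(profile$members) < 3)
    pm_data_error("motif derivation needs a profile of >= 3 members")
  keep <- which(profile$occupancy >= occ_threshold)
  if (length(keep) == 0) return(list())
  # order by the representative's sequence
  cols <- profile$columns[keep, , drop = FALSE]
  ord <- order(cols$chain, cols$resseq, cols$icode)
  keep <- keep[ord]

  element_of <- function(ci) {
    cnt <- profile$counts[ci, ]
    occ_members <- sum(cnt)
    aa <- names(cnt)[cnt / max(occ_members, 1) >= aa_freq_threshold]
    aa <- aa[order(-cnt[aa], aa)]          # frequency-major, then alpha
    list(kind = "set", aa = aa,
         anchor = as.numeric(profile$mean_ca[ci, ]),
         occupancy = profile$occupancy[ci])
  }
  # pairwise sequence separation between consecutive kept columns, over
  # members mapped at both (the representative always contributes)
  separations <- function(c1, c2) {
    same <- !is.na(profile$map_resseq[, c1]) &
      !is.na(profile$map_resseq[, c2]) &
      profile$map_chain[, c1] == profile$map_chain[, c2]
    s <- profile$map_resseq[same, c2] - profile$map_resseq[same, c1] - 1L
    s[s >= 0]
  }

  motifs <- list()
  cur <- list(element_of(keep[1]))
  for (q in seq_along(keep)[-1]) {
    seps <- separations(keep[q - 1], keep[q])
    if (length(seps) == 0) seps <- 0L
    if (max(seps) > max_gap) {            # discontinuous part: split
      motifs[[length(motifs) + 1L]] <- cur
      cur <- list(element_of(keep[q]))
      next
    }
    if (max(seps) > 0)
      cur[[length(cur) + 1L]] <- list(kind = "gap", min = min(seps),
                                      max = max(seps))
    cur[[length(cur) + 1L]] <- element_of(keep[q])
  }
  motifs[[length(motifs) + 1L]] <- cur
  lapply(seq_along(motifs), function(k)
    structure(list(elements = motifs[[k]],
                   source_cluster = profile$rep_id,
                   part = k), class = "Motif"))
}

#' Render a motif as a pattern string
#'
#' Elements joined by `-`; residue sets with more than one member are
#' bracketed (`[CS]`), variable gaps written `x(min,max)`.
#'
#' @param motif a `Motif`.
#' @return pattern string such as `"[CS]-P-[FNWY]"`.
#' @export
motif_to_string <- function(motif) {
  stopifnot(inherits(motif, "Motif"))
  paste(vapply(motif$elements, function(e) {
    if (e$kind == "gap") sprintf("x(%d,%d)", e$min, e$max)
    else if (length(e$aa) == 1) e$aa
    else paste0("[", paste(e$aa, collapse = ""), "]")
  }, ""), collapse = "-")
}

#' @export
print.Motif <- function(x, ...) {
  cat("Motif:", motif_to_string(x), "\n")
  invisible(x)
}

#' Parse a motif pattern string
#'
#' Inverse of [motif_to_string()] for the grammar `ELEMENT(-ELEMENT)*`
#' where an element is a single residue letter, a bracketed set, or a gap
#' `x(m,n)` (case-insensitive `x`).  Motifs must start and end with a
#' residue element, gaps may not be consecutive, and `0 <= m <= n`.  The
#' result carries no anchor geometry (sequence-only scanning).
#'
#' @param s pattern string.
#' @return a geometry-free `Motif`.
#' @export
parse_motif <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  toks <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (length(toks) == 0 || !nzchar(s))
    stop("empty motif string")
  elements <- vector("list", length(toks))
  for (q in seq_along(toks)) {
    tk <- toks[q]
    if (grepl("^[A-Z]$", tk)) {
      if (!(tk %in% AA20)) stop("element ", q, " ('", tk,
                                "'): unknown residue letter")
      elements[[q]] <- list(kind = "set", aa = tk, anchor = NULL,
                            occupancy = NA_real_)
    } else if (grepl("^\\[[A-Z]+\\]$", tk)) {
      aa <- strsplit(gsub("\\[|\\]", "", tk), "")[[1]]
      if (!all(aa %in% AA20)) stop("element ", q, " ('", tk,
                                   "'): unknown residue letter")
      elements[[q]] <- list(kind = "set", aa = aa, anchor = NULL,
                            occupancy = NA_real_)
    } else if (grepl("^[xX]\\([0-9]+,[0-9]+\\)$", tk)) {
      mm <- as.integer(strsplit(gsub("^[xX]\\(|\\)$", "", tk), ",")[[1]])
      if (mm[1] > mm[2]) stop("element ", q, " ('", tk,
                              "'): gap min exceeds max")
      elements[[q]] <- list(kind = "gap", min = mm[1], max = mm[2])
    } else {
      stop("element ", q, " ('", tk, "'): cannot parse")
    }
  }
  kinds <- vapply(elements, `[[`, "", "kind")
  if (kinds[1] == "gap" || kinds[length(kinds)] == "gap")
    stop("motif must start and end with a residue element")
  if (any(kinds[-1] == "gap" & kinds[-length(kinds)] == "gap"))
    stop("consecutive gaps are not allowed")
  structure(list(elements = elements, source_cluster = NA_character_,
                 part = 1L), class = "Motif")
}

# rigid-fit RMSD of assigned C-alpha onto anchors; closed forms for the
# underdetermined 1- and 2-point cases
anchor_rmsd <- function(anchors, ca) {
  m <- nrow(anchors)
  if (m == 1) return(0)
  if (m == 2) {
    d1 <- sqrt(sum((anchors[1, ] - anchors[2, ])^2))
    d2 <- sqrt(sum((ca[1, ] - ca[2, ])^2))
    return(abs(d1 - d2) / 2)
  }
  fit <- tryCatch(kabsch_superpose(anchors, ca), error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  fit$rmsd
}

#' Scan a motif against a pocket
#'
#' Searches for an injective assignment of pocket residues to the motif's
#' residue-set elements such that (a) every assigned residue's type
#' belongs to its element's set, (b) assigned residues sit on one chain
#' in increasing sequence order with separations satisfying the gap
#' elements (adjacent elements demand adjacent residues), and (c) in
#' structural mode, the Kabsch superposition of the assigned C-alpha
#' positions onto the element anchors has RMSD at most `geom_tol`.
#' Structural mode is used whenever the motif carries anchors and can be
#' disabled with `mode = "sequence"` (e.g. for motifs from
#' [parse_motif()]).
#'
#' @param motif a `Motif`.
#' @param pocket a `Pocket`.
#' @param geom_tol structural-mode RMSD tolerance in Angstrom
#'   (default 1.5).
#' @param mode `"auto"` (structural when anchors exist), `"structural"`,
#'   or `"sequence"`.
#' @return `NULL` when the pocket does not match; otherwise a list with
#'   `residues` (pocket residue indices per element), `rmsd` (`NA` in
#'   sequence mode) -- the minimum-RMSD assignment in structural mode.
#' @export
scan_motif <- function(motif, pocket, geom_tol = 1.5,
                       mode = c("auto", "structural", "sequence")) {
  stopifnot(inherits(motif, "Motif"), is_pocket(pocket))
  mode <- match.arg(mode)
  sets <- Filter(function(e) e$kind == "set", motif$elements)
  has_anchors <- all(vapply(sets, function(e) !is.null(e$anchor), TRUE))
  if (mode == "structural" && !has_anchors)
    pm_data_error("motif has no anchor geometry; structural scan impossible")
  structural <- (mode == "auto" && has_anchors) || mode == "structural"
  # gap window before each set element (elements after the first)
  lo <- integer(length(sets)); hi <- integer(length(sets))
  si <- 0L
  pending <- NULL
  for (e in motif$elements) {
    if (e$kind == "gap") { pending <- e; next }
    si <- si + 1L
    if (si > 1) {
      if (is.null(pending)) { lo[si] <- 0L; hi[si] <- 0L }
      else { lo[si] <- pending$min; hi[si] <- pending$max }
    }
    pending <- NULL
  }
  res <- pocket$residues
  anchors <- if (structural)
    do.call(rbind, lapply(sets, `[[`, "anchor"))
  best <- NULL
  assign_next <- function(si, chosen) {
    if (si > length(sets)) {
      if (!structural) {
        if (is.null(best)) best <<- list(residues = chosen, rmsd = NA_real_)
        return()
      }
      r <- anchor_rmsd(anchors, pocket$ca[chosen, , drop = FALSE])
      if (r <= geom_tol && (is.null(best) || r < best$rmsd))
        best <<- list(residues = chosen, rmsd = r)
      return()
    }
    cand <- which(res$aa %in% sets[[si]]$aa)
    if (si > 1) {
      prev <- chosen[si - 1]
      sep <- res$resseq[cand] - res$resseq[prev] - 1L
      cand <- cand[res$chain[cand] == res$chain[prev] &
                     sep >= lo[si] & sep <= hi[si]]
    }
    for (j in setdiff(cand, chosen)) assign_next(si + 1L, c(chosen, j))
  }
  assign_next(1L, integer())
  best
}

#' Export a profile's position-frequency matrix
#'
#' Writes a tab-separated columns-by-amino-acid table of counts and
#' normalised frequencies (counts divided by the column's occupying
#' member count), consumable by standard sequence-logo renderers.
#'
#' @param profile a `ConsensusProfile`.
#' @param path output TSV path.
#' @return the matrix (invisibly); side effect: the file.
#' @export
export_logo_matrix <- function(profile, path) {
  stopifnot(inherits(profile, "ConsensusProfile"))
  cnt <- profile$counts
  tot <- rowSums(cnt)
  freq <- cnt / pmax(tot, 1)
  out <- data.frame(col = profile$columns$col,
                    chain = profile$columns$chain,
                    resseq = profile$columns$resseq,
                    occupancy = profile$occupancy,
                    stringsAsFactors = FALSE)
  cntdf <- as.data.frame(cnt)
  names(cntdf) <- paste0("count_", AA20)
  freqdf <- as.data.frame(round(freq, 6))
  names(freqdf) <- paste0("freq_", AA20)
  out <- cbind(out, cntdf, freqdf)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
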