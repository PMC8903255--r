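#' Load a PDB-format structure
#'
#' Parses a PDB file (through [bio3d::read.pdb]) and applies the package's
#' conformer policy: only model 1 is kept when several MODEL records exist,
#' and for alternate locations the highest-occupancy conformer wins (ties:
#' first encountered).  Hydrogen atoms are retained but flagged, so that
#' distance tests can exclude them.
#'
#' @param path path to a readable PDB-format file.
#' @return a `pm_structure` object: a list with an `atoms` data.frame
#'   (columns `type`, `chain`, `resno`, `insert`, `resid`, `elety`, `x`,
#'   `y`, `z`, `occ`, `is_h`) and the source `path`.
#' @export
load_structure <- function(path) {
  if (!file.exists(path))
    pm_data_error("structure file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM|HETATM)", txt)))
    pm_data_error("no ATOM/HETATM records in ", path,
                  " (first line: '", if (length(txt)) txt[1] else "", "')")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) pm_data_error("failed to parse PDB file ", path,
                                      ": ", conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0) pm_data_error("empty structure: ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1.0

  # Altloc policy: within one (chain, resno, insert, atom-name) group keep
  # the highest-occupancy record; ties broken by file order.
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(rownames(at), rownames(pdb$atom))), , drop = FALSE]

  elesy <- if ("elesy" %in% names(at)) toupper(trimws(at$elesy)) else ""
  is_h <- elesy %in% c("H", "D") |
    (!nzchar(elesy) & grepl("^[0-9]*[HD]", trimws(at$elety)))
  atoms <- data.frame(
    type = at$type, chain = at$chain, resno = as.integer(at$resno),
    insert = at$insert, resid = at$resid, elety = trimws(at$elety),
    x = at$x, y = at$y, z = at$z, occ = at$o, is_h = is_h,
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, path = path), class = "pm_structure")
}

#' @export
print.pm_structure <- function(x, ...) {
  cat(sprintf("pm_structure: %d atoms from %s\n", nrow(x$atoms), x$path))
  invisible(x)
}

# Residues regarded as protein: ATOM records, plus HETATM records whose
# residue name has a known parent amino acid (e.g. MSE).  Waters and other
# heteroatoms never count.
protein_atom_mask <- function(atoms) {
  atoms$type == "ATOM" & atoms$resid != "HOH" |
    (atoms$type == "HETATM" & atoms$resid %in% names(HET_TO_PARENT))
}

#' List HETATM groups available in a structure
#'
#' @param structure a `pm_structure`.
#' @return data.frame with columns `het`, `chain`, `resno`, `n_atoms`.
#' @export
list_ligands <- function(structure) {
  at <- structure$atoms
  lig <- at[at$type == "HETATM" & !(at$resid %in% c("HOH")) &
              !(at$resid %in% names(HET_TO_PARENT)), , drop = FALSE]
  if (nrow(lig) == 0)
    return(data.frame(het = character(), chain = character(),
                      resno = integer(), n_atoms = integer()))
  agg <- stats::aggregate(seq_len(nrow(lig)),
                          by = list(het = lig$resid, chain = lig$chain,
                                    resno = lig$resno),
                          FUN = length)
  names(agg)[4] <- "n_atoms"
  agg[order(agg$chain, agg$resno), , drop = FALSE]
}

#' Extract the binding site around a bound ligand
#'
#' The binding site is the set of protein residues having at least one
#' non-hydrogen atom within `cutoff` (default 4.5 Angstrom) of any
#' non-hydrogen atom of the selected ligand copy.  Waters and other
#' heteroatoms are never pocket residues.  Each residue is reduced to the
#' three-point representation via [three_point_representation()].
#'
#' @param structure a `pm_structure` from [load_structure()].
#' @param ligand_selector list or vector `(het, chain, resno)` naming exactly
#'   one HETATM residue group.
#' @param cutoff positive distance threshold in Angstrom (default 4.5).
#' @return a [new_pocket()] `Pocket`.
#' @export
extract_binding_site <- function(structure, ligand_selector, cutoff = 4.5) {
  stopifnot(inherits(structure, "pm_structure"), cutoff > 0)
  sel <- as.list(ligand_selector)
  if (length(sel) != 3) stop("ligand_selector must be (het, chain, resno)")
  het <- as.character(sel[[1]]); chain <- as.character(sel[[2]])
  resno <- as.integer(sel[[3]])
  at <- structure$atoms
  lig <- at$type == "HETATM" & at$resid == het & at$chain == chain &
    at$resno == resno & !at$is_h
  if (!any(lig)) {
    avail <- list_ligands(structure)
    pm_data_error("ligand ", het, ":", chain, ":", resno, " not found in ",
                  structure$path, "; available het groups: ",
                  if (nrow(avail)) paste(avail$het, avail$chain, avail$resno,
                                         sep = ":", collapse = ", ")
                  else "(none)")
  }
  prot <- protein_atom_mask(at) & !at$is_h
  lxyz <- as.matrix(at[lig, c("x", "y", "z")])
  pxyz <- as.matrix(at[prot, c("x", "y", "z")])
  if (nrow(pxyz) == 0) pm_data_error("no protein atoms in ", structure$path)
  # nearest-ligand-atom distance for every protein atom
  d2min <- rep(Inf, nrow(pxyz))
  for (k in seq_len(nrow(lxyz))) {
    d2 <- (pxyz[, 1] - lxyz[k, 1])^2 + (pxyz[, 2] - lxyz[k, 2])^2 +
      (pxyz[, 3] - lxyz[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  near <- d2min <= cutoff^2
  pat <- at[prot, , drop = FALSE]
  rkey <- paste(pat$chain, pat$resno, pat$insert, sep = "\r")
  keep <- unique(rkey[near])
  if (length(keep) == 0)
    pm_data_error("empty site: no residue within ", cutoff, " A of ",
                  het, ":", chain, ":", resno)
  res3p <- list()
  for (k in keep) {
    ratoms <- pat[rkey == k, , drop = FALSE]
    rp <- three_point_representation(ratoms)
    if (!is.null(rp)) res3p[[length(res3p) + 1L]] <- rp
  }
  pocket_from_res3p(
    res3p,
    pocket_id = paste0(sub("\\.pdb$", "", basename(structure$path)), "_",
                       het, "_", chain, resno),
    ligand_id = het,
    source = sprintf("%s %s:%s:%d cutoff=%g", structure$path, het, chain,
                     resno, cutoff))
}

#' Three-point representation of one parsed residue
#'
#' Reduces a residue's atoms to `ca` (C-alpha), `cb` (C-beta) and `cn`
#' (unweighted centroid of the side-chain heavy atoms, C-beta included;
#' backbone N, CA, C, O and hydrogens excluded).  Glycine gets
#' `cb = cn = ca`; for alanine `cn = cb`.  A missing C-beta on a
#' non-glycine residue is rebuilt from N, CA and C at ideal tetrahedral
#' geometry; a side chain missing beyond C-beta is treated like alanine.
#'
#' @param residue_atoms data.frame of one residue's atoms with columns
#'   `chain`, `resno`, `insert`, `resid`, `elety`, `x`, `y`, `z`, `is_h`.
#' @return a list with fields `chain`, `resseq`, `icode`, `aa`, `ca`, `cb`,
#'   `cn`, or `NULL` (with a logged warning) when the residue has no
#'   C-alpha.
#' @export
three_point_representation <- function(residue_atoms) {
  ra <- residue_atoms
  aa <- aa_one_letter(ra$resid[1])
  getxyz <- function(name) {
    i <- which(ra$elety == name)
    if (length(i) == 0) return(NULL)
    as.numeric(ra[i[1], c("x", "y", "z")])
  }
  ca <- getxyz("CA")
  if (is.null(ca)) {
    pm_log("WARN", sprintf("residue %s %s%d%s has no CA atom; skipped",
                           ra$resid[1], ra$chain[1], ra$resno[1],
                           ra$insert[1]))
    return(NULL)
  }
  if (aa == "G") {
    cb <- ca; cn <- ca
  } else {
    cb <- getxyz("CB")
    if (is.null(cb)) {
      n <- getxyz("N"); c <- getxyz("C")
      if (is.null(n) || is.null(c)) {
        pm_log("WARN", sprintf(
          "residue %s %s%d%s lacks CB and backbone N/C; using CA as CB",
          ra$resid[1], ra$chain[1], ra$resno[1], ra$insert[1]))
        cb <- ca
      } else {
        cb <- ideal_cb(n, ca, c)
      }
    }
    side <- !ra$is_h & !(ra$elety %in% c("N", "CA", "C", "O", "OXT"))
    sxyz <- as.matrix(ra[side, c("x", "y", "z"), drop = FALSE])
    cn <- if (nrow(sxyz) == 0 || aa == "A") cb else colMeans(sxyz)
  }
  list(chain = ra$chain[1], resseq = as.integer(ra$resno[1]),
       icode = ra$insert[1], aa = aa,
       ca = as.numeric(ca), cb = as.numeric(cb), cn = as.numeric(cn))
}

# Ideal C-beta position from backbone N, CA, C (tetrahedral geometry).
ideal_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

pocket_from_res3p <- function(res3p, pocket_id, ligand_id = "", source = "") {
  if (length(res3p) < 3)
    pm_data_error("a pocket needs at least 3 residues with CA atoms; got ",
                  length(res3p), " (pocket '", pocket_id, "')")
  residues <- data.frame(
    chain = vapply(res3p, `[[`, "", "chain"),
    resseq = vapply(res3p, `[[`, 0L, "resseq"),
    icode = vapply(res3p, `[[`, "", "icode"),
    aa = vapply(res3p, `[[`, "", "aa"),
    stringsAsFactors = FALSE)
  new_pocket(pocket_id, residues,
             ca = do.call(rbind, lapply(res3p, `[[`, "ca")),
             cb = do.call(rbind, lapply(res3p, `[[`, "cb")),
             cn = do.call(rbind, lapply(res3p, `[[`, "cn")),
             ligand_id = ligand_id, source = source)
}

#' Write a pocket to a PDB-fragment file
#'
#' Emits one ATOM record per stored point (CA, CB and a pseudo-atom named
#' CN for the side-chain centroid; glycine gets only CA, alanine CA + CB),
#' preceded by REMARK lines carrying the pocket id and ligand id.  The file
#' is a valid PDB fragment readable by standard viewers and by
#' [read_pocket_file()].
#'
#' @param pocket a `Pocket`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pocket_file <- function(pocket, path) {
  stopifnot(is_pocket(pocket))
  res <- pocket$residues
  lines <- c(sprintf("REMARK 900 POCKET %s", pocket$pocket_id),
             sprintf("REMARK 900 LIGAND %s",
                     if (nzchar(pocket$ligand_id)) pocket$ligand_id else "-"))
  serial <- 0L
  fmt <- function(name, resname, chain, resno, icode, xyz) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, paste0(" ", name), resname, chain, resno,
            if (nzchar(icode)) icode else " ",
            xyz[1], xyz[2], xyz[3], 1.0, 0.0, "C")
  }
  for (i in seq_len(nrow(res))) {
    aa <- res$aa[i]
    resname <- if (aa == "X") "UNK" else AA_1TO3[[aa]]
    lines <- c(lines, fmt("CA", resname, res$chain[i], res$resseq[i],
                          res$icode[i], pocket$ca[i, ]))
    if (aa != "G") {
      lines <- c(lines, fmt("CB", resname, res$chain[i], res$resseq[i],
                            res$icode[i], pocket$cb[i, ]))
      if (aa != "A")
        lines <- c(lines, fmt("CN", resname, res$chain[i], res$resseq[i],
                              res$icode[i], pocket$cn[i, ]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a pocket file written by [write_pocket_file()]
#'
#' Accepts any PDB fragment of site residues: CA is required per residue
#' (residues without one are skipped with a warning); CB and the CN
#' centroid pseudo-atom are used when present and otherwise filled in by
#' the glycine/alanine rules.
#'
#' @param path pocket PDB file.
#' @return a `Pocket`.
#' @export
read_pocket_file <- function(path) {
  if (!file.exists(path)) pm_data_error("pocket file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  idline <- grep("^REMARK 900 POCKET ", txt, value = TRUE)
  pocket_id <- if (length(idline)) trimws(sub("^REMARK 900 POCKET ", "",
                                              idline[1]))
  else sub("\\.pdb$", "", basename(path))
  ligline <- grep("^REMARK 900 LIGAND ", txt, value = TRUE)
  ligand_id <- if (length(ligline)) {
    v <- trimws(sub("^REMARK 900 LIGAND ", "", ligline[1]))
    if (v == "-") "" else v
  } else ""
  s <- load_structure(path)
  at <- s$atoms
  at <- at[protein_atom_mask(at) | at$resid == "UNK", , drop = FALSE]
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  res3p <- list()
  for (k in unique(rkey)) {
    ra <- at[rkey == k, , drop = FALSE]
    cn_row <- which(ra$elety == "CN")
    rp <- three_point_representation(ra[ra$elety != "CN", , drop = FALSE])
    if (is.null(rp)) next
    if (length(cn_row)) # stored centroid wins over re-derivation
      rp$cn <- as.numeric(ra[cn_row[1], c("x", "y", "z")])
    res3p[[length(res3p) + 1L]] <- rp
  }
  pocket_from_res3p(res3p, pocket_id = pocket_id, ligand_id = ligand_id,
                    source = path)
}
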