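#' Construct a Pocket object
#'
#' A `Pocket` is an ordered set of binding-site residues, each reduced to the
#' three-point representation: the C-alpha atom (`ca`), the C-beta atom
#' (`cb`) and the unweighted centroid of the side-chain heavy atoms (`cn`).
#' Glycine carries only its C-alpha (`cb` and `cn` both equal `ca`); for
#' alanine the C-beta doubles as the centroid (`cn == cb`).  Residues are
#' stored in `(chain, resseq, icode)` order, so sequence separations are
#' computable from `resseq`.
#'
#' @param pocket_id single string identifying the pocket.
#' @param residues data.frame with columns `chain`, `resseq` (integer),
#'   `icode` (may be `""`) and `aa` (one-letter code, `"X"` allowed).
#' @param ca,cb,cn numeric matrices, one row per residue, 3 columns
#'   (Angstrom coordinates).
#' @param ligand_id optional ligand identifier (free text, may be `""`).
#' @param source optional free-text provenance.
#' @return an object of class `Pocket`.
#' @export
new_pocket <- function(pocket_id, residues, ca, cb, cn,
                       ligand_id = "", source = "") {
  stopifnot(is.character(pocket_id), length(pocket_id) == 1L)
  residues <- as.data.frame(residues, stringsAsFactors = FALSE)
  need <- c("chain", "resseq", "icode", "aa")
  if (!all(need %in% names(residues)))
    stop("residues must have columns: ", paste(need, collapse = ", "))
  n <- nrow(residues)
  if (n < 3L)
    pm_data_error("a pocket needs at least 3 residues; got ", n,
                  " (pocket '", pocket_id, "')")
  ca <- as.matrix(ca); cb <- as.matrix(cb); cn <- as.matrix(cn)
  stopifnot(nrow(ca) == n, nrow(cb) == n, nrow(cn) == n,
            ncol(ca) == 3, ncol(cb) == 3, ncol(cn) == 3)
  residues$resseq <- as.integer(residues$resseq)
  residues$icode <- as.character(residues$icode)
  residues$chain <- as.character(residues$chain)
  bad <- !(residues$aa %in% c(AA20, "X"))
  if (any(bad))
    stop("unknown amino-acid code(s): ",
         paste(unique(residues$aa[bad]), collapse = ", "))
  key <- paste(residues$chain, residues$resseq, residues$icode)
  if (anyDuplicated(key))
    stop("duplicate (chain, resseq, icode) in pocket '", pocket_id, "'")
  ord <- order(residues$chain, residues$resseq, residues$icode)
  residues <- residues[ord, , drop = FALSE]
  rownames(residues) <- NULL
  ca <- ca[ord, , drop = FALSE]
  cb <- cb[ord, , drop = FALSE]
  cn <- cn[ord, , drop = FALSE]
  dimnames(ca) <- dimnames(cb) <- dimnames(cn) <- NULL

  gly <- residues$aa == "G"
  if (any(gly)) {
    if (max(abs(cb[gly, , drop = FALSE] - ca[gly, , drop = FALSE])) > 1e-6 ||
        max(abs(cn[gly, , drop = FALSE] - ca[gly, , drop = FALSE])) > 1e-6)
      stop("glycine residues must have cb == cn == ca")
  }
  ala <- residues$aa == "A"
  if (any(ala)) {
    if (max(abs(cn[ala, , drop = FALSE] - cb[ala, , drop = FALSE])) > 1e-6)
      stop("alanine residues must have cn == cb")
  }
  dcb <- sqrt(rowSums((ca - cb)^2))
  if (any(dcb[!gly] > 2.0))
    stop("CA-CB distance above 2.0 A for a non-glycine residue in pocket '",
         pocket_id, "'")

  structure(
    list(pocket_id = pocket_id, residues = residues,
         ca = ca, cb = cb, cn = cn,
         ligand_id = ligand_id, source = source),
    class = "Pocket"
  )
}

#' @export
print.Pocket <- function(x, ...) {
  cat(sprintf("Pocket '%s': %d residues%s\n", x$pocket_id, nrow(x$residues),
              if (nzchar(x$ligand_id)) paste0(" (ligand ", x$ligand_id, ")")
              else ""))
  cat(" sequence:", paste(x$residues$aa, collapse = ""), "\n")
  invisible(x)
}

#' Number of residues in a pocket
#' @param pocket a `Pocket`.
#' @return integer residue count.
#' @export
pocket_size <- function(pocket) nrow(pocket$residues)

is_pocket <- function(x) inherits(x, "Pocket")

# Deterministic ordering key used to canonicalise alignment direction, so
# that scores for (P1, P2) and (P2, P1) are identical to the last bit.
pocket_key <- function(pocket) {
  paste(pocket_size(pocket), pocket$pocket_id,
        paste(sprintf("%.3f", as.numeric(t(pocket$ca))), collapse = ","),
        sep = "|")
}

# Apply a rigid motion x -> x R + t (row-vector convention) to all three
# point sets of a pocket.
transform_pocket <- function(pocket, rotation, translation) {
  tr <- function(m) sweep(m %*% rotation, 2, translation, `+`)
  pocket$ca <- tr(pocket$ca)
  pocket$cb <- tr(pocket$cb)
  pocket$cn <- tr(pocket$cn)
  pocket
}
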