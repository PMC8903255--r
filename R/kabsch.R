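#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation `R` (det +1, reflections corrected) and
#' translation `t` minimising the RMSD of `points_b` mapped onto
#' `points_a`, i.e. minimising `||A - (B R + t)||` in the row-vector
#' convention `x -> x R + t`.
#'
#' @param points_a,points_b numeric m x 3 matrices of paired points,
#'   `m >= 3`, not all collinear.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom over the input pairs).
#' @export
kabsch_superpose <- function(points_a, points_b) {
  A <- as.matrix(points_a); B <- as.matrix(points_b)
  stopifnot(ncol(A) == 3, ncol(B) == 3, nrow(A) == nrow(B))
  m <- nrow(A)
  if (m < 3) stop("kabsch_superpose needs at least 3 point pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  # rank < 2 means all points (near-)collinear: rotation underdetermined
  if (sum(svd(Ac)$d > 1e-8) < 2 || sum(svd(Bc)$d > 1e-8) < 2)
    stop("degenerate (collinear) point configuration")
  C <- crossprod(Bc, Ac)            # maximise tr(R' C) over rotations
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- ca - as.numeric(cb %*% R)
  Bt <- sweep(B %*% R, 2, t, `+`)
  rmsd <- sqrt(mean(rowSums((A - Bt)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}
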