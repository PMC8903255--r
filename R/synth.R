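#' Generate a synthetic binding pocket
#'
#' Samples `n` residues with uniformly random types inside a sphere of the
#' given diameter, enforcing a minimum pairwise C-alpha separation of
#' 3.5 Angstrom by rejection sampling.  C-beta sits 1.53 Angstrom from
#' C-alpha in a random direction and the side-chain centroid 0.5--2.5
#' Angstrom beyond C-beta (outward-biased random direction); glycine and
#' alanine follow the three-point degeneracy rules.  Deterministic for a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param n number of residues (3 to 50).
#' @param seed integer RNG seed.
#' @param diameter sphere diameter in Angstrom (default 20).
#' @param pocket_id optional id (default derived from `n` and `seed`).
#' @return a `Pocket` with chain `"A"` and residue numbers `1..n`.
#' @export
generate_synthetic_pocket <- function(n, seed, diameter = 20,
                                      pocket_id = NULL) {
  if (n < 3 || n > 50) pm_data_error("n must be between 3 and 50; got ", n)
  if (is.null(pocket_id)) pocket_id <- sprintf("synth_n%d_s%d", n, seed)
  with_seed(seed, {
    radius <- diameter / 2
    ca <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    max_tries <- 2000L * n
    while (placed < n) {
      if ((tries <- tries + 1L) > max_tries)
        pm_data_error("could not place ", n, " residues at >= 3.5 A ",
                      "separation inside a ", diameter,
                      " A sphere; increase diameter")
      p <- as.numeric(random_unit3()) * radius * runif(1)^(1 / 3)
      if (placed > 0) {
        d2 <- rowSums(sweep(ca[seq_len(placed), , drop = FALSE], 2, p)^2)
        if (min(d2) < 3.5^2) next
      }
      placed <- placed + 1L
      ca[placed, ] <- p
    }
    aa <- sample(AA20, n, replace = TRUE)
    cb <- ca + 1.53 * random_unit3(n)
    out_dir <- cb - ca + 0.5 * random_unit3(n)
    out_dir <- out_dir / sqrt(rowSums(out_dir^2))
    cn <- cb + runif(n, 0.5, 2.5) * out_dir
    gly <- aa == "G"
    cb[gly, ] <- ca[gly, ]; cn[gly, ] <- ca[gly, ]
    ala <- aa == "A"
    cn[ala, ] <- cb[ala, ]
    new_pocket(pocket_id,
               data.frame(chain = "A", resseq = seq_len(n), icode = "",
                          aa = aa, stringsAsFactors = FALSE),
               ca, cb, cn, source = sprintf("synthetic seed=%d", seed))
  })
}

#' Perturb residue positions to an exact target RMSD
#'
#' Displaces one or more residues rigidly (all three points of a residue
#' move together) along independent random directions, then rescales the
#' displacement field so the realized C-alpha RMSD to the original pocket
#' equals `target_rmsd` to within 1e-6.  Residue types are unchanged.
#'
#' The number of displaced residues grows with the requested magnitude:
#' by default `n_move = max(1, round(n * (target_rmsd / 14)^2))`, so a
#' small target RMSD corresponds to a few strongly displaced residues
#' (the rest of the site untouched) while the top of the studied 0--14
#' Angstrom range displaces the whole pocket.  Every displaced residue
#' moves by the same magnitude `target_rmsd * sqrt(n / n_move)`.  Pass
#' `n_move` explicitly to fix the subset size.
#'
#' @param pocket a `Pocket`.
#' @param target_rmsd target C-alpha RMSD in Angstrom (`>= 0`).
#' @param seed integer RNG seed.
#' @param n_move number of residues to displace (default: scaled with
#'   `target_rmsd` as described above).
#' @return the perturbed `Pocket` (id suffixed with `"_pert"`).
#' @export
perturb_positions <- function(pocket, target_rmsd, seed, n_move = NULL) {
  stopifnot(is_pocket(pocket), target_rmsd >= 0)
  n <- pocket_size(pocket)
  if (is.null(n_move))
    n_move <- max(1L, min(n, as.integer(round(n * (target_rmsd / 14)^2))))
  stopifnot(n_move >= 1, n_move <= n)
  with_seed(seed, {
    delta <- matrix(0, n, 3)
    idx <- if (n_move == n) seq_len(n) else sort(sample.int(n, n_move))
    delta[idx, ] <- random_unit3(length(idx))
    cur <- sqrt(mean(rowSums(delta^2)))   # = sqrt(n_move / n)
    if (target_rmsd > 0) delta <- delta * (target_rmsd / cur)
    else delta[] <- 0
    pocket$ca <- pocket$ca + delta
    pocket$cb <- pocket$cb + delta
    pocket$cn <- pocket$cn + delta
    pocket$pocket_id <- paste0(pocket$pocket_id, "_pert")
    pocket
  })
}

#' Mutate a fraction of residue types
#'
#' `round(fraction * n)` residues, chosen without replacement, are given a
#' uniformly random *different* residue type.  Coordinates are untouched
#' except that `cb`/`cn` are rebuilt when a mutation crosses the
#' glycine/alanine degeneracy rules (to glycine: `cb = cn = ca`; to
#' alanine: `cn = cb`; away from glycine: a new C-beta is placed 1.53
#' Angstrom from C-alpha in a random direction, with the centroid beyond
#' it).  C-alpha coordinates never change.
#'
#' @param pocket a `Pocket`.
#' @param fraction fraction of residues to mutate, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return the mutated `Pocket` (id suffixed with `"_mut"`).
#' @export
perturb_types <- function(pocket, fraction, seed) {
  stopifnot(is_pocket(pocket), fraction >= 0, fraction <= 1)
  n <- pocket_size(pocket)
  k <- round(fraction * n)
  with_seed(seed, {
    if (k > 0) {
      idx <- sort(sample.int(n, k))
      for (i in idx) {
        old <- pocket$residues$aa[i]
        new <- sample(setdiff(AA20, old), 1)
        if (old == "G" && new != "G") {   # regrow a side chain stub
          pocket$cb[i, ] <- pocket$ca[i, ] + 1.53 * as.numeric(random_unit3())
          pocket$cn[i, ] <- if (new == "A") pocket$cb[i, ] else
            pocket$cb[i, ] +
            runif(1, 0.5, 2.5) * unit3(pocket$cb[i, ] - pocket$ca[i, ])
        } else if (new == "G") {
          pocket$cb[i, ] <- pocket$ca[i, ]
          pocket$cn[i, ] <- pocket$ca[i, ]
        } else if (new == "A") {
          pocket$cn[i, ] <- pocket$cb[i, ]
        } else if (old == "A") {          # grow a centroid beyond C-beta
          pocket$cn[i, ] <- pocket$cb[i, ] +
            runif(1, 0.5, 2.5) * unit3(pocket$cb[i, ] - pocket$ca[i, ])
        }
        pocket$residues$aa[i] <- new
      }
    }
    pocket$pocket_id <- paste0(pocket$pocket_id, "_mut")
    pocket
  })
}

#' Run a perturbation sensitivity analysis
#'
#' For each magnitude and replicate, perturbs `base` (positionally or by
#' residue type), aligns the perturbed copy back onto `base` with
#' [align_pair()] and records the three scores.  This reproduces the
#' score-degradation experiments used to characterise the aligner: the
#' matched-residue scores decay with positional noise but are invariant to
#' pure residue-type exchange, while M-seq tracks mutation load.
#'
#' @param base a `Pocket`.
#' @param mode `"position"` (magnitudes are target C-alpha RMSDs in
#'   Angstrom, range 0--14) or `"type"` (magnitudes are mutation fractions
#'   in `[0, 1]`).
#' @param magnitudes numeric vector of perturbation magnitudes.
#' @param replicates replicates per magnitude.
#' @param seed integer seed controlling all replicate perturbations.
#' @param ... passed to [align_pair()].
#' @return data.frame with columns `mode`, `magnitude`, `replicate`,
#'   `n_matched`, `m_dist_min`, `m_dist_max`, `m_seq`, `realized_rmsd`
#'   (positional C-alpha RMSD actually applied), sorted by magnitude then
#'   replicate.
#' @export
run_sensitivity <- function(base, mode = c("position", "type"),
                            magnitudes, replicates = 100, seed = 1, ...) {
  mode <- match.arg(mode)
  stopifnot(is_pocket(base), replicates >= 1)
  if (mode == "position" && any(magnitudes < 0 | magnitudes > 14))
    pm_data_error("position magnitudes must be within 0..14 Angstrom")
  if (mode == "type" && any(magnitudes < 0 | magnitudes > 1))
    pm_data_error("type magnitudes are fractions in [0, 1]")
  subseeds <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max, length(magnitudes) * replicates),
    nrow = length(magnitudes)))
  rows <- vector("list", length(magnitudes) * replicates)
  q <- 0L
  for (m in seq_along(magnitudes)) {
    for (r in seq_len(replicates)) {
      pert <- if (mode == "position")
        perturb_positions(base, magnitudes[m], subseeds[m, r])
      else perturb_types(base, magnitudes[m], subseeds[m, r])
      realized <- sqrt(mean(rowSums((pert$ca - base$ca)^2)))
      aln <- align_pair(base, pert, ...)
      q <- q + 1L
      rows[[q]] <- data.frame(
        mode = mode, magnitude = magnitudes[m], replicate = r,
        n_matched = aln$n_matched, m_dist_min = aln$m_dist_min,
        m_dist_max = aln$m_dist_max, m_seq = aln$m_seq,
        realized_rmsd = realized, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$magnitude, out$replicate), , drop = FALSE]
}

#' Generate a synthetic pocket universe with planted conserved cores
#'
#' Builds `n_clusters` families of pockets.  Each family shares a planted
#' conserved core: `core_size` residues with a family-specific random type
#' sequence and a fixed geometry, reproduced in every member up to a small
#' rigid per-residue jitter.  The remaining residues of every member get
#' fresh random positions and types, so they align between members only by
#' chance.  Families differ in pocket size and spatial extent (as real
#' site types do), which keeps chance cross-family similarity safely below
#' clustering thresholds: the matched fraction of the larger pocket cannot
#' reach threshold when sizes are disparate.  This is the ground-truth
#' test bed for clustering, consensus profiling and motif recovery: the
#' derivable motif of each family is exactly its core.
#'
#' @param seed integer RNG seed.
#' @param n_clusters number of families (default 3).
#' @param members_per_cluster pockets per family (default 6).
#' @param n_residues residues per pocket, recycled per family
#'   (default `c(8, 18, 30)`).
#' @param core_size conserved residues per family, recycled
#'   (default `c(5, 11, 18)`).
#' @param diameter pocket sphere diameter in Angstrom, recycled
#'   (default `c(16, 24, 32)`).
#' @param jitter_sd per-residue rigid jitter SD in Angstrom (default 0.25).
#' @return list with `pockets` (named list of `Pocket`), `truth`
#'   (data.frame `pocket_id`, `cluster`) and `cores` (per-family list with
#'   `aa` types and core C-alpha geometry of the family base).
#' @export
generate_pocket_universe <- function(seed, n_clusters = 3,
                                     members_per_cluster = 6,
                                     n_residues = c(8, 18, 30),
                                     core_size = c(5, 11, 18),
                                     diameter = c(16, 24, 32),
                                     jitter_sd = 0.25) {
  n_residues <- rep_len(n_residues, n_clusters)
  core_size <- rep_len(core_size, n_clusters)
  diameter <- rep_len(diameter, n_clusters)
  stopifnot(all(core_size >= 3), all(n_residues > core_size),
            members_per_cluster >= 3)
  with_seed(seed, {
    place <- function(existing, count, radius) {
      pts <- matrix(NA_real_, count, 3)
      got <- 0L; tries <- 0L
      while (got < count) {
        if ((tries <- tries + 1L) > 4000L * count)
          pm_data_error("universe placement failed; increase diameter")
        p <- as.numeric(random_unit3()) * radius * runif(1)^(1 / 3)
        all_pts <- rbind(existing, pts[seq_len(got), , drop = FALSE])
        if (nrow(all_pts) > 0 &&
            min(rowSums(sweep(all_pts, 2, p)^2)) < 3.5^2) next
        got <- got + 1L
        pts[got, ] <- p
      }
      pts
    }
    pockets <- list()
    truth <- list()
    cores <- list()
    for (cl in seq_len(n_clusters)) {
      ncl <- n_residues[cl]; kcl <- core_size[cl]
      radius <- diameter[cl] / 2
      core_aa <- sample(AA20, kcl, replace = TRUE)
      core_ca <- place(NULL, kcl, radius)
      core_cb <- core_ca + 1.53 * random_unit3(kcl)
      dir <- core_cb - core_ca + 0.5 * random_unit3(kcl)
      dir <- dir / sqrt(rowSums(dir^2))
      core_cn <- core_cb + runif(kcl, 0.5, 2.5) * dir
      gly <- core_aa == "G"
      core_cb[gly, ] <- core_ca[gly, ]; core_cn[gly, ] <- core_ca[gly, ]
      ala <- core_aa == "A"
      core_cn[ala, ] <- core_cb[ala, ]
      cores[[cl]] <- list(aa = core_aa, ca = core_ca)
      n_var <- ncl - kcl
      for (m in seq_len(members_per_cluster)) {
        jit <- matrix(rnorm(kcl * 3, sd = jitter_sd), kcl, 3)
        ca <- rbind(core_ca + jit, place(core_ca + jit, n_var, radius))
        var_aa <- sample(AA20, n_var, replace = TRUE)
        var_ca <- ca[kcl + seq_len(n_var), , drop = FALSE]
        var_cb <- var_ca + 1.53 * random_unit3(n_var)
        vdir <- var_cb - var_ca + 0.5 * random_unit3(n_var)
        vdir <- vdir / sqrt(rowSums(vdir^2))
        var_cn <- var_cb + runif(n_var, 0.5, 2.5) * vdir
        vg <- var_aa == "G"
        var_cb[vg, ] <- var_ca[vg, , drop = FALSE]
        var_cn[vg, ] <- var_ca[vg, , drop = FALSE]
        va <- var_aa == "A"
        var_cn[va, ] <- var_cb[va, , drop = FALSE]
        cb <- rbind(core_cb + jit, var_cb)
        cn <- rbind(core_cn + jit, var_cn)
        id <- sprintf("c%d_m%d", cl, m)
        pockets[[id]] <- new_pocket(
          id,
          data.frame(chain = "A", resseq = seq_len(ncl), icode = "",
                     aa = c(core_aa, var_aa), stringsAsFactors = FALSE),
          ca, cb, cn,
          source = sprintf("synthetic universe seed=%d cluster=%d", seed, cl))
        truth[[id]] <- data.frame(pocket_id = id, cluster = cl,
                                  stringsAsFactors = FALSE)
      }
    }
    list(pockets = pockets, truth = do.call(rbind, truth), cores = cores)
  })
}
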