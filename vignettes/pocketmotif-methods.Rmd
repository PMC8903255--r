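---
title: "Methods: sequence-order-independent binding-site alignment and 3D motif derivation"
author: "pocketmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site alignment and motif derivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketmotif)
```

## The problem

Proteins that bind the same small molecule often do so with binding sites
that agree in three-dimensional residue arrangement while disagreeing in
sequence, in fold, and even in the order in which the site residues occur
along the chain.  Sequence alignment is therefore blind to much of the
similarity between ligand-binding sites.  `pocketmotif` compares binding
sites purely as labelled 3D point sets, independent of residue order,
places whole families of sites into one common frame, and condenses each
family into a PROSITE-style *structural motif*: a short pattern of allowed
residue sets with variable sequence gaps, each element anchored at a 3D
position.

## Site representation

A *pocket* is the set of protein residues with at least one non-hydrogen
atom within 4.5 &Aring; of any non-hydrogen atom of a bound ligand (the
cutoff is exposed; 4.5 &Aring; is the default shell).  Each residue is
reduced to three labelled points:

* `ca` — the C-alpha position,
* `cb` — the C-beta position,
* `cn` — the unweighted centroid of the side-chain heavy atoms
  (C-beta included).

Glycine has no side chain: `cb` and `cn` both equal `ca`.  For alanine the
C-beta is the whole side chain, so `cn = cb`.  A missing C-beta on any
other residue is rebuilt from the backbone N, CA and C atoms at ideal
tetrahedral geometry, and a side chain truncated beyond C-beta is treated
like alanine.  These conventions make pockets from imperfect crystal
structures comparable without discarding residues.

Per pocket, an `N × N × 3` distance matrix holds the `ca–ca`, `cb–cb` and
`cn–cn` distances of every residue pair.  An ordered residue pair together
with its three distances is a *dyad*; a 20-residue site has
`20 × 19 = 380` dyads, while triads (6840) and tetrads (116280) grow too
fast to be practical seeds, which is why seeding operates on dyads.

## Pairwise alignment

**Correspondence graph.** A candidate pairing `(i, j)` maps residue `i` of
pocket 1 onto residue `j` of pocket 2.  Two pairings `(i, j)` and
`(k, l)` are *compatible* when the dyad distance triplets agree: the RMSD
between `(d_ca, d_cb, d_cn)` of `(i, k)` in pocket 1 and of `(j, l)` in
pocket 2 is below the tolerance (1.0 &Aring; by default).  A clique in
this graph is a mutually consistent partial alignment.

**Seed search.** Seeds are grown from every compatible starting dyad by a
backtracking depth-first search: candidates compatible with the whole
current clique are tried best-first (smallest worst-case dyad RMSD); a
candidate explored at a level joins that level's visited set and is not
retried, so each maximal clique containing the start edge is enumerated
once.  Two caps bound the work — `max_starts` (default 1000) starting
dyads, smallest-RMSD first, and a per-start expansion `budget` (default
100), beyond which growth degrades to pure greedy completion.  On small
instances (a few dozen graph nodes) the caps are never reached and the
search is exhaustive; the unit tests pin the top seed length to an
independent brute-force maximum-clique enumeration.  The search stops
early once a seed reaches the size of the smaller pocket, which no other
seed can beat.  Seeds are ranked by length, then raw BLOSUM-62 sum of the
mapped pairs, then lexicographic pair order, so the ranking is fully
deterministic.

**Superposition and extension.** Each of the top `max_seeds` (default 10)
seeds is superposed with the Kabsch algorithm using *all three points* of
every seed pair — the side-chain points stabilise small seeds, whose
C-alpha sets alone can be nearly degenerate.  The correspondence is then
extended by greedy mutual-nearest-neighbour matching of unmatched
residues whose post-superposition C-alpha distance is below the extension
cutoff (2.0 &Aring; default), alternating extension and re-superposition
until the correspondence stops growing.  Extension requires at least
three existing pairs: a frame fitted to two residues leaves its third
rotational degree of freedom pinned only by the short side-chain lever
arms, and extending from such a frame mostly harvests noise.  The final
candidate is chosen by match count, then scaled-BLOSUM sum, then
lexicographic order.

**Scores.** With `M` matched residues between pockets of `N1` and `N2`
residues:

* `M-dist_min = M / min(N1, N2)` — local similarity (is the smaller site
  contained in the larger?),
* `M-dist_max = M / max(N1, N2)` — global similarity,
* `M-seq` — the mean scaled BLOSUM-62 score over matched pairs, where
  `s(a, b) = max(0, B62(a, b)) / min(B62(a, a), B62(b, b))` clamps to
  `[0, 1]` and every standard residue scores 1 against itself.

All three scores are 1 for identical pockets and 0 when no compatible
dyad exists.  Scores are symmetric in the argument order by construction:
the computation runs in a canonical direction (a deterministic key over
size, id and coordinates) and the mapping is mirrored back.

## Multiple alignment and motifs

For a pocket collection, every ordered pair including self-pairs is
scored (`N^2` records; each unordered pair computed once and mirrored).
Pockets become nodes of a similarity network with an edge wherever
`M-dist_max ≥ 0.4`, the threshold at which known site similarities are
captured.  Clusters are found by an MCODE-style procedure: vertices are
weighted by the highest k-core of their closed neighbourhood times that
core's density, complexes grow from the heaviest unseen vertex through
neighbours within 80% of the seed weight, and a haircut removes members
with fewer than two in-complex connections.  The member with the highest
weighted degree represents the cluster; every member is star-aligned onto
it, and each representative residue becomes a column of a consensus
profile holding occupancy, residue counts, mean C-alpha position in the
representative frame, and each member's mapped sequence position.

A motif is read off the profile: columns with occupancy ≥ 0.7 become
elements; residues reaching 10% frequency among the column's occupants
form the allowed set; observed sequence separations between consecutive
elements become variable gaps `x(min,max)`; separations beyond 30
residues split the motif into sequentially discontinuous parts (spatially
one site).  The occupancy and frequency thresholds and the split distance
are package choices — the derivation of how conserved a column must be to
enter a motif is genuinely open — and all three are exposed as arguments
and CLI flags.  Motif scanning searches a target pocket for an injective,
sequence-ordered assignment of residues to elements that satisfies the
residue sets, the gap windows, and (in structural mode) a Kabsch RMSD of
the assigned C-alphas onto the element anchors within 1.5 &Aring;.

## Synthetic data: what it does and does not emulate

The generator samples pocket-like point clouds: uniformly random residue
types, C-alpha positions in a sphere (default diameter 20 &Aring;) with a
3.5 &Aring; minimum separation, C-beta 1.53 &Aring; from C-alpha, and the
centroid 0.5–2.5 &Aring; beyond C-beta.  That reproduces the length
scales the aligner cares about — inter-residue spacing, side-chain lever
arms — and nothing else: real sites are shells around a ligand with
backbone connectivity and correlated side-chain packing, not uniform
balls.  One consequence is worth stating plainly: *compact random point
clouds are more self-similar than real unrelated sites*, so chance scores
between unrelated synthetic pockets overstate what unrelated real sites
would score.  Passing tests on synthetic data therefore demonstrate the
geometry-level behaviour of the algorithms (score definitions,
robustness, determinism, recovery of planted structure), not
field-realistic specificity margins.

**Position perturbation** displaces `n_move` residues rigidly (all three
points together) in independent random directions and rescales so the
realized C-alpha RMSD equals the target exactly (to 1e-6).  The subset
size grows with the target as `n_move = max(1, round(n (t/14)^2))`, 14
&Aring; being the top of the studied 0–14 &Aring; range: small
perturbations move one or a few residues strongly, the largest move the
whole site.  This shape makes the characteristic robustness claim hold
exactly — below 1.5 &Aring; RMSD a 20-residue pocket keeps 19 of 20
residues untouched, so `M-dist_min` stays at 0.95 — while still degrading
smoothly to chance level at 14 &Aring;.  **Type perturbation** mutates a
chosen fraction of residues to uniformly random different types without
touching any C-alpha; `cb`/`cn` are rebuilt only where a mutation crosses
the glycine/alanine degeneracy rules.  Geometry-blind mutation leaves
`M-dist_max` at exactly 1 while `M-seq` decays — the separation of
geometric from sequence similarity that motivates having three scores.

**The planted universe** builds families sharing an exact conserved core
(reproduced up to 0.25 &Aring; rigid jitter) padded with per-member
random residues.  Families differ in size and spatial extent
(8/18/30 residues in 16/24/32 &Aring; spheres by default), as real site
types do; because `M-dist_max` divides by the larger pocket, disparate
sizes structurally cap chance cross-family scores below the 0.4 edge
threshold, giving a clean ground truth for clustering and motif
recovery.

## Numerical choices and edge cases

* Kabsch superposition corrects the reflection branch (`det(R) = +1`
  always) and refuses fewer than 3 point pairs or collinear
  configurations; alignment candidates whose seed geometry is degenerate
  (e.g. a two-glycine dyad, six coincident points) are skipped.
* Distance-compatibility is strict (`RMSD < tol`), so a triplet at
  exactly the tolerance is incompatible.
* All tie-breaks — seed ranking, candidate selection, representative
  choice, cluster seeding — are lexicographic, and no alignment step uses
  randomness, so every result is bit-reproducible and independent of the
  worker count.
* Nonstandard residues map to their parent amino acid through a fixed
  table (e.g. MSE to M); anything unknown becomes `X`, which scores 0 in
  every substitution lookup.
* Altloc handling keeps the highest-occupancy conformer (ties: first in
  file); only model 1 of multi-model files is read; hydrogens are parsed
  but excluded from distance tests.  Waters never count as pocket
  residues.
* Problem sizes in the test suite: sensitivity analyses run 20-residue
  pockets with around 100 replicates per condition, the oracle comparison
  200 pocket pairs of 3–8 residues, and the pipeline check three families
  of six pockets; these sizes exercise every code path while keeping the
  default suite fast.

## Known limitations

* The extension step matches on post-superposition C-alpha distance
  alone.  On unrelated compact point clouds it occasionally adds a chance
  pair beyond the maximum dyad-compatible clique, so the final match
  count can slightly exceed the clique optimum for random inputs; the
  seed search itself is clique-exact.  A compatibility-filtered extension
  was considered and rejected because it would break the invariance of
  the geometric score under pure residue-type mutation (rebuilt side
  chains shift the `cb`/`cn` channels).
* Scanning requires all motif elements on one chain in increasing
  sequence order; a motif whose instances straddle chains is split into
  parts instead.
* mmCIF input is not supported; pocket prediction is out of scope —
  predicted sites are accepted as input pockets.
* MCODE parameters follow the published defaults (node score cutoff 0.2,
  haircut on, no fluff); the clustering names the procedure it
  implements, not the original program.
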