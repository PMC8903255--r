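# All-vs-all comparison, similarity network, MCODE-style clustering,
# representative selection and consensus profiles.

test_that("all_vs_all enumerates ordered pairs including self", {
  pockets <- lapply(1:4, function(k) generate_synthetic_pocket(6, seed = k))
  sc <- all_vs_all(pockets)
  expect_equal(nrow(sc), 16)
  self <- sc[sc$id_a == sc$id_b, ]
  expect_equal(nrow(self), 4)
  expect_true(all(self$m_dist_min == 1 & self$m_dist_max == 1 &
                    self$m_seq == 1))
  # mirrored records carry identical scores
  for (q in which(sc$id_a < sc$id_b)) {
    mirror <- sc[sc$id_a == sc$id_b[q] & sc$id_b == sc$id_a[q], ]
    expect_equal(mirror$m_dist_max, sc$m_dist_max[q])
    expect_equal(mirror$n_matched, sc$n_matched[q])
  }
})

test_that("a single pocket yields one perfect self record", {
  p <- generate_synthetic_pocket(7, seed = 99)
  sc <- all_vs_all(list(p))
  expect_equal(nrow(sc), 1)
  expect_equal(sc$m_dist_min, 1)
  expect_equal(sc$m_seq, 1)
})

test_that("stubbed comparisons reproduce the N^2 record convention", {
  mocks <- lapply(1:26, function(k) list(pocket_id = sprintf("mock%03d", k)))
  stub <- function(a, b) list(n_matched = 0L, rmsd = 0, m_dist_min = 0,
                              m_dist_max = 0, m_seq = 0)
  sc <- all_vs_all(mocks, compare_fun = stub)
  expect_equal(nrow(sc), 676)
})

test_that("all_vs_all output is invariant to the worker count", {
  pockets <- lapply(1:6, function(k) generate_synthetic_pocket(6, seed = k))
  s1 <- all_vs_all(pockets, workers = 1)
  s2 <- all_vs_all(pockets, workers = 2)
  expect_identical(s1[order(s1$id_a, s1$id_b), ],
                   s2[order(s2$id_a, s2$id_b), ])
})

test_that("a failing pair is flagged, not fatal", {
  pockets <- lapply(1:3, function(k) generate_synthetic_pocket(5, seed = k))
  poison <- pockets[[2]]$pocket_id
  cf <- function(a, b) {
    if (a$pocket_id == poison || b$pocket_id == poison)
      stop("bad pocket")
    list(n_matched = 1L, rmsd = 0, m_dist_min = 0.5, m_dist_max = 0.5,
         m_seq = 0.5)
  }
  sc <- all_vs_all(pockets, compare_fun = cf)
  bad <- !is.na(sc$error)
  expect_equal(sum(bad), 5)                     # every pair touching pocket 2
  expect_true(all(grepl("bad pocket", sc$error[bad])))
  expect_true(all(sc$m_dist_min[!bad] == 0.5))
})

test_that("network edges respect the 0.4 threshold exactly", {
  p <- generate_synthetic_pocket(6, seed = 50)
  copies <- lapply(1:3, function(k) { q <- p; q$pocket_id <- paste0("id", k); q })
  sc <- all_vs_all(copies)
  net <- build_network(sc)
  expect_equal(nrow(net$edges), 3)              # triangle
  expect_true(all(net$edges$weight == 1))

  tab <- data.frame(
    id_a = c("a", "a", "b", "b", "a", "b"),
    id_b = c("a", "b", "a", "b", "b", "a"),
    m_dist_max = c(1, 0.39, 0.39, 1, 0.39, 0.39),
    error = NA_character_, stringsAsFactors = FALSE)
  net <- build_network(tab[1:4, ])
  expect_equal(nrow(net$edges), 0)              # 0.39 misses the threshold
  tab$m_dist_max[2] <- 0.40
  tab$m_dist_max[3] <- 0.40
  net <- build_network(tab[1:4, ])
  expect_equal(nrow(net$edges), 1)              # >= is inclusive
})

test_that("asymmetric score tables are rejected", {
  tab <- data.frame(id_a = c("a", "b"), id_b = c("b", "a"),
                    m_dist_max = c(0.9, 0.5), error = NA_character_,
                    stringsAsFactors = FALSE)
  expect_error(build_network(tab), "asymmetric")
})

test_that("a clique clusters whole and disjoint cliques stay apart", {
  clique_edges <- function(ids, w = 1) {
    cmb <- t(combn(ids, 2))
    data.frame(id_a = cmb[, 1], id_b = cmb[, 2], weight = w,
               stringsAsFactors = FALSE)
  }
  net <- manual_network(clique_edges(c("p1", "p2", "p3", "p4")))
  cls <- cluster_network(net)
  expect_length(cls, 1)
  expect_setequal(cls[[1]]$members, c("p1", "p2", "p3", "p4"))

  net2 <- manual_network(rbind(clique_edges(c("a1", "a2", "a3", "a4")),
                               clique_edges(c("b1", "b2", "b3", "b4"))))
  cls2 <- cluster_network(net2)
  expect_length(cls2, 2)
  expect_setequal(cls2[[1]]$members, c("a1", "a2", "a3", "a4"))
  expect_setequal(cls2[[2]]$members, c("b1", "b2", "b3", "b4"))
})

test_that("a five-vertex path clusters exactly as the stated rule dictates", {
  # Hand simulation of the procedure on the path a-b-c-d-e:
  #  weights: endpoints see a single-edge neighbourhood (k=1, density 1,
  #  w=1); b, c, d see a 3-vertex path (k=1, density 2/3, w=2/3).
  #  Seeds in order a, e: no neighbour reaches 0.8*1 -> trivial, reverted.
  #  Seed b: a (w=1), c, then d, then e all reach 0.8*(2/3) -> complex
  #  {a,b,c,d,e}; haircut removes the degree-1 endpoints a and e.
  #  Result: one complex {b,c,d}; a and e fall out as singletons.
  net <- manual_network(data.frame(
    id_a = c("a", "b", "c", "d"), id_b = c("b", "c", "d", "e"),
    weight = 1, stringsAsFactors = FALSE))
  cls <- cluster_network(net)
  members <- lapply(cls, `[[`, "members")
  expect_length(cls, 3)
  expect_true(any(vapply(members, function(m)
    setequal(m, c("b", "c", "d")), TRUE)))
  singletons <- members[vapply(members, length, 0L) == 1]
  expect_setequal(unlist(singletons), c("a", "e"))
})

test_that("clusters never span network components", {
  set.seed(8)
  pockets <- c(lapply(1:3, function(k) {
    q <- generate_synthetic_pocket(8, seed = 300)
    q <- perturb_positions(q, 0.3, seed = k)
    q$pocket_id <- paste0("x", k); q
  }), lapply(1:3, function(k) {
    q <- generate_synthetic_pocket(24, seed = 400, diameter = 30)
    q <- perturb_positions(q, 0.3, seed = k)
    q$pocket_id <- paste0("y", k); q
  }))
  sc <- all_vs_all(pockets)
  net <- build_network(sc)
  cls <- cluster_network(net)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$nodes)
  comp <- igraph::components(g)$membership
  for (cl in cls)
    expect_equal(length(unique(comp[cl$members])), 1L)
})

test_that("representative selection maximises weighted degree", {
  star <- manual_network(data.frame(
    id_a = c("hub", "hub", "hub"), id_b = c("l1", "l2", "l3"),
    weight = 1, stringsAsFactors = FALSE))
  expect_equal(select_representative(
    list(members = c("hub", "l1", "l2", "l3")), star), "hub")

  clique <- manual_network(data.frame(
    id_a = c("a", "a", "b"), id_b = c("b", "c", "c"), weight = 0.5,
    stringsAsFactors = FALSE))
  expect_equal(select_representative(
    list(members = c("a", "b", "c")), clique), "a")   # tie -> smallest id

  wnet <- manual_network(data.frame(
    id_a = c("A", "A", "B", "B"), id_b = c("u", "v", "u", "v"),
    weight = c(0.9, 0.5, 0.8, 0.7), stringsAsFactors = FALSE))
  expect_equal(select_representative(
    list(members = c("A", "B")), wnet), "B")          # 1.5 beats 1.4
})

test_that("consensus profiles track occupancy and residue frequencies", {
  p <- generate_synthetic_pocket(8, seed = 70)
  members <- lapply(1:5, function(k) {
    q <- p; q$pocket_id <- paste0("m", k); q
  })
  names(members) <- paste0("m", 1:5)
  cl <- list(members = paste0("m", 1:5), representative = "m1")
  prof <- build_profile(cl, members)
  expect_equal(nrow(prof$columns), 8)
  expect_true(all(prof$occupancy == 1))
  expect_true(all(rowSums(prof$counts) == 5))
  for (q in 1:8)
    expect_equal(unname(prof$counts[q, p$residues$aa[q]]), 5L)

  # one member mutated at residue 3 (geometry untouched): 4:1 split
  old <- members$m5$residues$aa[3]
  new <- setdiff(c("W", "Y"), old)[1]
  members$m5$residues$aa[3] <- new
  if (new == "G") stop("test construction error")
  prof <- build_profile(cl, members)
  expect_equal(unname(prof$counts[3, old]), 4L)
  expect_equal(unname(prof$counts[3, new]), 1L)
  expect_equal(sum(prof$counts[3, ]), 5L)
})

test_that("a planted conserved triad dominates column occupancy", {
  u <- generate_pocket_universe(seed = 23, n_clusters = 1,
                                members_per_cluster = 5,
                                n_residues = 8, core_size = 3,
                                diameter = 30)
  # the family is known by construction; profile it directly
  cl <- list(members = u$truth$pocket_id,
             representative = u$truth$pocket_id[1])
  prof <- build_profile(cl, u$pockets)
  core_cols <- which(prof$columns$resseq <= 3)
  expect_equal(length(core_cols), 3)
  expect_true(min(prof$occupancy[core_cols]) >
                max(prof$occupancy[-core_cols]))
})

test_that("profiles require at least three members", {
  p <- generate_synthetic_pocket(5, seed = 80)
  q <- p; q$pocket_id <- "other"
  expect_error(build_profile(list(members = c(p$pocket_id, "other"),
                                  representative = p$pocket_id),
                             setNames(list(p, q), c(p$pocket_id, "other"))),
               "at least 3")
})
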