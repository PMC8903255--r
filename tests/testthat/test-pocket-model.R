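# Structure parsing, binding-site extraction and the three-point residue
# representation.

test_that("load_structure keeps model 1 and the highest-occupancy altloc", {
  lines <- c(
    "MODEL        1",
    residue_lines(1, "ALA", "A", 1, c(0, 0, 0)),
    # altloc pair: B has the higher occupancy and must win despite order
    pdb_line(10, "CA", "SER", "A", 2, 8.0, 0, 0, occ = 0.4, alt = "A"),
    pdb_line(11, "CA", "SER", "A", 2, 8.5, 0, 0, occ = 0.6, alt = "B"),
    pdb_line(12, "CB", "SER", "A", 2, 8.5, 1.0, 1.0),
    pdb_line(13, "OG", "SER", "A", 2, 8.5, 1.0, 3.0),
    residue_lines(20, "GLY", "A", 3, c(16, 0, 0)),
    "ENDMDL",
    "MODEL        2",
    pdb_line(30, "CA", "ALA", "A", 9, 99.0, 99.0, 99.0),
    "ENDMDL")
  path <- write_structure_fixture(lines)
  s <- load_structure(path)
  expect_equal(sort(unique(s$atoms$resno)), c(1, 2, 3))   # model 2 dropped
  ser_ca <- s$atoms[s$atoms$resno == 2 & s$atoms$elety == "CA", ]
  expect_equal(nrow(ser_ca), 1L)
  expect_equal(ser_ca$x, 8.5)                              # altloc B kept
  expect_equal(ser_ca$occ, 0.6)
})

test_that("load_structure rejects unreadable or empty input", {
  expect_error(load_structure(tempfile()), "not found")
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("this is not", "a pdb file"), bad)
  expect_error(load_structure(bad), "no ATOM/HETATM")
})

test_that("binding-site extraction applies the 4.5 A shell exactly", {
  # ligand atom at the origin; residue nearest atoms at controlled radii
  lines <- c(
    pdb_line(1, "C1", "LIG", "L", 900, 0, 0, 0, type = "HETATM",
             element = "C"),
    residue_lines(10, "LEU", "A", 1, c(4.4 + 1.2, 0, 0)),  # N at 4.4 -> in
    residue_lines(20, "LYS", "A", 2, c(4.6 + 1.2, 0, 0)),  # N at 4.6 -> out
    residue_lines(30, "PHE", "A", 3, c(0, 5.7, 0)),        # N at 5.84, CA 5.7? no:
    residue_lines(40, "SER", "A", 4, c(0, 0, 4.0)),        # CA at 4.0 -> in
    residue_lines(50, "ASP", "A", 5, c(3.0, 3.0, 0)),      # CA 4.24 -> in
    # water within range must never become a pocket residue
    pdb_line(60, "O", "HOH", "W", 901, 1.0, 1.0, 1.0, type = "HETATM",
             element = "O"))
  path <- write_structure_fixture(lines)
  s <- load_structure(path)

  pocket <- extract_binding_site(s, list("LIG", "L", 900), cutoff = 4.5)
  # brute-force oracle: rescan all residue atoms against the ligand atom
  at <- s$atoms
  d <- sqrt(at$x^2 + at$y^2 + at$z^2)
  in_range <- unique(at$resno[at$type == "ATOM" & d <= 4.5])
  expect_setequal(pocket$residues$resseq, in_range)
  expect_true(1 %in% pocket$residues$resseq)    # nearest atom at 4.4
  expect_false(2 %in% pocket$residues$resseq)   # nearest atom beyond
  expect_equal(pocket$ligand_id, "LIG")

  # monotone in cutoff
  bigger <- extract_binding_site(s, list("LIG", "L", 900), cutoff = 5.0)
  expect_true(all(pocket$residues$resseq %in% bigger$residues$resseq))

  expect_error(extract_binding_site(s, list("XYZ", "L", 900)),
               "available het groups")
})

test_that("extraction of an empty shell errors out", {
  lines <- c(
    pdb_line(1, "C1", "LIG", "L", 900, 500, 500, 500, type = "HETATM",
             element = "C"),
    residue_lines(10, "LEU", "A", 1, c(0, 0, 0)),
    residue_lines(20, "LYS", "A", 2, c(8, 0, 0)),
    residue_lines(30, "PHE", "A", 3, c(0, 8, 0)))
  s <- load_structure(write_structure_fixture(lines))
  expect_error(extract_binding_site(s, list("LIG", "L", 900)),
               "empty site")
})

test_that("three-point representation follows the glycine/alanine rules", {
  gly <- data.frame(chain = "A", resno = 1L, insert = "", resid = "GLY",
                    elety = c("N", "CA", "C", "O"),
                    x = c(0, 1, 2, 2), y = c(0, 2, 3, 4), z = c(0, 3, 0, 0),
                    is_h = FALSE, stringsAsFactors = FALSE)
  rp <- three_point_representation(gly)
  expect_equal(rp$cb, c(1, 2, 3))
  expect_equal(rp$cn, c(1, 2, 3))
  expect_equal(rp$aa, "G")

  ala <- data.frame(chain = "A", resno = 2L, insert = "", resid = "ALA",
                    elety = c("N", "CA", "C", "CB"),
                    x = c(-1, 0, 1, 0), y = c(0, 0, 0.5, 0),
                    z = c(0, 0, 0, 1), is_h = FALSE,
                    stringsAsFactors = FALSE)
  rp <- three_point_representation(ala)
  expect_equal(rp$cn, c(0, 0, 1))   # centroid is the C-beta itself

  ser <- data.frame(chain = "A", resno = 3L, insert = "", resid = "SER",
                    elety = c("N", "CA", "C", "CB", "OG"),
                    x = c(-1, 0, 1, 0, 0), y = c(0, 0, 0.5, 0, 0),
                    z = c(0, 0, 0, 0, 2), is_h = FALSE,
                    stringsAsFactors = FALSE)
  rp <- three_point_representation(ser)
  expect_equal(rp$cn, c(0, 0, 1))   # centroid of CB=(0,0,0), OG=(0,0,2)
})

test_that("a missing C-beta is rebuilt at sensible geometry", {
  leu <- data.frame(chain = "A", resno = 4L, insert = "", resid = "LEU",
                    elety = c("N", "CA", "C"),
                    x = c(1.458, 0, -0.55), y = c(0, 0, 1.42),
                    z = c(0, 0, 0), is_h = FALSE, stringsAsFactors = FALSE)
  rp <- three_point_representation(leu)
  d <- sqrt(sum((rp$ca - rp$cb)^2))
  expect_gt(d, 1.3)
  expect_lt(d, 2.0)
})

test_that("a residue without C-alpha is skipped with a warning", {
  noca <- data.frame(chain = "A", resno = 5L, insert = "", resid = "LEU",
                     elety = c("N", "C"), x = c(0, 1), y = c(0, 0),
                     z = c(0, 0), is_h = FALSE, stringsAsFactors = FALSE)
  expect_message(out <- three_point_representation(noca), "no CA")
  expect_null(out)
})

test_that("the representation is rigid-motion equivariant", {
  ser <- data.frame(chain = "A", resno = 3L, insert = "", resid = "SER",
                    elety = c("N", "CA", "C", "CB", "OG"),
                    x = c(-1, 0, 1, 0, 0), y = c(0, 0, 0.5, 0, 0),
                    z = c(0, 0, 0, 0, 2), is_h = FALSE,
                    stringsAsFactors = FALSE)
  set.seed(31)
  for (rep_ in 1:5) {
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    xyz <- as.matrix(ser[, c("x", "y", "z")])
    moved <- ser
    moved[, c("x", "y", "z")] <- sweep(xyz %*% R, 2, t, `+`)
    a <- three_point_representation(ser)
    b <- three_point_representation(moved)
    for (f in c("ca", "cb", "cn"))
      expect_equal(as.numeric(a[[f]] %*% R + t), b[[f]], tolerance = 1e-9)
  }
})

test_that("pocket construction enforces ordering and minimum size", {
  ca <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(5, 5, 0))
  p <- pocket_from_ca("ord", ca, aa = c("L", "K", "F", "S"),
                      resseq = c(7, 3, 12, 5))
  expect_equal(p$residues$resseq, c(3, 5, 7, 12))
  expect_equal(p$residues$aa, c("K", "S", "L", "F"))  # reordered with resseq
  expect_error(pocket_from_ca("tiny", ca[1:2, , drop = FALSE]),
               "at least 3")
})

test_that("pocket files round-trip through PDB fragments", {
  ca <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(5, 5, 0), c(2, 2, 4))
  # distinct icodes separate the two residues numbered 2
  p <- pocket_from_ca("rt_pocket", ca, aa = c("G", "A", "W", "S", "C"),
                      resseq = c(1, 2, 2, 9, 30),
                      icode = c("", "", "A", "", ""))
  p <- new_pocket(p$pocket_id, p$residues, p$ca, p$cb, p$cn,
                  ligand_id = "GSH")
  path <- tempfile(fileext = ".pdb")
  write_pocket_file(p, path)
  q <- read_pocket_file(path)
  expect_equal(q$pocket_id, "rt_pocket")
  expect_equal(q$ligand_id, "GSH")
  expect_equal(q$residues$aa, p$residues$aa)
  expect_equal(q$residues$resseq, p$residues$resseq)
  expect_equal(q$residues$icode, p$residues$icode)
  expect_equal(q$ca, p$ca, tolerance = 1e-3)
  expect_equal(q$cb, p$cb, tolerance = 1e-3)
  expect_equal(q$cn, p$cn, tolerance = 1e-3)
})

test_that("a two-residue pocket file is rejected", {
  lines <- c("REMARK 900 POCKET too_small",
             pdb_line(1, "CA", "LEU", "A", 1, 0, 0, 0),
             pdb_line(2, "CA", "LYS", "A", 2, 5, 0, 0))
  path <- write_structure_fixture(lines)
  expect_error(read_pocket_file(path), "at least 3")
})
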