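test_that("ss_assignment partitions labels into maximal runs", {
  ss <- ss_assignment("CHHHC")
  expect_equal(ss$labels, c("C", "H", "H", "H", "C"))
  expect_equal(ss$sections,
               data.frame(label = c("C", "H", "C"),
                          start = c(1L, 2L, 5L), end = c(1L, 4L, 5L)))
  # DSSP-style 8-state collapse and case-insensitivity
  expect_equal(ss_assignment("hGIebTSx")$labels,
               c("H", "H", "H", "E", "E", "C", "C", "C"))
  expect_error(ss_assignment(character(0)), "empty")
})

test_that("clean_ss removes singleton SSEs between linkers", {
  expect_equal(clean_ss(ss_assignment("CHC"))$labels, c("C", "C", "C"))
  expect_equal(clean_ss(ss_assignment("CHHC"))$labels, c("C", "H", "H", "C"))
  # chain-terminal singleton counts as one-sided linker
  expect_equal(clean_ss(ss_assignment("H"))$labels, "C")
  expect_equal(clean_ss(ss_assignment("HC"))$labels, c("C", "C"))
  # singleton flanked by a different SSE type is kept
  expect_equal(clean_ss(ss_assignment("CHE"))$labels, c("C", "H", "E"))
})

test_that("clean_ss is idempotent and never adds sections", {
  set.seed(20)
  for (k in 1:25) {
    labels <- sample(c("H", "E", "C"), 30, replace = TRUE)
    ss <- ss_assignment(labels)
    once <- clean_ss(ss)
    expect_identical(clean_ss(once)$labels, once$labels)
    expect_lte(nrow(once$sections), nrow(ss$sections))
  }
})

test_that("read_ss_psipred parses the vertical format", {
  lines <- c("# PSIPRED VFORMAT", "",
             "  1 M C   0.997  0.002  0.001",
             "  2 K h   0.020  0.950  0.030",
             "  3 V H   0.010  0.980  0.010",
             "  4 L H   0.010  0.980  0.010",
             "  5 F C   0.900  0.050  0.050")
  ss <- read_ss_psipred(lines)
  expect_equal(ss$labels, c("C", "H", "H", "H", "C"))
  expect_equal(ss$sections$start, c(1L, 2L, 5L))
  expect_error(read_ss_psipred(c("# header only", "")), "empty")
})

test_that("read_ca_backbone extracts the requested chain", {
  ptsA <- cbind(seq(0, 19) * 3.8, 0, 0)
  ptsB <- cbind(0, seq(0, 9) * 3.8, 50)
  txt <- c(pdb_text(ptsA, chain = "A"), pdb_text(ptsB, chain = "B"), "END")
  cvA <- read_ca_backbone(txt, chain = "A")
  expect_equal(n_points(cvA), 20L)
  expect_equal(curve_points(cvA)[, 1], ptsA[, 1], tolerance = 1e-9)
  cvB <- read_ca_backbone(txt, chain = "B")
  expect_equal(n_points(cvB), 10L)
  expect_error(read_ca_backbone(txt, chain = "Z"), "available chains: A, B")
})

test_that("read_ca_backbone keeps the first altloc and skips non-CA/HETATM", {
  pts <- cbind(seq(0, 5) * 3.8, 0, 0)
  txt <- pdb_text(pts)
  # duplicate residue 3 with altloc B at a different position
  alt <- sub("  1.00", "  0.50", sub("CA  ", "CA B", txt[3]))
  alt <- sub("   7.600", "  99.000", alt)
  txt3 <- sub("CA  ", "CA A", txt[3])
  txt <- c(txt[1:2], txt3, alt, txt[4:6],
           "HETATM    9  CA  HOH A  99      1.000   1.000   1.000  1.00  0.00",
           sub("CA ", "CB ", pdb_text(matrix(c(9, 9, 9), 1), resseq = 50)))
  cv <- read_ca_backbone(txt, chain = "A")
  expect_equal(n_points(cv), 6L)
  expect_equal(curve_points(cv)[3, 1], 7.6, tolerance = 1e-9)
})

test_that("distance jumps are flagged as chain breaks", {
  pts <- cbind(c(0, 3.8, 7.6, 30, 33.8), 0, 0)   # deleted-residue gap
  expect_warning(cv <- read_ca_backbone(pdb_text(pts), chain = "A"),
                 "chain break")
  expect_equal(attr(cv, "breaks"), 3L)
})

test_that("PDB write/read round-trips coordinates at PDB precision", {
  cv <- make_random_walk(15, step = 3.8, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cv, path)
  back <- read_ca_backbone(path, chain = "A")
  expect_equal(curve_points(back), round(curve_points(cv), 3),
               tolerance = 1e-9)
})

test_that("pair_backbone validates lengths and cleans the assignment", {
  mb <- make_mock_backbone(list(c("H", 8), c("C", 3), c("E", 5)), seed = 6)
  bb <- pair_backbone(mb$curve, mb$ss)
  expect_s3_class(bb, "labeled_backbone")
  expect_equal(length(bb$ss$labels), n_points(mb$curve))
  expect_error(pair_backbone(mb$curve, ss_assignment(rep("C", 15))),
               "16 residues but assignment has 15")
  # cleaning applied automatically: CHC singleton vanishes
  cv <- discrete_curve(cbind(0:4 * 3.8, 0, 0))
  bb2 <- pair_backbone(cv, "CCHCC")
  expect_equal(bb2$ss$labels, rep("C", 5))
})
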