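# PDB round-trips, loop identification from secondary structure, and loop
# database construction.

make_mini_pdb <- function(path) {
  ## one alanine with an A/B altloc on CB (occupancies 0.6 / 0.4) and a water
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB AALA A   1       2.000  -0.700   1.200  0.60  0.00           C",
    "ATOM      6  CB BALA A   1       2.000  -0.800  -1.200  0.40  0.00           C",
    "HETATM    7  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

test_that("read_pdb parses a minimal fixture, keeps the top altloc, parks waters", {
  f <- tempfile(fileext = ".pdb")
  make_mini_pdb(f)
  st <- read_pdb(f)
  expect_s3_class(st, "lg_structure")
  expect_equal(nrow(st$atoms), 5L)  # N CA C O CB(A)
  cb <- st$atoms[st$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$z, 1.2)  # the 0.6-occupancy A conformer won
  expect_equal(nrow(st$het), 1L)
  expect_error(read_pdb(tempfile()), "no such file")
})

test_that("write_pdb/read_pdb round-trips coordinates to PDB precision", {
  fx <- make_protein("CCCCCC", seed = 31, clash_ratio = 0)
  f <- tempfile(fileext = ".pdb")
  write_pdb(fx$structure, f, loop = list(chain = "A", start = 2, end = 5))
  expect_match(readLines(f)[1], "REMARK 999 LOOP A 2 5")
  st2 <- read_pdb(f)
  expect_equal(nrow(st2$atoms), nrow(fx$structure$atoms))
  m1 <- as.matrix(fx$structure$atoms[, c("x", "y", "z")])
  ord <- match(paste(fx$structure$atoms$resno, fx$structure$atoms$elety),
               paste(st2$atoms$resno, st2$atoms$elety))
  m2 <- as.matrix(st2$atoms[ord, c("x", "y", "z")])
  expect_lt(max(abs(m1 - m2)), 1e-3 + 1e-9)
  ## write again, read again: now bit-stable at the format precision
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(st2, f2)
  st3 <- read_pdb(f2)
  expect_identical(st2$atoms[, c("x", "y", "z")], st3$atoms[, c("x", "y", "z")])
  ## B-factor column carries provided values
  f3 <- tempfile(fileext = ".pdb")
  write_pdb(st2, f3, bfactor = seq_len(nrow(st2$atoms)) / 10)
  st4 <- read_pdb(f3)
  expect_equal(sort(st4$atoms$b), sort(seq_len(nrow(st2$atoms)) / 10))
  ## coordinate overflow errors out
  bad <- fx$structure
  bad$atoms$x[1] <- 12345.0
  expect_error(write_pdb(bad, tempfile(fileext = ".pdb")), "overflow")
})

test_that("identify_loops merges short elements and filters by completeness", {
  fx <- make_protein("CCCCHHHHHCCC", seed = 32, clash_ratio = 0)
  ## threshold 4: the 5-helix survives, two coil runs remain
  r <- identify_loops(fx$structure, fx$assignment, min_len = 3, max_len = 12,
                      short_element = 4)
  expect_equal(nrow(r), 2L)
  expect_equal(r$start, c(1L, 10L))
  expect_equal(r$length, c(4L, 3L))
  ## threshold 5: the helix is absorbed, one long region
  r2 <- identify_loops(fx$structure, fx$assignment, min_len = 3, max_len = 12,
                       short_element = 5)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$length, 12L)
  ## all-helix chain: nothing
  fh <- make_protein("HHHHHHHH", seed = 33, clash_ratio = 0)
  expect_equal(nrow(identify_loops(fh$structure, fh$assignment)), 0L)
  ## a residue missing CA rejects its region
  broken <- fx$structure
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 2 &
                                   broken$atoms$elety == "CA"), ]
  r3 <- identify_loops(broken, fx$assignment, min_len = 3, max_len = 12,
                       short_element = 4)
  expect_equal(r3$start, 10L)
})

test_that("build_loop_db walks loops correctly on a hand-checkable fixture", {
  fx <- make_protein("HHHHHCCCCCCHHHHH", seed = 34)
  db <- build_loop_db(list(fx$structure), list(fx$assignment))
  expect_equal(length(db$loops), 1L)
  rec <- db$loops[[1]]
  expect_equal(rec$length, 6L)
  ## pair sets exist for g = 1..6 and dihedrals for 6 residues
  expect_setequal(names(db$pairs$c), as.character(1:6))
  expect_setequal(names(db$pairs$ca), as.character(1:6))
  expect_equal(sum(vapply(db$dihedrals, nrow, 0L)), 6L)
  ## distances verified by hand against the anchor (N of residue 12)
  anchor <- as.numeric(fx$structure$atoms[
    fx$structure$atoms$resno == 12 & fx$structure$atoms$elety == "N",
    c("x", "y", "z")])
  ca8 <- as.numeric(fx$structure$atoms[
    fx$structure$atoms$resno == 8 & fx$structure$atoms$elety == "CA",
    c("x", "y", "z")])
  g8 <- rec$pairs_c[rec$pairs_c[, "g"] == 4, ]  # residue 8 has g = 4
  expect_equal(unname(g8["d_prev"]), sqrt(sum((ca8 - anchor)^2)),
               tolerance = 1e-12)
  ## measured dihedrals lie in the canonical range
  expect_true(all(rec$dihedrals$phi >= -180 & rec$dihedrals$phi < 180))
  ## every recorded distance respects the backbone-span bound
  span <- sum(c(backbone_geometry("ALA", "b_CN"),
                rep(c(backbone_geometry("ALA", "b_NCA"),
                      backbone_geometry("ALA", "b_CAC"),
                      backbone_geometry("ALA", "b_CN")), 6))) + 1
  for (mdl in c("c", "ca")) for (m in db$pairs[[mdl]])
    expect_true(all(m > 0 & m < span))
})

test_that("database building is linear in duplicates and order-insensitive", {
  fx1 <- make_protein("HHHHHCCCCCHHHHH", seed = 35, id = "a")
  fx2 <- make_protein("EEEEECCCCCCEEEEE", seed = 36, id = "b")
  db1 <- build_loop_db(list(fx1$structure, fx2$structure),
                       list(fx1$assignment, fx2$assignment))
  dbdup <- build_loop_db(list(fx1$structure, fx2$structure, fx1$structure,
                              fx2$structure),
                         list(fx1$assignment, fx2$assignment, fx1$assignment,
                              fx2$assignment))
  for (g in names(db1$pairs$c))
    expect_equal(nrow(dbdup$pairs$c[[g]]), 2L * nrow(db1$pairs$c[[g]]))
  dbrev <- build_loop_db(list(fx2$structure, fx1$structure),
                         list(fx2$assignment, fx1$assignment))
  for (mdl in c("c", "ca")) for (g in names(db1$pairs[[mdl]]))
    expect_identical(db1$pairs[[mdl]][[g]], dbrev$pairs[[mdl]][[g]])
  ## excluding a structure id removes its contribution
  dbx <- build_loop_db(list(fx1$structure, fx2$structure),
                       list(fx1$assignment, fx2$assignment),
                       exclude_ids = "a")
  only2 <- build_loop_db(list(fx2$structure), list(fx2$assignment))
  expect_equal(length(dbx$loops), length(only2$loops))
  for (g in names(only2$pairs$c))
    expect_identical(dbx$pairs$c[[g]], only2$pairs$c[[g]])
})
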