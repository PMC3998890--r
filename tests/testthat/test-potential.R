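# Atom typing, distance binning, pair counting, the log-ratio energy
# identities, and the brute-force scoring oracle.

test_that("the atom-type scheme has exactly 20 classes with the stated split", {
  sc <- atom_type_scheme()
  expect_equal(sc$n_types, 20L)
  ids <- integer()
  for (aa in amino_acids()) {
    topo <- sidechain_topology(aa)
    nms <- c("N", "CA", "C", "O", vapply(topo, `[[`, "", "name"))
    ids <- c(ids, assign_atom_type(rep(aa, length(nms)), nms))
  }
  expect_setequal(unique(ids), 1:20)
  ## side-chain classes: 6 carbon, 6 nitrogen, 3 oxygen, 1 sulfur
  side_names <- sc$names[5:20]
  expect_equal(sum(startsWith(side_names, "C_")), 6L)
  expect_equal(sum(startsWith(side_names, "N_")), 6L)
  expect_equal(sum(startsWith(side_names, "O_")), 3L)
  expect_equal(sum(side_names == "S"), 1L)
  ## one sulfur type shared by CYS and MET
  expect_equal(assign_atom_type("CYS", "SG"), assign_atom_type("MET", "SD"))
  ## backbone names map to backbone ids; proline N to its own class
  expect_equal(assign_atom_type("ALA", "CA"), 2L)
  expect_equal(assign_atom_type("GLY", "O"), 4L)
  expect_equal(assign_atom_type("ALA", "OXT"), 4L)
  expect_equal(assign_atom_type("PRO", "N"), 16L)
  expect_error(assign_atom_type("ALA", "XX9"), "cannot type")
})

test_that("bin_of follows the half-open convention with a sub-contact bin", {
  spec <- bin_spec(r_lo = 2, r_hi = 8, w = 0.2)
  expect_equal(spec$n_bins, 31L)
  expect_equal(bin_of(0, spec), 1L)
  expect_equal(bin_of(1.999, spec), 1L)
  expect_equal(bin_of(2.0, spec), 2L)     # exactly r_lo opens bin 2
  expect_equal(bin_of(2.199, spec), 2L)
  expect_equal(bin_of(2.2, spec), 3L)
  expect_equal(bin_of(7.999, spec), 31L)  # last bin
  expect_true(is.na(bin_of(8.0, spec)))
  expect_true(is.na(bin_of(9.0, spec)))
  ## edges cover [0, r_hi) without gaps
  d <- seq(0, 7.9999, by = 0.0001)
  expect_false(anyNA(bin_of(d, spec)))
  expect_error(bin_spec(2, 8, 0.23), "divide")
})

## tiny hand-countable system: a glycine "loop" plus one fixed atom
gly_fixture <- function(env_dist = 5.0) {
  gly <- data.frame(chain = "A", resno = 5, insert = "", resid = "GLY",
                    elety = c("N", "CA", "C", "O"),
                    x = c(0, 1.458, 2.0, 1.3), y = c(0, 0, 1.4, 2.4),
                    z = 0, stringsAsFactors = FALSE)
  env <- data.frame(chain = "A", resno = 20, insert = "", resid = "ALA",
                    elety = "CB", x = env_dist, y = 0, z = 0,
                    stringsAsFactors = FALSE)
  list(gly = gly, env = env)
}

test_that("observed counting matches a hand count and is linear", {
  fx <- gly_fixture(5.0)
  st <- lg_structure(rbind(fx$gly, fx$env), id = "tiny")
  asn <- data.frame(chain = "A", resno = c(5, 20), label = c("C", "C"))
  ## build a db with this single 1-residue loop by hand
  db <- structure(list(loops = list(list(structure_index = 1L, chain = "A",
                                         start = 5, end = 5)),
                       structures = list(st)), class = "lg_loopdb")
  spec <- bin_spec()
  obs <- count_observed(db, spec)
  ## 4 cross pairs at ~5 A (N, CA, C, O of the loop vs the env CB); the
  ## intra-loop pairs are same-residue and excluded
  expect_equal(obs$N, 4)
  expect_equal(sum(obs$n), 4)
  ## the exact cells: distance from each backbone atom to (5, 0, 0)
  dists <- sqrt((fx$gly$x - 5)^2 + fx$gly$y^2)
  for (i in 1:4) {
    t1 <- assign_atom_type("GLY", fx$gly$elety[i])
    t2 <- assign_atom_type("ALA", "CB")
    expect_equal(obs$n[min(t1, t2), max(t1, t2), bin_of(dists[i], spec)], 1)
  }
  ## doubling the database doubles every count
  db2 <- db; db2$loops <- c(db$loops, db$loops)
  obs2 <- count_observed(db2, spec)
  expect_equal(obs2$n, 2 * obs$n)
  ## pairs beyond r_hi not counted (every atom at least 8 A away)
  far <- gly_fixture(12.0)
  stf <- lg_structure(rbind(far$gly, far$env))
  dbf <- db; dbf$structures <- list(stf)
  expect_equal(count_observed(dbf, spec)$N, 0)
})

test_that("expected counts average decoys per loop and match the degenerate case", {
  fx <- gly_fixture(5.0)
  st <- lg_structure(rbind(fx$gly, fx$env))
  db <- structure(list(loops = list(list(structure_index = 1L, chain = "A",
                                         start = 5, end = 5)),
                       structures = list(st)), class = "lg_loopdb")
  spec <- bin_spec()
  obs <- count_observed(db, spec)
  ## decoys identical to the native: n_exp == n_obs exactly
  expd <- count_expected(db, list(list(fx$gly, fx$gly)), spec)
  expect_equal(expd$n, obs$n)
  ## two decoys at different distances: mean of the two count arrays
  d2 <- fx$gly; d2$x <- d2$x + 1  # shifts all four atoms 1 A closer
  e2 <- count_expected(db, list(list(fx$gly, d2)), spec)
  o2 <- count_observed(structure(list(loops = db$loops,
                                      structures = list(lg_structure(
                                        rbind(d2, fx$env)))),
                                 class = "lg_loopdb"), spec)
  expect_equal(e2$n, (obs$n + o2$n) / 2)
  ## permuting decoys changes nothing
  e3 <- count_expected(db, list(list(d2, fx$gly)), spec)
  expect_equal(e3$n, e2$n)
  expect_warning(count_expected(db, list(list()), spec), "no decoys")
})

test_that("the energy table obeys the log-ratio identities, caps, and symmetry", {
  spec <- bin_spec()
  n1 <- array(0, dim = c(20, 20, spec$n_bins))
  n2 <- n1
  n1[2, 5, 10] <- 50; n2[2, 5, 10] <- 50       # equal probabilities -> 0
  n1[3, 6, 12] <- 50 * exp(1); n2[3, 6, 12] <- 50  # ratio e -> -1
  n1[4, 7, 15] <- 25; n2[4, 7, 15] <- 0        # zero expected -> cap
  n1[1, 1, 1] <- 5; n2[1, 1, 1] <- 5           # sub-contact -> clash
  ## make the normalizers equal so the ratios are exactly the cell ratios
  N1 <- sum(n1); N2 <- sum(n2)
  pot <- build_potential(list(n = n1, N = N1), list(n = n2, N = N2), spec)
  r <- N2 / N1
  expect_equal(pot$E[2, 5, 10], -log(1 * r))
  expect_equal(pot$E[3, 6, 12] - pot$E[2, 5, 10], -1, tolerance = 1e-12)
  expect_equal(pot$E[4, 7, 15], 3)
  expect_equal(pot$E[1, 1, 1], 10)
  ## symmetry everywhere
  for (b in c(1, 10, 31)) expect_equal(pot$E[, , b], t(pot$E[, , b]))
  expect_error(build_potential(list(n = n1 * 0, N = 0),
                               list(n = n2, N = N2), spec), "all-zero")
  ## readable export covers all upper-triangle cells
  tab <- potential_table(pot)
  expect_equal(nrow(tab), 210L * spec$n_bins)
})

test_that("score_loop equals the brute-force O(n^2) oracle on fixtures", {
  set.seed(41)
  fx <- make_protein("HHHHCCCCCHHHH", seed = 41)
  st <- fx$structure
  loop <- list(chain = "A", start = 5, end = 9)
  loop_at <- st$atoms[st$atoms$resno >= 5 & st$atoms$resno <= 9, ]
  loop_at$resi <- loop_at$resno - 4L
  other_at <- st$atoms[!(st$atoms$resno >= 5 & st$atoms$resno <= 9), ]
  ## random but reproducible potential table
  spec <- bin_spec()
  pot <- null_potential(spec)
  pot$E <- array(round(rnorm(20 * 20 * spec$n_bins), 3),
                 dim = c(20, 20, spec$n_bins))
  for (b in seq_len(spec$n_bins)) {
    Eb <- pot$E[, , b]; Eb[lower.tri(Eb)] <- t(Eb)[lower.tri(Eb)]
    pot$E[, , b] <- Eb
  }
  e_pkg <- score_loop(loop_at, st, pot, loop = loop)
  e_brute <- brute_score(loop_at, other_at, pot)
  expect_equal(e_pkg, e_brute, tolerance = 1e-12)
  ## empty environment, single-atom loop -> 0
  single <- loop_at[loop_at$elety == "CA" & loop_at$resno == 7, ]
  empty_st <- lg_structure(single)
  expect_equal(score_loop(single, empty_st, pot,
                          loop = list(chain = "A", start = 7, end = 7)), 0)
})

test_that("fragment energies telescope exactly to the full loop score", {
  set.seed(43)
  fx <- make_protein("HHHHCCCCCHHHH", seed = 43)
  st <- fx$structure
  loop_at <- st$atoms[st$atoms$resno >= 5 & st$atoms$resno <= 9, ]
  other_at <- st$atoms[!(st$atoms$resno >= 5 & st$atoms$resno <= 9), ]
  spec <- bin_spec()
  pot <- null_potential(spec)
  pot$E <- array(round(rnorm(20 * 20 * spec$n_bins), 3),
                 dim = c(20, 20, spec$n_bins))
  for (b in seq_len(spec$n_bins)) {
    Eb <- pot$E[, , b]; Eb[lower.tri(Eb)] <- t(Eb)[lower.tri(Eb)]
    pot$E[, , b] <- Eb
  }
  env <- loopgrow:::energy_arrays(other_at)
  ## feed atoms one residue at a time: sum of fragments == full score
  total <- 0
  grown <- NULL
  for (rn in 5:9) {
    frag <- loop_at[loop_at$resno == rn, ]
    ctx <- list(env, grown)
    total <- total + fragment_energy(frag, ctx, pot)
    fa <- loopgrow:::energy_arrays(frag)
    grown <- if (is.null(grown)) fa else
      list(xyz = rbind(grown$xyz, fa$xyz), type = c(grown$type, fa$type),
           res = c(grown$res, fa$res), bb = c(grown$bb, fa$bb))
  }
  full <- score_loop(loop_at, st, pot, loop = list(chain = "A", start = 5,
                                                   end = 9))
  expect_equal(total, full, tolerance = 1e-12)
  ## clashing placement pays at least the clash constant
  pot$E[, , 1] <- 10
  clashing <- loop_at[1, ]
  near <- other_at[1, ]
  clashing[, c("x", "y", "z")] <- near[, c("x", "y", "z")] + c(0.5, 0, 0)
  e <- fragment_energy(clashing, list(loopgrow:::energy_arrays(near)), pot)
  expect_gte(e, 10)
})

test_that("the compiled pair-energy kernel matches the R reference", {
  set.seed(45)
  fx <- make_protein("HHHHCCCCCHHHH", seed = 45)
  st <- fx$structure
  loop_at <- st$atoms[st$atoms$resno >= 5 & st$atoms$resno <= 9, ]
  other_at <- st$atoms[!(st$atoms$resno >= 5 & st$atoms$resno <= 9), ]
  spec <- bin_spec()
  pot <- null_potential(spec)
  pot$E <- array(round(rnorm(20 * 20 * spec$n_bins), 3),
                 dim = c(20, 20, spec$n_bins))
  for (b in seq_len(spec$n_bins)) {
    Eb <- pot$E[, , b]; Eb[lower.tri(Eb)] <- t(Eb)[lower.tri(Eb)]
    pot$E[, , b] <- Eb
  }
  A <- loopgrow:::energy_arrays(loop_at)
  B <- loopgrow:::energy_arrays(other_at)
  e_cpp <- loopgrow:::pairs_eval(A, B, pot, spec, within_A = TRUE)
  e_r <- loopgrow:::pairs_eval_r(A, B, pot, spec, within_A = TRUE)
  expect_equal(e_cpp, e_r, tolerance = 1e-12)
  ## clash kernel against an independent count
  rad <- vdw_radius(loop_at$elety); radB <- vdw_radius(other_at$elety)
  cnt <- 0
  for (i in seq_len(nrow(A$xyz))) {
    d <- sqrt(colSums((t(B$xyz) - A$xyz[i, ])^2))
    sel <- which(d < 0.95 * (rad[i] + radB))
    if (length(sel))
      cnt <- cnt + sum(!loopgrow:::exclude_bonded(A$res[i], A$bb[i],
                                                  B$res[sel], B$bb[sel]))
  }
  m <- loopgrow:::clash_matrix(A$xyz, rad, A$res, A$bb, 0.95)
  cc <- loopgrow:::clash_count(loop_at, B, sort(unique(st$atoms$chain)), 0.95)
  expect_equal(cc, cnt + sum(m))
})
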