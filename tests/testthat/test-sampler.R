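# The chain-growth engine: step mechanics, seeded determinism, telescoping
# energies, side-chain construction, clash resolution, and ensemble
# statistics.

test_that("rank_and_report computes the three statistics and is permutation-safe", {
  ens <- structure(list(report = data.frame(
    model = 1:2, energy = c(1, 0), rmsd4 = c(2, 3), rmsd3 = c(1.8, 2.7),
    closure_residual = 0, restarts = 0L, flags = "")), class = "lg_ensemble")
  rr <- rank_and_report(ens)
  expect_equal(rr$min_rmsd, 2)
  expect_equal(rr$mean_rmsd, 2.5)
  expect_equal(rr$rmsd_lowest_energy, 3)
  ## permutation invariance
  ens2 <- ens; ens2$report <- ens$report[2:1, ]
  rr2 <- rank_and_report(ens2)
  expect_equal(rr2[c("min_rmsd", "mean_rmsd", "rmsd_lowest_energy")],
               rr[c("min_rmsd", "mean_rmsd", "rmsd_lowest_energy")])
  ## singleton: all three equal that conformation's RMSD
  ens1 <- ens; ens1$report <- ens$report[1, ]
  rr1 <- rank_and_report(ens1)
  expect_equal(unname(unlist(rr1[1:3])), c(2, 2, 2))
  ## energy tie broken by lower model index
  enst <- ens; enst$report$energy <- c(5, 5)
  expect_equal(rank_and_report(enst)$rmsd_lowest_energy, 2)
  ## no native: NA statistics, ranking still present
  ensn <- ens; ensn$report$rmsd4 <- NA_real_
  rrn <- rank_and_report(ensn)
  expect_true(is.na(rrn$min_rmsd))
  expect_equal(rrn$ranked$model, c(2, 1))
})

test_that("sampled conformations close properly and are seed-deterministic", {
  corpus <- lg_test_bundle()
  tg <- lg_test_target()
  cfg <- sampler_config(max_restarts = 50L)
  target <- prepare_target(tg$structure, tg$loop, corpus$bundle, cfg)
  set.seed(501)
  cf1 <- sample_loop(tg$structure, tg$loop, corpus$bundle, cfg, target = target)
  set.seed(501)
  cf2 <- sample_loop(tg$structure, tg$loop, corpus$bundle, cfg, target = target)
  expect_false(inherits(cf1, "lg_failure"))
  expect_identical(cf1$atoms, cf2$atoms)
  expect_identical(cf1$energy, cf2$energy)
  ## junction geometry within closure tolerance
  expect_lte(cf1$closure_residual, 1e-4)
  ## all backbone atoms present for every loop residue
  bb <- cf1$atoms[cf1$atoms$elety %in% c("N", "CA", "C", "O"), ]
  expect_equal(nrow(bb), 4L * length(tg$loop$sequence))
  ## all atoms inside the enlarged ellipsoid
  expect_true(all(in_ellipsoid(as.matrix(bb[, c("x", "y", "z")]),
                               target$ellipsoid)))
  ## clash audit clean
  expect_equal(cf1$n_clashes, 0L)
})

test_that("backbone growth energy telescopes to score_loop exactly", {
  corpus <- lg_test_bundle()
  tg <- lg_test_target()
  cfg <- sampler_config(side_chains = FALSE, max_restarts = 50L)
  target <- prepare_target(tg$structure, tg$loop, corpus$bundle, cfg)
  for (seed in 502:504) {
    set.seed(seed)
    cf <- sample_loop(tg$structure, tg$loop, corpus$bundle, cfg,
                      target = target)
    expect_false(inherits(cf, "lg_failure"))
    e_direct <- score_loop(cf, tg$structure, corpus$bundle$potential,
                           environment = target$env)
    expect_equal(cf$energy, e_direct, tolerance = 1e-10)
  }
})

test_that("full-atom energies telescope too when no clash rotation occurred", {
  corpus <- lg_test_bundle()
  tg <- lg_test_target()
  cfg <- sampler_config(max_restarts = 50L)
  target <- prepare_target(tg$structure, tg$loop, corpus$bundle, cfg)
  found <- FALSE
  for (seed in 505:514) {
    set.seed(seed)
    cf <- sample_loop(tg$structure, tg$loop, corpus$bundle, cfg,
                      target = target)
    if (inherits(cf, "lg_failure") || is.na(cf$energy)) next
    ## energy is still the growth sum: compare with a fresh re-score
    e_direct <- score_loop(cf, tg$structure, corpus$bundle$potential,
                           environment = target$env)
    expect_equal(cf$energy, e_direct, tolerance = 1e-10)
    found <- TRUE
  }
  expect_true(found)
})

test_that("infeasible anchors error out before any sampling", {
  corpus <- lg_test_bundle()
  tg <- lg_test_target()
  far <- tg$structure
  sel <- far$atoms$resno > 10
  far$atoms[sel, c("x", "y", "z")] <- far$atoms[sel, c("x", "y", "z")] + 200
  expect_error(prepare_target(far, tg$loop, corpus$bundle, sampler_config()),
               "infeasible")
})

test_that("a clash-dominated trial is essentially never selected", {
  ## two-trial softmax with the clash constant vs zero energy
  w <- exp(-(c(10, 0)) / 1)
  p_clash <- w[1] / sum(w)
  expect_lt(p_clash, 1e-4)
  set.seed(515)
  picks <- sample(1:2, 1e4, replace = TRUE, prob = w)
  expect_gt(mean(picks == 2L), 0.9999 - 4 * sqrt(p_clash / 1e4) - 1e-3)
})

test_that("ensembles are reproducible and nested under one master seed", {
  corpus <- lg_test_bundle()
  tg <- lg_test_target()
  cfg <- sampler_config(max_restarts = 50L)
  ens_a <- sample_ensemble(tg$structure, tg$loop, corpus$bundle, n = 4,
                           config = cfg, seed = 99, native = tg$native)
  ens_b <- sample_ensemble(tg$structure, tg$loop, corpus$bundle, n = 4,
                           config = cfg, seed = 99, native = tg$native)
  expect_identical(ens_a$report, ens_b$report)
  ## prefix property: first 4 of a 6-member run equal the 4-member run
  ens_c <- sample_ensemble(tg$structure, tg$loop, corpus$bundle, n = 6,
                           config = cfg, seed = 99, native = tg$native)
  expect_identical(ens_c$report[1:4, ], ens_a$report)
  ## min-RMSD is non-increasing in n for nested runs
  expect_lte(min(ens_c$report$rmsd4), min(ens_a$report$rmsd4))
  ## RMSD columns present and positive
  expect_true(all(ens_a$report$rmsd4 > 0))
  expect_true(all(ens_a$report$rmsd3 > 0))
})

test_that("side chains are complete, selected by energy, and re-scorable", {
  corpus <- lg_test_bundle()
  tg <- lg_test_target()
  cfg <- sampler_config(max_restarts = 50L)
  target <- prepare_target(tg$structure, tg$loop, corpus$bundle, cfg)
  set.seed(516)
  cf <- sample_loop(tg$structure, tg$loop, corpus$bundle, cfg, target = target)
  expect_false(inherits(cf, "lg_failure"))
  for (ri in seq_along(tg$loop$sequence)) {
    ty <- tg$loop$sequence[ri]
    want <- 4L + length(sidechain_topology(ty))
    have <- sum(cf$atoms$resno == tg$loop$start + ri - 1L)
    expect_equal(have, want)
  }
})

test_that("resolve_clashes rotates a constructed clash away and fixes nothing else", {
  ## a lysine whose side chain is forced into a fixed atom; a rotation about
  ## chi1 frees it
  n <- c(0, 0, 0); ca <- c(1.458, 0, 0)
  cc <- place_atom(c(0, 0, 1), n, ca, bond_geometry(1.525, 111.2), -60)
  sc <- build_side_chain("LYS", n, ca, cc, c(-65, 180, 180, 180))
  loop_at <- data.frame(chain = "A", resno = 5, insert = "", resid = "LYS",
                        elety = c("N", "CA", "C", "O", rownames(sc)),
                        rbind(data.frame(x = c(0, 1.458, cc[1], cc[1] + 1),
                                         y = c(0, 0, cc[2], cc[2]),
                                         z = c(0, 0, cc[3], cc[3] + 1)),
                              data.frame(x = sc[, 1], y = sc[, 2],
                                         z = sc[, 3])),
                        stringsAsFactors = FALSE)
  loop_at$resi <- 1L
  ## place a blocking atom right on the NZ position
  nz <- as.numeric(loop_at[loop_at$elety == "NZ", c("x", "y", "z")])
  env_at <- data.frame(chain = "A", resno = 40, insert = "", resid = "ALA",
                       elety = "CB", x = nz[1] + 0.3, y = nz[2], z = nz[3],
                       stringsAsFactors = FALSE)
  st <- lg_structure(rbind(loop_at[, names(env_at)], env_at))
  conf <- structure(list(atoms = loop_at, energy = 0, flags = character(),
                         n_clashes = 0L,
                         loop = list(chain = "A", start = 5, end = 5,
                                     sequence = "LYS")),
                    class = "lg_conformation")
  before <- loopgrow:::clash_count(loop_at, loopgrow:::energy_arrays(env_at),
                                   "A", 0.7)
  expect_gt(before, 0)
  out <- resolve_clashes(conf, st, ratio = 0.7)
  expect_equal(out$n_clashes, 0L)
  ## backbone untouched
  bb_before <- loop_at[loop_at$elety %in% c("N", "CA", "C", "O"),
                       c("x", "y", "z")]
  bb_after <- out$atoms[out$atoms$elety %in% c("N", "CA", "C", "O"),
                        c("x", "y", "z")]
  expect_identical(bb_before, bb_after)
  ## clash-free input is returned unchanged
  conf2 <- conf
  st2 <- lg_structure(loop_at[, names(env_at)])
  out2 <- resolve_clashes(conf2, st2, ratio = 0.7)
  expect_identical(out2$atoms, conf2$atoms)
  expect_equal(out2$n_clashes, 0L)
})

test_that("an all-glycine loop needs no side-chain stage", {
  corpus <- lg_test_bundle()
  fx <- make_protein("HHHHHHCCCCHHHHHH",
                     sequence = c(rep("ALA", 6), rep("GLY", 4), rep("ALA", 6)),
                     seed = 517)
  tg <- make_loop_target(fx$structure, "A", 7, 10)
  cfg <- sampler_config(max_restarts = 50L)
  target <- prepare_target(tg$structure, tg$loop, corpus$bundle, cfg)
  set.seed(518)
  cf <- sample_loop(tg$structure, tg$loop, corpus$bundle, cfg, target = target)
  expect_false(inherits(cf, "lg_failure"))
  expect_true(all(cf$atoms$elety %in% c("N", "CA", "C", "O")))
})
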