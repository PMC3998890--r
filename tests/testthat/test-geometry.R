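# Internal-coordinate geometry: placement/measurement round-trips, the
# analytic circle and circle/sphere constructions, and fixed-frame RMSD.

test_that("place_atom satisfies its construction constraints and round-trips", {
  a <- c(0, 0, 0); b <- c(1.5, 0, 0); cc <- c(2, 1.4, 0)
  g <- bond_geometry(1.33, 120)
  d0 <- place_atom(a, b, cc, g, 0)
  expect_lt(abs(d0[3]), 1e-9)  # zero dihedral stays in the frame plane
  for (tau in c(-179, -90, 0, 37.5, 120)) {
    d <- place_atom(a, b, cc, g, tau)
    expect_equal(sqrt(sum((d - cc)^2)), 1.33, tolerance = 1e-9)
    expect_lt(abs(wrap_angle(measure_dihedral(a, b, cc, d) - tau)), 1e-6)
  }
})

test_that("round-trip holds across random frames, lengths, angles, dihedrals", {
  set.seed(101)
  worst <- 0
  for (i in 1:2000) {
    a <- rnorm(3); b <- a + rnorm(3); cc <- b + rnorm(3)
    if (sqrt(sum((b - a)^2)) < 0.3 || sqrt(sum((cc - b)^2)) < 0.3) next
    ab <- b - a; bc <- cc - b
    cr <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
    if (sqrt(sum(cr^2)) < 1e-3) next
    tau <- runif(1, -180, 180)
    g <- bond_geometry(runif(1, 0.8, 2), runif(1, 61, 179))
    d <- place_atom(a, b, cc, g, tau)
    worst <- max(worst, abs(wrap_angle(measure_dihedral(a, b, cc, d) - tau)))
  }
  expect_lt(worst, 1e-6)
})

test_that("measure_dihedral follows the sign convention and handles trans", {
  a <- c(0, 0, 0); b <- c(1, 0, 0); cc <- c(1, 1, 0)
  d_cis <- c(0, 1, 0)
  expect_equal(measure_dihedral(a, b, cc, d_cis), 0, tolerance = 1e-9)
  d_trans <- c(2, 1, 0)
  expect_equal(measure_dihedral(a, b, cc, d_trans), -180)  # boundary maps down
  ## mirror image negates the dihedral
  set.seed(7)
  for (i in 1:50) {
    pts <- lapply(1:4, function(j) rnorm(3) * 2)
    di <- tryCatch(measure_dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
                   error = function(e) NULL)
    if (is.null(di) || abs(abs(di) - 180) < 1e-6) next
    m <- lapply(pts, function(p) c(p[1], p[2], -p[3]))
    expect_equal(measure_dihedral(m[[1]], m[[2]], m[[3]], m[[4]]), -di,
                 tolerance = 1e-9)
  }
  expect_error(measure_dihedral(a, b, c(2, 0, 0), c(3, 0, 0)), "collinear")
})

test_that("placement_circle produces the right-angle case and obeys both constraints", {
  ci <- placement_circle(c(0, 0, 0), c(1.5, 0, 0), bond_geometry(1.5, 90))
  expect_equal(ci$center, c(1.5, 0, 0), tolerance = 1e-12)
  expect_equal(ci$radius, 1.5, tolerance = 1e-12)
  expect_equal(ci$normal, c(1, 0, 0), tolerance = 1e-12)
  ## 100 sampled points satisfy bond length and bond angle
  prev2 <- c(0.3, -1, 2); prev1 <- c(1.1, 0.4, 1.2)
  g <- bond_geometry(1.46, 111.2)
  ci <- placement_circle(prev2, prev1, g)
  p <- circle_point(ci, seq(0, 359, length.out = 100))
  dist_err <- abs(sqrt(rowSums(sweep(p, 2, prev1)^2)) - g$bond_length)
  ang <- apply(p, 1, function(q) {
    u <- (prev2 - prev1) / sqrt(sum((prev2 - prev1)^2))
    v <- (q - prev1) / sqrt(sum((q - prev1)^2))
    acos(sum(u * v)) * 180 / pi
  })
  expect_lt(max(dist_err), 1e-9)
  expect_lt(max(abs(ang - g$bond_angle)), 1e-9)
  expect_error(placement_circle(prev2, prev1, bond_geometry(1.4, 180)),
               "degenerate")
})

test_that("circle/sphere intersection matches a dense-scan oracle", {
  set.seed(33)
  for (rep in 1:10) {
    prev2 <- rnorm(3); prev1 <- prev2 + rnorm(3)
    if (sqrt(sum((prev1 - prev2)^2)) < 0.5) next
    ci <- placement_circle(prev2, prev1, bond_geometry(1.52, 112))
    anchor <- prev1 + rnorm(3) * 3
    ## pick a distance that certainly intersects: distance of a random
    ## circle point to the anchor
    dtarget <- sqrt(sum((circle_point(ci, runif(1, 0, 360)) - anchor)^2))
    pts <- intersect_circle_sphere(ci, anchor, dtarget)
    expect_gte(length(pts), 1L)
    for (p in pts) {
      expect_equal(sqrt(sum((p - anchor)^2)), dtarget, tolerance = 1e-9)
      expect_equal(sqrt(sum((p - prev1)^2)), 1.52, tolerance = 1e-9)
    }
    ## dense scan: the returned points coincide with the minima of
    ## | |P - anchor| - d | over a fine sweep of the circle
    phis <- seq(0, 360, length.out = 1e5)
    sweep_pts <- circle_point(ci, phis)
    dd <- abs(sqrt(rowSums(sweep(sweep_pts, 2, anchor)^2)) - dtarget)
    near <- sweep_pts[dd < 1e-3, , drop = FALSE]
    for (p in pts) {
      gaps <- sqrt(rowSums(sweep(near, 2, p)^2))
      expect_lt(min(gaps), 0.01)
    }
    ## infeasible distance -> empty
    dmin <- min(sqrt(rowSums(sweep(sweep_pts, 2, anchor)^2)))
    expect_length(intersect_circle_sphere(ci, anchor, max(dmin - 0.5, 0.01)), 0)
  }
})

test_that("axis-symmetric anchor raises the degenerate-case error", {
  ci <- placement_circle(c(0, 0, 0), c(1, 0, 0), bond_geometry(1.5, 90))
  on_axis <- ci$center + 2 * ci$normal
  d_exact <- sqrt(ci$radius^2 + 4)
  expect_error(intersect_circle_sphere(ci, on_axis, d_exact), "degenerate")
  expect_length(intersect_circle_sphere(ci, on_axis, d_exact + 1), 0)
})

test_that("backbone_rmsd has the closed-form translation value and is a metric", {
  ch <- build_ideal_chain(rep("ALA", 4), rep(-70, 4), rep(140, 4))
  conf <- do.call(rbind, c(ch$N, ch$CA, ch$C, ch$O))
  expect_equal(backbone_rmsd(conf, conf), 0)
  shifted <- sweep(conf, 2, c(1, 0, 0), `+`)
  expect_equal(backbone_rmsd(conf, shifted), 1.0, tolerance = 1e-12)
  ## symmetry and triangle inequality on random triples
  set.seed(5)
  for (i in 1:20) {
    a <- conf + matrix(rnorm(length(conf), 0, 0.5), nrow(conf))
    b <- conf + matrix(rnorm(length(conf), 0, 0.5), nrow(conf))
    cc <- conf + matrix(rnorm(length(conf), 0, 0.5), nrow(conf))
    expect_equal(backbone_rmsd(a, b), backbone_rmsd(b, a))
    expect_lte(backbone_rmsd(a, cc),
               backbone_rmsd(a, b) + backbone_rmsd(b, cc) + 1e-12)
  }
  expect_error(backbone_rmsd(conf, conf[1:8, ]), "different numbers")
})

test_that("the three-atom RMSD variant drops the carbonyl oxygen", {
  ch <- build_ideal_chain(rep("GLY", 3), rep(-80, 3), rep(150, 3))
  df <- do.call(rbind, lapply(1:3, function(i)
    data.frame(resi = i, elety = c("N", "CA", "C", "O"),
               x = c(ch$N[[i]][1], ch$CA[[i]][1], ch$C[[i]][1], ch$O[[i]][1]),
               y = c(ch$N[[i]][2], ch$CA[[i]][2], ch$C[[i]][2], ch$O[[i]][2]),
               z = c(ch$N[[i]][3], ch$CA[[i]][3], ch$C[[i]][3], ch$O[[i]][3]))))
  df2 <- df
  df2[df2$elety == "O", c("x", "y", "z")] <-
    df2[df2$elety == "O", c("x", "y", "z")] + 5
  expect_equal(backbone_rmsd(df, df2, atoms = "NCAC"), 0)
  expect_gt(backbone_rmsd(df, df2, atoms = "NCACO"), 1)
})
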