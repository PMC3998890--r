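# Analytic tripeptide loop closure. Given the last three grown backbone
# atoms (C of the residue before the tripeptide, then N and CA of its first
# residue) and the first three fixed anchor atoms after it (N, CA, C of the
# post-anchor residue), find all torsion assignments (phi1, psi1, phi2,
# psi2, phi3, psi3) that reconnect the chain with ideal bond geometry.
#
# With this anchor convention the junction constraints leave one continuous
# degree of freedom; it is pinned by prescribing the phi dihedral of the
# post-anchor residue (C3-Npost-CApost-Cpost). The solver then reduces to a
# one-dimensional problem: the middle CA lies on the circle where the
# spheres of the two rigid peptide-unit virtual bonds intersect; for each
# position on that circle the four remaining torsions follow in closed form
# (cone/cone intersections, two branches per unit), leaving a single angular
# residual at the third CA that is driven to zero by a scan with bisection
# polishing. Up to 16 solutions are returned, matching the count of the
# classical 16-degree-polynomial formulation.

#' Per-attempt closure geometry
#'
#' Bond lengths, bond angles and omega dihedrals used by one closure
#' attempt, residue-typed from the backbone geometry table, optionally
#' jittered by [perturbed_closure()].
#'
#' @param types Three-letter codes of the three residues to place.
#' @param type_post Code of the post-anchor residue (its C-N-CA angle is
#'   used at the junction).
#' @return A list of geometric parameters.
#' @keywords internal
closure_geometry <- function(types, type_post) {
  g <- lapply(types, backbone_geometry)
  list(b_NCA = vapply(g, `[[`, 0, "b_NCA"),
       b_CAC = vapply(g, `[[`, 0, "b_CAC"),
       b_CO = vapply(g, `[[`, 0, "b_CO"),
       a_NCAC = vapply(g, `[[`, 0, "a_NCAC"),
       a_CACN = vapply(g, `[[`, 0, "a_CACN"),
       a_CNCA = vapply(g, `[[`, 0, "a_CNCA"),
       a_CACO = vapply(g, `[[`, 0, "a_CACO"),
       b_CN = rep(backbone_geometry(types[1], "b_CN"), 3),
       a_CNCA_post = backbone_geometry(type_post, "a_CNCA"),
       omega = c(180, 180, 180))
}

#' Define a tripeptide closure problem
#'
#' @param c_prev,n1,ca1 Coordinates of the last three grown backbone atoms
#'   (C of the preceding residue, N and CA of the first closure residue).
#' @param n_post,ca_post,c_post Coordinates of the first three fixed anchor
#'   atoms after the loop.
#' @param types Three-letter codes of the three residues to place.
#' @param type_post Code of the post-anchor residue.
#' @param phi_post The phi dihedral (degrees) prescribed for the post-anchor
#'   residue; pins the closure's residual degree of freedom. Supply the
#'   measured value for self-closure, or draw from a Ramachandran marginal
#'   when predicting.
#' @return An object of class `lg_closure_problem`.
#' @export
closure_problem <- function(c_prev, n1, ca1, n_post, ca_post, c_post,
                            types, type_post = "ALA", phi_post = -120) {
  check_frame(c_prev, n1, ca1)
  check_frame(n_post, ca_post, c_post)
  structure(list(c_prev = c_prev, n1 = n1, ca1 = ca1, n_post = n_post,
                 ca_post = ca_post, c_post = c_post, types = types,
                 type_post = type_post, phi_post = phi_post,
                 geom = closure_geometry(types, type_post)),
            class = "lg_closure_problem")
}

## rigid peptide-unit constants between residues i and i+1: virtual CA-CA
## distance and the angle at CA_i between CA->C and CA->CA(next)
unit_constants <- function(cg, i) {
  ca <- c(0, 0, 0)
  cc <- c(cg$b_CAC[i], 0, 0)
  nn <- place_atom(c(0, 1, 0), ca, cc,
                   bond_geometry(cg$b_CN[i], cg$a_CACN[i]), 0)
  ca2 <- place_atom(ca, cc, nn,
                    bond_geometry(cg$b_NCA[i + 1], cg$a_CNCA[i + 1]),
                    cg$omega[i])
  list(d = vnorm(ca2 - ca), gamma = angle3(cc, ca, ca2))
}

## signed rotation angle (degrees) about unit axis u taking p0 to p1 as seen
## from a common axis point `org` (both assumed at the same axis latitude)
axis_rotation_angle <- function(p0, p1, org, u) {
  w0 <- (p0 - org) - sum((p0 - org) * u) * u
  w1 <- (p1 - org) - sum((p1 - org) * u) * u
  atan2(sum(cross3(w0, w1) * u), sum(w0 * w1)) / DEG
}

## Solve one peptide unit: from frame (aprev, n, ca) place C on its cone
## (branch s in {1,2}), then the psi rotation landing the next CA on
## `ca_next_t`. Returns NULL when the cone condition is infeasible.
solve_unit <- function(aprev, n, ca, ca_next_t, b_cac, a_ncac, b_cn, a_cacn,
                       b_nca_next, a_cnca_next, omega, gamma, s) {
  m <- unitv(n - ca)
  ref <- if (abs(m[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(cross3(m, ref)); e2 <- cross3(m, e1)
  v <- unitv(ca_next_t - ca)
  th <- a_ncac * DEG
  A <- sin(th) * sum(e1 * v); B <- sin(th) * sum(e2 * v)
  Cc <- cos(gamma * DEG) - cos(th) * sum(m * v)
  R <- sqrt(A^2 + B^2)
  if (R < abs(Cc)) return(NULL)
  alpha <- atan2(B, A) + (if (s == 1) 1 else -1) * acos(max(-1, min(1, Cc / R)))
  cdir <- cos(th) * m + sin(th) * (cos(alpha) * e1 + sin(alpha) * e2)
  cpos <- ca + b_cac * cdir
  gm_n <- bond_geometry(b_cn, a_cacn)
  gm_ca <- bond_geometry(b_nca_next, a_cnca_next)
  n0 <- place_atom(n, ca, cpos, gm_n, 0)
  ca0 <- place_atom(ca, cpos, n0, gm_ca, omega)
  u <- unitv(cpos - ca)
  delta <- axis_rotation_angle(ca0, ca_next_t, cpos, u)
  ## the analytic delta is defined up to the dihedral sign convention;
  ## verify and flip if needed
  n_a <- place_atom(n, ca, cpos, gm_n, wrap_angle(delta))
  ca_a <- place_atom(ca, cpos, n_a, gm_ca, omega)
  if (vnorm(ca_a - ca_next_t) > 1e-6) {
    n_b <- place_atom(n, ca, cpos, gm_n, wrap_angle(-delta))
    ca_b <- place_atom(ca, cpos, n_b, gm_ca, omega)
    if (vnorm(ca_b - ca_next_t) < vnorm(ca_a - ca_next_t)) {
      n_a <- n_b; ca_a <- ca_b; delta <- -delta
    }
  }
  list(c = cpos, n_next = n_a, ca_next = ca_a, psi = wrap_angle(delta),
       err = vnorm(ca_a - ca_next_t))
}

## residual (degrees) of the angle constraint at CA3 for scan position u and
## branch pair (s1, s2); attaches the intermediate atoms
closure_residual <- function(pr, cg, targets, circ, u, s1, s2) {
  ca2_t <- circ$foot + circ$rho * (cos(u) * circ$e1 + sin(u) * circ$e2)
  u1 <- solve_unit(pr$c_prev, pr$n1, pr$ca1, ca2_t,
                   cg$b_CAC[1], cg$a_NCAC[1], cg$b_CN[1], cg$a_CACN[1],
                   cg$b_NCA[2], cg$a_CNCA[2], cg$omega[1], circ$gamma1, s1)
  if (is.null(u1) || u1$err > 1e-6) return(NULL)
  u2 <- solve_unit(u1$c, u1$n_next, u1$ca_next, targets$ca3,
                   cg$b_CAC[2], cg$a_NCAC[2], cg$b_CN[2], cg$a_CACN[2],
                   cg$b_NCA[3], cg$a_CNCA[3], cg$omega[2], circ$gamma2, s2)
  if (is.null(u2) || u2$err > 1e-6) return(NULL)
  r <- angle3(u2$n_next, targets$ca3, targets$c3) - cg$a_NCAC[3]
  list(r = r, c1 = u1$c, n2 = u1$n_next, ca2 = u1$ca_next, psi1 = u1$psi,
       c2 = u2$c, n3 = u2$n_next, psi2 = u2$psi)
}

## forward-rebuild a candidate and package it as a solution (or NULL if the
## junction residuals exceed tolerance)
assemble_solution <- function(pr, cg, targets, parts, tol_bond = 1e-4,
                              tol_angle = 1e-3) {
  phi1 <- measure_dihedral(pr$c_prev, pr$n1, pr$ca1, parts$c1)
  phi2 <- measure_dihedral(parts$c1, parts$n2, parts$ca2, parts$c2)
  phi3 <- measure_dihedral(parts$c2, parts$n3, targets$ca3, targets$c3)
  ## forward rebuild with the attempt geometry
  C1 <- place_atom(pr$c_prev, pr$n1, pr$ca1,
                   bond_geometry(cg$b_CAC[1], cg$a_NCAC[1]), phi1)
  N2 <- place_atom(pr$n1, pr$ca1, C1,
                   bond_geometry(cg$b_CN[1], cg$a_CACN[1]), parts$psi1)
  CA2 <- place_atom(pr$ca1, C1, N2,
                    bond_geometry(cg$b_NCA[2], cg$a_CNCA[2]), cg$omega[1])
  C2 <- place_atom(C1, N2, CA2,
                   bond_geometry(cg$b_CAC[2], cg$a_NCAC[2]), phi2)
  N3 <- place_atom(N2, CA2, C2,
                   bond_geometry(cg$b_CN[2], cg$a_CACN[2]), parts$psi2)
  CA3 <- place_atom(CA2, C2, N3,
                    bond_geometry(cg$b_NCA[3], cg$a_CNCA[3]), cg$omega[2])
  C3 <- place_atom(C2, N3, CA3,
                   bond_geometry(cg$b_CAC[3], cg$a_NCAC[3]), phi3)
  res_bond <- abs(vnorm(C3 - pr$n_post) - cg$b_CN[3])
  res_angle <- max(abs(angle3(CA3, C3, pr$n_post) - cg$a_CACN[3]),
                   abs(angle3(C3, pr$n_post, pr$ca_post) - cg$a_CNCA_post))
  if (res_bond > tol_bond || res_angle > tol_angle) return(NULL)
  psi3 <- measure_dihedral(N3, CA3, C3, pr$n_post)
  O1 <- place_atom(pr$n1, pr$ca1, C1, bond_geometry(cg$b_CO[1], cg$a_CACO[1]),
                   wrap_angle(parts$psi1 + 180))
  O2 <- place_atom(N2, CA2, C2, bond_geometry(cg$b_CO[2], cg$a_CACO[2]),
                   wrap_angle(parts$psi2 + 180))
  O3 <- place_atom(N3, CA3, C3, bond_geometry(cg$b_CO[3], cg$a_CACO[3]),
                   wrap_angle(psi3 + 180))
  atoms <- rbind(C1 = C1, O1 = O1, N2 = N2, CA2 = CA2, C2 = C2, O2 = O2,
                 N3 = N3, CA3 = CA3, C3 = C3, O3 = O3)
  list(dihedrals = c(phi1 = phi1, psi1 = parts$psi1, phi2 = phi2,
                     psi2 = parts$psi2, phi3 = phi3, psi3 = psi3),
       atoms = atoms, residual_bond = res_bond, residual_angle = res_angle)
}

## ---- vectorized scan kernel ------------------------------------------------

rnorm3 <- function(M) sqrt(rowSums(M * M))
runit3 <- function(M) M / rnorm3(M)
rcross3 <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}
rowmat <- function(v, n) {
  if (n == 0L) return(matrix(numeric(), 0, 3))
  matrix(v, n, 3, byrow = TRUE)
}

## NeRF placement, rowwise over matrices (tau in degrees, scalar or vector)
vplace <- function(A, B, C, len, ang, tau) {
  th <- ang * DEG; tu <- tau * DEG
  bc <- runit3(C - B)
  nn <- runit3(rcross3(B - A, bc))
  mm <- rcross3(nn, bc)
  C + len * (-cos(th) * bc + sin(th) * cos(tu) * mm - sin(th) * sin(tu) * nn)
}

## Rodrigues rotation rowwise: rotate P about axes U (unit, rowwise) through
## origins O by theta degrees
vrot <- function(P, O, U, theta) {
  th <- theta * DEG; ct <- cos(th); st <- sin(th)
  p <- P - O
  dotu <- rowSums(p * U)
  p * ct + rcross3(U, p) * st + U * (dotu * (1 - ct)) + O
}

## rowwise orthonormal basis perpendicular to unit vectors M
vbasis <- function(M) {
  ref <- rowmat(c(1, 0, 0), nrow(M))
  swap <- abs(M[, 1]) >= 0.9
  ref[swap, ] <- rowmat(c(0, 1, 0), sum(swap))
  e1 <- runit3(rcross3(M, ref))
  list(e1 = e1, e2 = rcross3(M, e1))
}

## vectorized solve_unit: frames may vary rowwise. Returns positions and a
## feasibility mask. Arguments Aprev, Nm, Cam, CaT are n x 3 matrices.
vsolve_unit <- function(Aprev, Nm, Cam, CaT, b_cac, a_ncac, b_cn, a_cacn,
                        b_nca_next, a_cnca_next, omega, gamma, sgn) {
  n <- nrow(Cam)
  m <- runit3(Nm - Cam)
  bas <- vbasis(m)
  v <- runit3(CaT - Cam)
  th <- a_ncac * DEG
  A <- sin(th) * rowSums(bas$e1 * v)
  B <- sin(th) * rowSums(bas$e2 * v)
  Cc <- cos(gamma * DEG) - cos(th) * rowSums(m * v)
  R <- sqrt(A^2 + B^2)
  ok <- R >= abs(Cc) & R > 0
  alpha <- atan2(B, A) + sgn * acos(pmax(-1, pmin(1, Cc / R)))
  cdir <- cos(th) * m + sin(th) * (cos(alpha) * bas$e1 + sin(alpha) * bas$e2)
  Cp <- Cam + b_cac * cdir
  N0 <- vplace(Nm, Cam, Cp, b_cn, a_cacn, 0)
  Ca0 <- vplace(Cam, Cp, N0, b_nca_next, a_cnca_next, omega)
  u <- runit3(Cp - Cam)
  w0 <- (Ca0 - Cp); w0 <- w0 - rowSums(w0 * u) * u
  w1 <- (CaT - Cp); w1 <- w1 - rowSums(w1 * u) * u
  delta <- atan2(rowSums(rcross3(w0, w1) * u), rowSums(w0 * w1)) / DEG
  CaA <- vrot(Ca0, Cp, u, delta)
  CaB <- vrot(Ca0, Cp, u, -delta)
  flip <- rowSums((CaB - CaT)^2) < rowSums((CaA - CaT)^2)
  delta[flip] <- -delta[flip]
  CaA[flip, ] <- CaB[flip, , drop = FALSE]
  NN <- vrot(N0, Cp, u, delta)
  err <- rnorm3(CaA - CaT)
  ok <- ok & err < 1e-6
  list(c = Cp, n_next = NN, ca_next = CaA, psi = wrap_angle(delta), ok = ok)
}

## vectorized residual over a vector of scan angles (NA where infeasible);
## s1, s2 are per-element branch signs (+1/-1), recycled. Thin wrapper over
## the compiled kernel; the pure-R path (vsolve_unit / closure_residual)
## remains as the reference implementation cross-checked in the tests.
closure_residual_vec <- function(pr, cg, targets, circ, us, s1, s2) {
  n <- length(us)
  .closure_scan_cpp(us, rep_len(s1, n), rep_len(s2, n), circ$foot, circ$rho,
                    circ$e1, circ$e2, circ$gamma1, circ$gamma2,
                    pr$c_prev, pr$n1, pr$ca1, targets$ca3, targets$c3,
                    cg$b_CAC, cg$a_NCAC, cg$b_CN, cg$a_CACN,
                    cg$b_NCA, cg$a_CNCA, cg$omega)
}

## pure-R reference version of the batched residual (kept for the tests)
closure_residual_vec_r <- function(pr, cg, targets, circ, us, s1, s2) {
  n <- length(us)
  s1 <- rep_len(s1, n); s2 <- rep_len(s2, n)
  CaT2 <- rowmat(circ$foot, n) +
    circ$rho * (outer(cos(us), circ$e1) + outer(sin(us), circ$e2))
  u1 <- vsolve_unit(rowmat(pr$c_prev, n), rowmat(pr$n1, n), rowmat(pr$ca1, n),
                    CaT2, cg$b_CAC[1], cg$a_NCAC[1], cg$b_CN[1], cg$a_CACN[1],
                    cg$b_NCA[2], cg$a_CNCA[2], cg$omega[1], circ$gamma1, s1)
  u2 <- vsolve_unit(u1$c, u1$n_next, CaT2, rowmat(targets$ca3, n),
                    cg$b_CAC[2], cg$a_NCAC[2], cg$b_CN[2], cg$a_CACN[2],
                    cg$b_NCA[3], cg$a_CNCA[3], cg$omega[2], circ$gamma2, s2)
  a <- runit3(u2$n_next - rowmat(targets$ca3, n))
  b <- runit3(rowmat(targets$c3 - targets$ca3, n))
  r <- acos(pmax(-1, pmin(1, rowSums(a * b)))) / DEG - cg$a_NCAC[3]
  r[!(u1$ok & u2$ok)] <- NA_real_
  r
}

#' Solve the tripeptide closure problem
#'
#' Returns every torsion assignment (up to 16) that reconnects the chain to
#' the fixed anchor within the residual tolerances (junction bond within
#' 1e-4 Angstrom, junction angles within 1e-3 degrees), each re-verified by
#' forward rebuilding. Deterministic for fixed inputs; an empty list means
#' the anchors are out of reach for this geometry.
#'
#' @param problem An `lg_closure_problem`.
#' @param geom Optional geometry override (jittered copy of `problem$geom`).
#' @param n_scan Scan resolution of the 1D root search.
#' @return List of closure solutions (possibly empty), each with
#'   `dihedrals`, `atoms` (10 x 3 named matrix: C/O of residue 1, full
#'   backbone of residues 2-3), `residual_bond`, `residual_angle`.
#' @export
solve_closure <- function(problem, geom = NULL, n_scan = 1024L) {
  pr <- problem
  cg <- if (is.null(geom)) pr$geom else geom
  ## targets determined from the anchor side
  c3 <- place_atom(pr$c_post, pr$ca_post, pr$n_post,
                   bond_geometry(cg$b_CN[3], cg$a_CNCA_post), pr$phi_post)
  ca3 <- place_atom(pr$ca_post, pr$n_post, c3,
                    bond_geometry(cg$b_CAC[3], cg$a_CACN[3]), cg$omega[3])
  targets <- list(c3 = c3, ca3 = ca3)
  k1 <- unit_constants(cg, 1); k2 <- unit_constants(cg, 2)
  ## circle of CA2: intersection of spheres around CA1 (radius d12) and
  ## around the CA3 target (radius d23)
  axis <- ca3 - pr$ca1
  D <- vnorm(axis)
  if (D < 1e-9 || D >= k1$d + k2$d || D <= abs(k1$d - k2$d)) return(list())
  ax <- axis / D
  h <- (D^2 + k1$d^2 - k2$d^2) / (2 * D)
  rho2 <- k1$d^2 - h^2
  if (rho2 <= 0) return(list())
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(cross3(ax, ref)); e2 <- cross3(ax, e1)
  circ <- list(foot = pr$ca1 + h * ax, rho = sqrt(rho2), e1 = e1, e2 = e2,
               gamma1 = k1$gamma, gamma2 = k2$gamma)
  us <- seq(0, 2 * pi, length.out = n_scan + 1L)
  nu <- n_scan + 1L
  branches <- cbind(s1 = c(1, 1, -1, -1), s2 = c(1, -1, 1, -1))
  u_all <- rep(us, 4L)
  b1_all <- rep(branches[, 1], each = nu)
  b2_all <- rep(branches[, 2], each = nu)
  rvec <- function(u, v1, v2) closure_residual_vec(pr, cg, targets, circ, u, v1, v2)
  rs <- rvec(u_all, b1_all, b2_all)
  ## interval table over all branch pairs at once
  j <- which((seq_along(u_all) %% nu) != 0)  # drop last point of each branch
  r0 <- rs[j]; r1 <- rs[j + 1L]
  u0 <- u_all[j]; u1v <- u_all[j + 1L]
  v1 <- b1_all[j]; v2 <- b2_all[j]
  both <- !is.na(r0) & !is.na(r1)
  sc <- both & r0 * r1 < 0
  lo <- u0[sc]; hi <- u1v[sc]; flo <- r0[sc]
  blo1 <- v1[sc]; blo2 <- v2[sc]
  ## feasibility-edge intervals: locate the edge by batched bisection, then
  ## bracket between the edge and the feasible endpoint
  em <- which(is.na(r0) != is.na(r1))
  roots <- numeric(); rb1 <- numeric(); rb2 <- numeric()
  if (length(em)) {
    elo <- u0[em]; ehi <- u1v[em]
    ev1 <- v1[em]; ev2 <- v2[em]
    lo_ok <- !is.na(r0[em])
    edge_u <- rep(NA_real_, length(em)); edge_val <- rep(NA_real_, length(em))
    for (it in 1:34) {
      mid <- (elo + ehi) / 2
      fm <- rvec(mid, ev1, ev2)
      feas <- !is.na(fm)
      edge_u[feas] <- mid[feas]; edge_val[feas] <- fm[feas]
      move_lo <- feas == lo_ok
      elo[move_lo] <- mid[move_lo]
      ehi[!move_lo] <- mid[!move_lo]
    }
    feas_u <- ifelse(lo_ok, u0[em], u1v[em])
    feas_val <- ifelse(lo_ok, r0[em], r1[em])
    good <- !is.na(edge_val)
    direct <- good & abs(edge_val) < 1e-8
    brk <- good & !direct & edge_val * feas_val < 0
    if (any(brk)) {
      lo <- c(lo, pmin(edge_u[brk], feas_u[brk]))
      hi <- c(hi, pmax(edge_u[brk], feas_u[brk]))
      flo <- c(flo, ifelse(edge_u[brk] < feas_u[brk], edge_val[brk], feas_val[brk]))
      blo1 <- c(blo1, ev1[brk]); blo2 <- c(blo2, ev2[brk])
    }
    roots <- edge_u[direct]; rb1 <- ev1[direct]; rb2 <- ev2[direct]
  }
  ## batched bisection of all brackets across all branch pairs
  if (length(lo)) {
    dead <- rep(FALSE, length(lo))
    for (it in 1:34) {
      mid <- (lo + hi) / 2
      fm <- rvec(mid, blo1, blo2)
      dead <- dead | is.na(fm)
      upd <- !dead & flo * fm <= 0
      hi[upd] <- mid[upd]
      sel <- !dead & !upd
      lo[sel] <- mid[sel]; flo[sel] <- fm[sel]
    }
    roots <- c(roots, ((lo + hi) / 2)[!dead])
    rb1 <- c(rb1, blo1[!dead]); rb2 <- c(rb2, blo2[!dead])
  }
  sols <- list()
  for (ri in seq_along(roots)) {
    parts <- closure_residual(pr, cg, targets, circ, roots[ri],
                              if (rb1[ri] > 0) 1 else 2,
                              if (rb2[ri] > 0) 1 else 2)
    if (is.null(parts) || abs(parts$r) > 1e-6) next
    sol <- assemble_solution(pr, cg, targets, parts)
    if (!is.null(sol)) sols[[length(sols) + 1L]] <- sol
  }
  if (length(sols) == 0) return(sols)
  ## deduplicate (same torsion vector found from adjacent brackets/branches)
  dih <- do.call(rbind, lapply(sols, `[[`, "dihedrals"))
  keep <- !duplicated(round(dih, 3))
  sols <- sols[keep]
  if (length(sols) > 16L) {
    ord <- order(vapply(sols, `[[`, 0, "residual_bond"))
    sols <- sols[ord[1:16]]
  }
  sols
}

#' Closure with geometric jitter
#'
#' The first attempt uses unperturbed ideal geometry; subsequent attempts
#' draw Gaussian jitter on bond lengths, bond angles and omega dihedrals
#' (and optionally redraw the pinned post-anchor phi), which raises the
#' success rate for marginally unreachable anchors. Uses R's RNG stream.
#'
#' @param problem An `lg_closure_problem`.
#' @param n_attempts Maximum attempts (>= 1).
#' @param sigma_length,sigma_angle,sigma_omega Jitter standard deviations
#'   (Angstrom, degrees, degrees).
#' @param phi_post_sampler Optional function(n) returning draws of the
#'   pinned post-anchor phi for attempts after the first.
#' @param n_scan Scan resolution forwarded to [solve_closure()]; the
#'   sampler uses a coarser scan than the default since a missed root only
#'   costs one more jittered attempt.
#' @return A list with `solutions` (non-empty), `attempt`, and `geom` (the
#'   jittered geometry that succeeded), or NULL when every attempt failed.
#' @export
perturbed_closure <- function(problem, n_attempts = 20, sigma_length = 0.01,
                              sigma_angle = 1.0, sigma_omega = 2.0,
                              phi_post_sampler = NULL, n_scan = 512L) {
  stopifnot(n_attempts >= 1)
  for (att in seq_len(n_attempts)) {
    cg <- problem$geom
    pr <- problem
    if (att > 1) {
      jl <- function(x) x + stats::rnorm(length(x), 0, sigma_length)
      ja <- function(x) x + stats::rnorm(length(x), 0, sigma_angle)
      cg$b_NCA <- jl(cg$b_NCA); cg$b_CAC <- jl(cg$b_CAC); cg$b_CN <- jl(cg$b_CN)
      cg$a_NCAC <- ja(cg$a_NCAC); cg$a_CACN <- ja(cg$a_CACN)
      cg$a_CNCA <- ja(cg$a_CNCA)
      cg$omega <- wrap_angle(180 + stats::rnorm(3, 0, sigma_omega))
      if (!is.null(phi_post_sampler)) pr$phi_post <- phi_post_sampler(1)
    }
    sols <- solve_closure(pr, geom = cg, n_scan = n_scan)
    if (length(sols) > 0)
      return(list(solutions = sols, attempt = att, geom = cg))
  }
  NULL
}

#' Boltzmann selection among closure solutions
#'
#' Picks one solution with probability proportional to `exp(-E/T)` of its
#' fragment energy, mirroring the growth-step selection rule.
#'
#' @param solutions Non-empty list from [solve_closure()].
#' @param energies Numeric vector of fragment energies, one per solution.
#' @param temperature Effective temperature T (> 0).
#' @return The index of the selected solution.
#' @export
select_closure <- function(solutions, energies, temperature = 1) {
  stopifnot(length(solutions) >= 1, length(energies) == length(solutions))
  if (length(solutions) == 1L) return(1L)
  w <- exp(-(energies - min(energies)) / temperature)
  sample.int(length(solutions), 1L, prob = w)
}
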