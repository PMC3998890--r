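# The distance-guided sequential chain-growth engine. Loops grow residue by
# residue from the N-side anchor toward the C-side anchor: at each step the
# next C and CA atoms are placed by sampling their distances to the anchor
# from the fitted conditional KDEs and intersecting the resulting spheres
# with the placement circles; m such trials are reduced to k by the
# residue-typed (phi, psi) table and one of the k is drawn by a Boltzmann
# factor on its fragment energy. Three residues before the anchor the
# analytic closure takes over. Side chains are built afterwards from the chi
# tables and steric clashes resolved by chi-axis rotation.

#' Sampler configuration
#'
#' @param m Distance-guided trial count per growth step.
#' @param k Size of the dihedral-filtered subset (`1 <= k <= m`).
#' @param temperature Effective temperature of the Boltzmann selections.
#' @param omega_sd Standard deviation (degrees) of the trans peptide omega
#'   model, mean 180.
#' @param sc_trials Side-chain trial states per residue.
#' @param clash_ratio Two atoms clash when distance / (sum of vdW radii)
#'   falls below this ratio.
#' @param max_restarts Growth restarts per requested conformation.
#' @param closure_attempts Maximum jittered closure attempts.
#' @param jitter_length,jitter_angle,jitter_omega Closure jitter standard
#'   deviations (Angstrom, degrees, degrees).
#' @param side_chains Build side chains (set FALSE for backbone-only decoys).
#' @param require_clash_free Restart until the conformation passes the
#'   clash audit (FALSE for geometry-only decoys, which keep clashes by
#'   design).
#' @param redcell_c Residue-cutoff constant (Angstrom).
#' @return An object of class `lg_sampler_config`.
#' @export
sampler_config <- function(m = 32L, k = 8L, temperature = 1, omega_sd = 5,
                           sc_trials = 16L, clash_ratio = 0.7,
                           max_restarts = 100L, closure_attempts = 8L,
                           jitter_length = 0.01, jitter_angle = 1.0,
                           jitter_omega = 2.0, side_chains = TRUE,
                           require_clash_free = TRUE, redcell_c = 8) {
  stopifnot(k >= 1, k <= m, temperature > 0, omega_sd > 0)
  structure(as.list(environment()), class = "lg_sampler_config")
}

## dihedral-table marginal sampler for one axis (1 = phi, 2 = psi)
dihedral_marginal_sampler <- function(table, axis = 1L) {
  w <- if (axis == 1L) rowSums(table$counts) else colSums(table$counts)
  w <- w + table$eps * length(w)
  bw <- table$bin_width
  function(n) {
    b <- sample.int(length(w), n, replace = TRUE, prob = w)
    wrap_angle((b - 1) * bw - 180 + stats::runif(n, 0, bw))
  }
}

## grown-atom accumulator compatible with fragment_energy context
new_grown <- function(capacity) {
  list(xyz = matrix(NA_real_, capacity, 3), type = integer(capacity),
       res = integer(capacity), bb = integer(capacity),
       elety = character(capacity), resno = integer(capacity),
       resid = character(capacity), n = 0L)
}

grown_add <- function(gr, xyz, resid, resno, elety, reskey) {
  i <- gr$n + 1L
  gr$xyz[i, ] <- xyz
  gr$type[i] <- assign_atom_type(resid, elety)
  gr$res[i] <- reskey
  gr$bb[i] <- {
    b <- match(elety, c("N", "CA", "C", "O")); if (is.na(b)) 0L else b
  }
  gr$elety[i] <- elety; gr$resno[i] <- resno; gr$resid[i] <- resid
  gr$n <- i
  gr
}

grown_view <- function(gr, from = 1L, to = gr$n) {
  if (to < from) return(NULL)
  idx <- from:to
  list(xyz = gr$xyz[idx, , drop = FALSE], type = gr$type[idx],
       res = gr$res[idx], bb = gr$bb[idx])
}

## resolve the distance model for separation g (clamped to the largest
## fitted separation)
model_for_g <- function(models, g) {
  gs <- as.integer(names(models))
  models[[as.character(min(max(gs), max(min(gs), g)))]]
}

sample_distance <- function(kde, d_prev) {
  tryCatch(sample_conditional(kde, d_prev),
           lg_empty_slice = function(e) sample_marginal(kde))
}

## anchor/stem coordinates and loop bookkeeping for one target
loop_frame <- function(structure, loop) {
  pre <- loop$start - 1L; post <- loop$end + 1L
  ch <- loop$chain
  need <- list(n_prev = residue_atom(structure, ch, pre, "N"),
               ca_prev = residue_atom(structure, ch, pre, "CA"),
               c_prev = residue_atom(structure, ch, pre, "C"),
               o_prev = residue_atom(structure, ch, pre, "O"),
               n_post = residue_atom(structure, ch, post, "N"),
               ca_post = residue_atom(structure, ch, post, "CA"),
               c_post = residue_atom(structure, ch, post, "C"))
  if (any(vapply(need, is.null, logical(1))))
    stop("anchor residues lack complete backbone", call. = FALSE)
  res <- chain_residues(structure, ch)
  need$pre_type <- res$resid[match(pre, res$resno)]
  need$post_type <- res$resid[match(post, res$resno)]
  need$chains <- sort(unique(structure$atoms$chain))
  need$chain_id <- match(ch, need$chains)
  need
}

#' Build the enlarged ellipsoid for a loop target
#'
#' Convenience wrapper: foci are the C of the residue before the loop and
#' the N of the residue after it; the backbone bond lengths along the loop
#' path come from the geometry table for the loop sequence.
#'
#' @param structure Target `lg_structure` (loop removed or present).
#' @param loop Loop spec with `chain`, `start`, `end`, `sequence`
#'   (three-letter codes).
#' @param d_cut Interaction cutoff enlargement (default 8).
#' @return An `lg_ellipsoid`.
#' @export
loop_ellipsoid <- function(structure, loop, d_cut = 8) {
  fr <- loop_frame(structure, loop)
  lens <- c(backbone_geometry(fr$pre_type, "b_CN"),
            unlist(lapply(loop$sequence, function(ty)
              c(backbone_geometry(ty, "b_NCA"), backbone_geometry(ty, "b_CAC"),
                backbone_geometry(ty, "b_CN")))))
  build_ellipsoid(fr$c_prev, fr$n_post, lens, d_cut = d_cut)
}

#' One distance-guided growth step
#'
#' Advances the growth state by one residue: generates `m` trials (C placed
#' from the conditional distance model given the current CA-anchor distance,
#' the next N carried by a sampled omega, the next CA from the C-conditional
#' model, O by standard geometry), prunes trials leaving the ellipsoid,
#' keeps `k` by the residue-typed dihedral table, and draws one by
#' `exp(-E/T)` on the fragment energy. Returns the updated state or NULL on
#' step failure (no feasible trial).
#'
#' @param state Growth state from [sample_loop()]'s internals.
#' @param target Target context (models, potential, ellipsoid, environment).
#' @param config An `lg_sampler_config`.
#' @return Updated state, or NULL.
#' @export
grow_step <- function(state, target, config) {
  i <- state$i
  L <- length(state$types)
  ty <- state$types[i]
  ty_next <- state$types[i + 1L]
  g <- L - i + 1L
  A <- target$anchor
  gm_c <- bb_geom(ty, "b_CAC", "a_NCAC")
  gm_o <- bb_geom(ty, "b_CO", "a_CACO")
  gm_n <- bb_geom(ty, "b_CN", "a_CACN")
  gm_ca2 <- bb_geom(ty_next, "b_NCA", "a_CNCA")
  kde_c <- model_for_g(target$models$c, g)
  kde_ca <- model_for_g(target$models$ca, g - 1L)
  d_ca <- vnorm(state$ca_i - A)
  ## the C-placement slice is shared by all trials of this step; the slice
  ## for the next CA depends on the trial's C and is computed in the kernel
  slice_c <- conditional_slice(kde_c, d_ca)
  if (sum(slice_c) <= 0) {
    dx <- diff(kde_c$x); gmat <- kde_c$grid
    slice_c <- colSums((gmat[-nrow(gmat), , drop = FALSE] +
                          gmat[-1, , drop = FALSE]) / 2 * dx)
  }
  gv <- grown_view(state$grown)
  empty3 <- matrix(numeric(), 0, 3)
  tr <- .grow_trials_cpp(
    state$n_i, state$ca_i, state$c_prev, A, as.integer(config$m),
    kde_c$y, slice_c, kde_ca$grid, kde_ca$x, kde_ca$y,
    gm_c$bond_length, gm_c$bond_angle, gm_o$bond_length, gm_o$bond_angle,
    gm_n$bond_length, gm_n$bond_angle, gm_ca2$bond_length,
    gm_ca2$bond_angle, config$omega_sd,
    target$ellipsoid$f1, target$ellipsoid$f2, target$ellipsoid$threshold,
    if (g == 4L) target$reach_hi else -1,
    target$env$arrays$xyz, target$env_rad,
    as.integer(target$env$arrays$res), as.integer(target$env$arrays$bb),
    if (is.null(gv)) empty3 else gv$xyz,
    if (is.null(gv)) numeric() else ctx_radii(gv),
    as.integer(if (is.null(gv)) integer() else gv$res),
    as.integer(if (is.null(gv)) integer() else gv$bb),
    config$clash_ratio,
    as.integer(state$chain_off + state$resnos[i]),
    as.integer(state$chain_off + state$resnos[i + 1L]))
  nt <- tr$n
  if (nt == 0L) return(NULL)
  keep <- select_k_trials(list(phi = tr$phi, psi = tr$psi),
                          target$dihedral[[ty]], min(config$k, nt))
  trials <- lapply(keep, function(t2)
    list(xyz = tr$xyz[(4L * t2 - 3L):(4L * t2), , drop = FALSE],
         phi = tr$phi[t2], psi = tr$psi[t2]))
  frag_meta <- list(resid = c(ty, ty, ty_next, ty_next),
                    elety = c("C", "O", "N", "CA"),
                    reskey = state$chain_off + c(state$resnos[i], state$resnos[i],
                                                 state$resnos[i + 1L],
                                                 state$resnos[i + 1L]))
  ctx <- list(target$env$arrays, grown_view(state$grown))
  energies <- vapply(trials, function(tr) {
    A4 <- list(xyz = tr$xyz, type = assign_atom_type(frag_meta$resid, frag_meta$elety),
               res = frag_meta$reskey, bb = c(3L, 4L, 1L, 2L))
    fragment_energy(A4, ctx, target$potential)
  }, numeric(1))
  sel <- if (length(trials) == 1L) 1L else {
    w <- exp(-(energies - min(energies)) / config$temperature)
    sample.int(length(trials), 1L, prob = w)
  }
  tr <- trials[[sel]]
  for (a in 1:4)
    state$grown <- grown_add(state$grown, tr$xyz[a, ], frag_meta$resid[a],
                             if (a <= 2) state$resnos[i] else state$resnos[i + 1L],
                             frag_meta$elety[a], frag_meta$reskey[a])
  state$energy <- state$energy + energies[sel]
  state$phi[i] <- tr$phi; state$psi[i] <- tr$psi
  state$c_prev <- tr$xyz[1, ]
  state$n_i <- tr$xyz[3, ]
  state$ca_i <- tr$xyz[4, ]
  state$i <- i + 1L
  state
}

#' Sample one closed loop conformation
#'
#' Runs the growth engine until three residues remain, then the jittered
#' analytic closure with Boltzmann selection among its solutions. The
#' backbone's total energy is the telescoping sum of fragment energies,
#' which equals [score_loop()] of the finished backbone. With
#' `config$side_chains`, side chains are built and clashes resolved; a
#' conformation with remaining clashes triggers a restart. Restart budget
#' exhausted returns a failure report.
#'
#' @param structure Target structure with the loop region removed.
#' @param loop Loop spec: `chain`, `start`, `end`, `sequence` (three-letter
#'   codes, length = loop length).
#' @param bundle Fitted parameter bundle from [make_corpus()] /
#'   [fit_bundle()].
#' @param config An `lg_sampler_config`.
#' @param target Optional precomputed target context (see
#'   [prepare_target()]); built on the fly otherwise.
#' @return An `lg_conformation` (atoms, energy, dihedrals, closure metadata,
#'   `flags`), or an `lg_failure` object carrying the per-stage failure
#'   histogram when the restart budget is exhausted.
#' @export
sample_loop <- function(structure, loop, bundle, config = sampler_config(),
                        target = NULL) {
  if (is.null(target)) target <- prepare_target(structure, loop, bundle, config)
  L <- length(loop$sequence)
  stopifnot(L >= 3)
  failures <- c(step = 0L, closure = 0L, clash = 0L, prune = 0L)
  for (att in seq_len(config$max_restarts)) {
    conf <- try_grow_once(structure, loop, target, config)
    if (is.character(conf)) {
      failures[conf] <- failures[conf] + 1L
      next
    }
    if (config$side_chains) {
      conf <- build_side_chains(conf, structure, bundle, config, target)
      conf <- resolve_clashes(conf, structure, config$clash_ratio,
                              env = target$env)
      if (conf$n_clashes > 0 && config$require_clash_free) {
        failures["clash"] <- failures["clash"] + 1L
        if (att < config$max_restarts) next
        conf$flags <- unique(c(conf$flags, "clash_unresolved"))
      }
    }
    conf$restarts <- att - 1L
    conf$failures <- failures
    return(conf)
  }
  structure(list(failures = failures), class = "lg_failure")
}

## one growth + closure attempt; returns an lg_conformation or a failure tag
try_grow_once <- function(structure, loop, target, config) {
  fr <- target$frame
  L <- length(loop$sequence)
  types <- loop$sequence
  resnos <- loop$start:loop$end
  chain_off <- fr$chain_id * 100000L
  psi_prev <- wrap_angle(measure_dihedral(fr$n_prev, fr$ca_prev, fr$c_prev,
                                          fr$o_prev) + 180)
  n1 <- place_atom(fr$n_prev, fr$ca_prev, fr$c_prev,
                   bb_geom(fr$pre_type, "b_CN", "a_CACN"), psi_prev)
  ca1 <- place_atom(fr$ca_prev, fr$c_prev, n1,
                    bb_geom(types[1], "b_NCA", "a_CNCA"),
                    stats::rnorm(1, 180, config$omega_sd))
  if (!all(in_ellipsoid(rbind(n1, ca1), target$ellipsoid))) return("prune")
  if (frag_clash(rbind(n1, ca1), c(1L, 2L),
                 chain_off + c(resnos[1], resnos[1]), target$env$arrays,
                 target$env_rad, target$clash_ratio)) return("prune")
  grown <- new_grown(4L * L + 2L)
  grown <- grown_add(grown, n1, types[1], resnos[1], "N", chain_off + resnos[1])
  grown <- grown_add(grown, ca1, types[1], resnos[1], "CA", chain_off + resnos[1])
  e_init <- fragment_energy(grown_view(grown), list(target$env$arrays),
                            target$potential)
  state <- list(i = 1L, types = types, resnos = resnos, chain_off = chain_off,
                grown = grown, energy = e_init, c_prev = fr$c_prev,
                n_i = n1, ca_i = ca1,
                phi = rep(NA_real_, L), psi = rep(NA_real_, L))
  while (state$i <= L - 3L) {
    state <- grow_step(state, target, config)
    if (is.null(state)) return("step")
  }
  ## closure of the final three residues: per attempt, sweep several pinned
  ## post-anchor phi values over the reach-feasible arc with a coarse scan,
  ## keeping only solutions inside the ellipsoid and free of backbone
  ## clashes; geometry is jittered from the second attempt on
  cl_types <- types[(L - 2L):L]
  pps <- feasible_phi_post_sampler(state$ca_i, fr, cl_types, target)
  if (is.null(pps)) return("closure")
  cl_res <- resnos[(L - 2L):L]
  cl_bb <- match(c("C", "O", "N", "CA", "C", "O", "N", "CA", "C", "O"),
                 c("N", "CA", "C", "O"))
  cl_rk <- chain_off + cl_res[c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3)]
  gv <- grown_view(state$grown)
  keep_sol <- function(s) {
    all(in_ellipsoid(s$atoms, target$ellipsoid)) &&
      !frag_clash(s$atoms, cl_bb, cl_rk, target$env$arrays, target$env_rad,
                  target$clash_ratio) &&
      !frag_clash(s$atoms, cl_bb, cl_rk, gv, ctx_radii(gv),
                  target$clash_ratio)
  }
  prob <- closure_problem(state$c_prev, state$n_i, state$ca_i,
                          fr$n_post, fr$ca_post, fr$c_post,
                          cl_types, fr$post_type, phi_post = 0)
  sols <- NULL; res_attempt <- NA_integer_
  for (att in seq_len(config$closure_attempts)) {
    cg <- prob$geom
    if (att > 1) {
      cg$b_NCA <- cg$b_NCA + stats::rnorm(3, 0, config$jitter_length)
      cg$b_CAC <- cg$b_CAC + stats::rnorm(3, 0, config$jitter_length)
      cg$b_CN <- cg$b_CN + stats::rnorm(3, 0, config$jitter_length)
      cg$a_NCAC <- cg$a_NCAC + stats::rnorm(3, 0, config$jitter_angle)
      cg$a_CACN <- cg$a_CACN + stats::rnorm(3, 0, config$jitter_angle)
      cg$a_CNCA <- cg$a_CNCA + stats::rnorm(3, 0, config$jitter_angle)
      cg$omega <- wrap_angle(180 + stats::rnorm(3, 0, config$jitter_omega))
    }
    pool <- list()
    for (phi in pps(4L)) {
      prob$phi_post <- phi
      cand <- Filter(keep_sol, solve_closure(prob, geom = cg, n_scan = 128L))
      pool <- c(pool, cand)
    }
    if (length(pool)) { sols <- pool; res_attempt <- att; break }
  }
  if (is.null(sols)) return("closure")
  res <- list(attempt = res_attempt)
  meta <- list(resid = cl_types[c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3)],
               elety = c("C", "O", "N", "CA", "C", "O", "N", "CA", "C", "O"),
               resno = cl_res[c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3)])
  meta$reskey <- chain_off + meta$resno
  ctx <- list(target$env$arrays, grown_view(state$grown))
  energies <- vapply(sols, function(s) {
    A10 <- list(xyz = s$atoms, type = assign_atom_type(meta$resid, meta$elety),
                res = meta$reskey, bb = match(meta$elety, c("N", "CA", "C", "O")))
    fragment_energy(A10, ctx, target$potential)
  }, numeric(1))
  sel <- select_closure(sols, energies, config$temperature)
  sol <- sols[[sel]]
  for (a in seq_len(10L))
    state$grown <- grown_add(state$grown, sol$atoms[a, ], meta$resid[a],
                             meta$resno[a], meta$elety[a], meta$reskey[a])
  state$energy <- state$energy + energies[sel]
  d <- sol$dihedrals
  state$phi[(L - 2L):L] <- d[c("phi1", "phi2", "phi3")]
  state$psi[(L - 2L):L] <- d[c("psi1", "psi2", "psi3")]
  gr <- state$grown
  atoms <- data.frame(chain = loop$chain, resno = gr$resno[1:gr$n], insert = "",
                      resid = gr$resid[1:gr$n], elety = gr$elety[1:gr$n],
                      x = gr$xyz[1:gr$n, 1], y = gr$xyz[1:gr$n, 2],
                      z = gr$xyz[1:gr$n, 3], stringsAsFactors = FALSE)
  atoms$resi <- match(atoms$resno, resnos)
  structure(list(atoms = atoms, energy = state$energy,
                 phi = state$phi, psi = state$psi,
                 closure_attempt = res$attempt,
                 closure_residual = sol$residual_bond,
                 flags = character(), n_clashes = 0L, loop = loop),
            class = "lg_conformation")
}

## Backbone-fragment clash test against precomputed arrays: TRUE when any
## new atom sits below the vdW clash ratio from a context atom (with the
## bonded-pair exclusions). Used to hard-prune growth trials early, since a
## backbone clash cannot be repaired later.
frag_clash <- function(xyz, bb, reskey, ctx, ctx_rad, ratio) {
  if (is.null(ctx) || nrow(ctx$xyz) == 0) return(FALSE)
  rad4 <- c(1.55, 1.70, 1.70, 1.52)[bb]
  .clash_count_cpp(xyz, rad4, as.integer(reskey), as.integer(bb),
                   ctx$xyz, ctx_rad, as.integer(ctx$res),
                   as.integer(ctx$bb), ratio, FALSE, TRUE) > 0L
}

## vdW radii of context arrays (backbone code when available, else element
## of the stored atom name)
ctx_radii <- function(arr) {
  if (!is.null(arr$elety)) return(vdw_radius(arr$elety))
  c(1.55, 1.70, 1.70, 1.52)[pmax(arr$bb, 1L)]
}

## Sampler for the pinned post-anchor phi, restricted to the arc where the
## implied CA3 target is reachable by the tripeptide from the grown CA
## (|CA1 - CA3t| strictly between |d12 - d23| and d12 + d23, with margin),
## weighted by the residue-typed phi marginal. NULL when no value is
## feasible (the growth attempt is then restarted).
feasible_phi_post_sampler <- function(ca1, fr, cl_types, target,
                                      step = 5, margin = 0.3) {
  cg <- closure_geometry(cl_types, fr$post_type)
  k1 <- unit_constants(cg, 1)
  k2 <- unit_constants(cg, 2)
  grid <- seq(-180 + step / 2, 180 - step / 2, by = step)
  gm_cn <- bond_geometry(cg$b_CN[3], cg$a_CNCA_post)
  gm_cac <- bond_geometry(cg$b_CAC[3], cg$a_CACN[3])
  D <- vapply(grid, function(phi) {
    c3 <- place_atom(fr$c_post, fr$ca_post, fr$n_post, gm_cn, phi)
    ca3 <- place_atom(fr$ca_post, fr$n_post, c3, gm_cac, 180)
    vnorm(ca1 - ca3)
  }, numeric(1))
  lim_hi <- k1$d + k2$d
  feas <- D > abs(k1$d - k2$d) + margin & D < lim_hi - margin
  if (!any(feas)) return(NULL)
  tab <- target$dihedral[[fr$post_type]]
  w <- rowSums(tab$counts)[dihedral_bin(grid[feas], tab$bin_width)] + tab$eps
  ## closure solutions are scarce near full extension: bias the pinned phi
  ## toward values whose CA3 target sits well inside the reach interval
  w <- w * pmax(lim_hi - D[feas], margin)
  gf <- grid[feas]
  function(n) {
    idx <- if (length(gf) == 1L) rep(1L, n)
           else sample.int(length(gf), n, replace = TRUE, prob = w)
    wrap_angle(gf[idx] + stats::runif(n, -step / 2, step / 2))
  }
}

#' Precompute the per-target sampling context
#'
#' Resolves anchors, builds the enlarged ellipsoid and the Redcell
#' environment, and binds the distance/dihedral models and the potential.
#' Reused across all conformations of an ensemble.
#'
#' @inheritParams sample_loop
#' @return A target context list.
#' @export
prepare_target <- function(structure, loop, bundle, config = sampler_config()) {
  fr <- loop_frame(structure, loop)
  ell <- loop_ellipsoid(structure, loop, d_cut = bundle$potential$spec$r_hi)
  env <- environment_atoms(structure, loop, ell, bundle$radius,
                           c = config$redcell_c)
  dtabs <- lapply(setNames(AA3, AA3), function(ty) {
    tb <- bundle$dihedral[[ty]]
    if (is.null(tb)) dihedral_table(NULL, ty) else tb
  })
  post_tab <- dtabs[[fr$post_type]]
  ## necessary reach bound for the closure pivot CA: two CA-CA virtual
  ## bonds plus the anchor-to-CA3 offset, minus the feasibility margin
  d_caca <- 2 * 3.81
  d_n_ca3 <- sqrt(backbone_geometry("ALA", "b_CAC")^2 +
                    backbone_geometry("ALA", "b_CN")^2 -
                    2 * backbone_geometry("ALA", "b_CAC") *
                    backbone_geometry("ALA", "b_CN") *
                    cos(backbone_geometry("ALA", "a_CACN") * pi / 180))
  list(frame = fr, ellipsoid = ell, env = env, models = bundle$models,
       dihedral = dtabs, chi = bundle$chi, potential = bundle$potential,
       anchor = fr$n_post, reach_hi = d_caca + d_n_ca3 - 0.6,
       env_rad = vdw_radius(env$arrays$elety),
       clash_ratio = config$clash_ratio,
       phi_post_sampler = dihedral_marginal_sampler(post_tab, 1L))
}

#' Build side chains onto a sampled backbone
#'
#' Per residue in growth order: draws `sc_trials` chi vectors from the
#' residue-typed chi table, builds the side-chain atoms with ideal geometry,
#' and keeps one trial by `exp(-E/T)` on its fragment energy against the
#' environment, the loop backbone, and previously built side chains.
#'
#' @param conformation An `lg_conformation` with complete backbone.
#' @param structure The target structure.
#' @param bundle Parameter bundle (chi tables).
#' @param config An `lg_sampler_config`.
#' @param target Optional precomputed target context.
#' @return The conformation with side-chain atoms appended.
#' @export
build_side_chains <- function(conformation, structure, bundle,
                              config = sampler_config(), target = NULL) {
  loop <- conformation$loop
  if (is.null(target)) target <- prepare_target(structure, loop, bundle, config)
  bb <- conformation$atoms
  chain_off <- target$frame$chain_id * 100000L
  sc_rows <- list()
  built <- NULL  # accumulated side-chain arrays
  bb_arr <- energy_arrays(bb, chains = target$frame$chains)
  for (ri in seq_along(loop$sequence)) {
    ty <- loop$sequence[ri]
    if (ty == "GLY") next
    resno <- loop$start + ri - 1L
    sel <- bb$resno == resno
    n <- as.numeric(bb[sel & bb$elety == "N", c("x", "y", "z")])
    ca <- as.numeric(bb[sel & bb$elety == "CA", c("x", "y", "z")])
    cc <- as.numeric(bb[sel & bb$elety == "C", c("x", "y", "z")])
    nch <- chi_count(ty)
    n_trials <- if (nch == 0L) 1L else config$sc_trials
    chis <- if (nch == 0L) matrix(numeric(), 1, 0)
            else sample_chi(target$chi[[ty]] %||% chi_table(list(), ty), n_trials)
    cand <- vector("list", n_trials)
    energies <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      m <- build_side_chain(ty, n, ca, cc, chis[t, ])
      arr <- list(xyz = m, type = assign_atom_type(ty, rownames(m)),
                  res = rep(chain_off + resno, nrow(m)),
                  bb = rep(0L, nrow(m)))
      cand[[t]] <- arr
      energies[t] <- fragment_energy(arr, list(target$env$arrays, bb_arr, built),
                                     target$potential)
    }
    sel_t <- if (n_trials == 1L) 1L else {
      w <- exp(-(energies - min(energies)) / config$temperature)
      sample.int(n_trials, 1L, prob = w)
    }
    arr <- cand[[sel_t]]
    built <- if (is.null(built)) arr else
      list(xyz = rbind(built$xyz, arr$xyz), type = c(built$type, arr$type),
           res = c(built$res, arr$res), bb = c(built$bb, arr$bb))
    conformation$energy <- conformation$energy + energies[sel_t]
    sc_rows[[length(sc_rows) + 1L]] <-
      data.frame(chain = loop$chain, resno = resno, insert = "", resid = ty,
                 elety = rownames(arr$xyz), x = arr$xyz[, 1], y = arr$xyz[, 2],
                 z = arr$xyz[, 3], resi = ri, stringsAsFactors = FALSE)
  }
  if (length(sc_rows))
    conformation$atoms <- rbind(conformation$atoms, do.call(rbind, sc_rows))
  conformation
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## clash detection: pairs below the vdW ratio among (loop x env) and
## (loop x loop), with the energy exclusion rules (compiled kernel)
clash_count <- function(atoms, env_arrays, chains, ratio) {
  A <- energy_arrays(atoms, chains = chains)
  rad <- vdw_radius(atoms$elety)
  empty <- list(xyz = matrix(numeric(), 0, 3), res = integer(),
                bb = integer())
  BB <- if (!is.null(env_arrays) && nrow(env_arrays$xyz) > 0) env_arrays
        else empty
  brad <- if (nrow(BB$xyz) > 0) vdw_radius(BB$elety) else numeric()
  .clash_count_cpp(A$xyz, rad, as.integer(A$res), as.integer(A$bb),
                   BB$xyz, brad, as.integer(BB$res), as.integer(BB$bb),
                   ratio, TRUE, FALSE)
}

exclude_bonded <- function(res_i, bb_i, res_j, bb_j) {
  same <- res_j == res_i
  fwd <- res_j == res_i + 1L
  bwd <- res_j == res_i - 1L
  out <- same
  if (any(fwd)) out[fwd] <- out[fwd] | .excl_fwd[cbind(bb_i + 1L, bb_j[fwd] + 1L)]
  if (any(bwd)) out[bwd] <- out[bwd] | .excl_fwd[cbind(bb_j[bwd] + 1L, bb_i + 1L)]
  out
}

#' Resolve steric clashes by side-chain rotation
#'
#' Iteratively rotates the side chains of clashing loop residues about the
#' chi1 axis (chi2 for proline) in fixed 15-degree increments, keeping the
#' rotation with the fewest clashes (zero when possible). Backbone atoms are
#' never moved. Unresolvable clashes leave `n_clashes > 0` and a flag.
#'
#' @param conformation Full-atom `lg_conformation`.
#' @param structure The target structure.
#' @param ratio Clash ratio threshold (default 0.7).
#' @param env Precomputed environment (from the target context); NULL uses
#'   the full structure minus the loop.
#' @param max_passes Sweeps over the loop residues.
#' @return The conformation with `n_clashes` updated (and side chains
#'   possibly rotated).
#' @export
resolve_clashes <- function(conformation, structure, ratio = 0.7, env = NULL,
                            max_passes = 3L) {
  loop <- conformation$loop
  if (is.null(env)) {
    sets <- split_loop_environment(structure, loop$chain, loop$start, loop$end)
    env_arrays <- sets$other; chains <- sets$chains
  } else {
    env_arrays <- env$arrays; chains <- env$chains
  }
  at <- conformation$atoms
  total <- clash_count(at, env_arrays, chains, ratio)
  if (total == 0L) { conformation$n_clashes <- 0L; return(conformation) }
  angles <- seq(15, 345, by = 15)
  ## incremental counting: when one residue's side chain moves, only pairs
  ## involving those atoms change
  A_all <- energy_arrays(at, chains = chains)
  rad_all <- vdw_radius(at$elety)
  env_rad <- if (nrow(env_arrays$xyz) > 0) vdw_radius(env_arrays$elety)
             else numeric()
  sc_clash <- function(idx, xyz_sc) {
    rest <- setdiff(seq_len(nrow(at)), idx)
    cnt <- .clash_count_cpp(xyz_sc, rad_all[idx], as.integer(A_all$res[idx]),
                            as.integer(A_all$bb[idx]), env_arrays$xyz,
                            env_rad, as.integer(env_arrays$res),
                            as.integer(env_arrays$bb), ratio, FALSE, FALSE)
    cnt + .clash_count_cpp(xyz_sc, rad_all[idx], as.integer(A_all$res[idx]),
                           as.integer(A_all$bb[idx]),
                           A_all$xyz[rest, , drop = FALSE], rad_all[rest],
                           as.integer(A_all$res[rest]),
                           as.integer(A_all$bb[rest]), ratio, FALSE, FALSE)
  }
  for (pass in seq_len(max_passes)) {
    for (ri in seq_along(loop$sequence)) {
      ty <- loop$sequence[ri]
      if (chi_count(ty) == 0L) next
      resno <- loop$start + ri - 1L
      sel <- at$resno == resno
      sc_sel <- sel & !(at$elety %in% c("N", "CA", "C", "O"))
      if (!any(sc_sel)) next
      idx <- which(sc_sel)
      cur <- sc_clash(idx, A_all$xyz[idx, , drop = FALSE])
      if (cur == 0L) next
      if (ty == "PRO") {
        ax_from <- as.numeric(at[sel & at$elety == "CB", c("x", "y", "z")])
        ax_to <- as.numeric(at[sel & at$elety == "CG", c("x", "y", "z")])
        rot_rows <- which(sc_sel & !(at$elety %in% c("CB", "CG")))
      } else {
        ax_from <- as.numeric(at[sel & at$elety == "CA", c("x", "y", "z")])
        ax_to <- as.numeric(at[sel & at$elety == "CB", c("x", "y", "z")])
        rot_rows <- which(sc_sel & at$elety != "CB")
      }
      if (!length(rot_rows) || length(ax_to) == 0) next
      best <- cur; best_xyz <- NULL
      axis <- ax_to - ax_from
      base_xyz <- A_all$xyz[idx, , drop = FALSE]
      rot_pos <- match(rot_rows, idx)
      for (ang in angles) {
        m <- rotate_about_axis(A_all$xyz[rot_rows, , drop = FALSE],
                               ax_from, axis, ang)
        trial_xyz <- base_xyz
        trial_xyz[rot_pos, ] <- m
        cc <- sc_clash(idx, trial_xyz)
        if (cc < best) { best <- cc; best_xyz <- trial_xyz }
        if (cc == 0L) break
      }
      ## chi-axis spins exhausted: also try rebuilding from the canonical
      ## rotamer library (all chis change, backbone untouched)
      if (best > 0L) {
        nres <- as.numeric(at[sel & at$elety == "N", c("x", "y", "z")])
        cares <- as.numeric(at[sel & at$elety == "CA", c("x", "y", "z")])
        cres <- as.numeric(at[sel & at$elety == "C", c("x", "y", "z")])
        rot <- canonical_rotamers(ty)
        for (r in seq_len(nrow(rot))) {
          m <- build_side_chain(ty, nres, cares, cres, rot[r, ])
          ord <- match(at$elety[idx], rownames(m))
          trial_xyz <- m[ord, , drop = FALSE]
          cc <- sc_clash(idx, trial_xyz)
          if (cc < best) { best <- cc; best_xyz <- trial_xyz }
          if (cc == 0L) break
        }
      }
      if (!is.null(best_xyz)) {
        A_all$xyz[idx, ] <- best_xyz
        at[idx, c("x", "y", "z")] <- best_xyz
      }
    }
    if (clash_count(at, env_arrays, chains, ratio) == 0L) break
  }
  conformation$atoms <- at
  conformation$n_clashes <- clash_count(at, env_arrays, chains, ratio)
  if (conformation$n_clashes > 0)
    conformation$flags <- unique(c(conformation$flags, "clash_unresolved"))
  else
    conformation$flags <- setdiff(conformation$flags, "clash_unresolved")
  ## atoms may have moved: refresh the total energy
  conformation$energy <- NA_real_
  conformation
}

#' Sample an ensemble of loop conformations
#'
#' Draws `n` conformations (restarting failures), each from its own RNG
#' substream derived from the master seed, so ensembles are reproducible and
#' nested: the first `n` members of a larger run with the same seed are
#' identical. Each conformation is scored by [score_loop()] on the Redcell
#' environment; fixed-frame backbone RMSDs to the native loop are recorded
#' when a native conformation is supplied.
#'
#' @param structure Target structure (loop removed).
#' @param loop Loop spec (`chain`, `start`, `end`, `sequence`).
#' @param bundle Fitted parameter bundle.
#' @param n Ensemble size.
#' @param config An `lg_sampler_config`.
#' @param seed Master seed (integer).
#' @param native Optional native loop conformation for RMSD columns.
#' @return An `lg_ensemble`: list of conformations plus a report data frame
#'   (`model`, `energy`, `rmsd4`, `rmsd3`, `closure_residual`,
#'   `restarts`, `flags`).
#' @export
sample_ensemble <- function(structure, loop, bundle, n,
                            config = sampler_config(), seed = 1,
                            native = NULL) {
  stopifnot(n >= 1)
  target <- prepare_target(structure, loop, bundle, config)
  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
  confs <- vector("list", n)
  failures <- c(step = 0L, closure = 0L, clash = 0L, prune = 0L)
  n_failed <- 0L
  for (j in seq_len(n)) {
    set.seed(member_seeds[j])
    cf <- sample_loop(structure, loop, bundle, config, target = target)
    if (inherits(cf, "lg_failure")) {
      n_failed <- n_failed + 1L
      failures <- failures + cf$failures
      if (n_failed > 99 && n_failed / j > 0.99)
        stop("aggregate sampling failure rate above 99%; check the target",
             call. = FALSE)
      ## retry with a fresh derived seed until success
      retry <- 0L
      while (inherits(cf, "lg_failure") && retry < 50L) {
        retry <- retry + 1L
        set.seed((member_seeds[j] + 7919L * retry) %% (.Machine$integer.max - 1L) + 1L)
        cf <- sample_loop(structure, loop, bundle, config, target = target)
      }
      if (inherits(cf, "lg_failure"))
        stop("could not sample conformation ", j, call. = FALSE)
    }
    failures <- failures + cf$failures
    cf$energy <- score_loop(cf, structure, target$potential,
                            environment = target$env)
    if (!is.null(native)) {
      cf$rmsd4 <- backbone_rmsd(cf, native, atoms = "NCACO")
      cf$rmsd3 <- backbone_rmsd(cf, native, atoms = "NCAC")
    }
    confs[[j]] <- cf
  }
  report <- data.frame(
    model = seq_len(n),
    energy = vapply(confs, `[[`, 0, "energy"),
    rmsd4 = if (is.null(native)) NA_real_ else vapply(confs, `[[`, 0, "rmsd4"),
    rmsd3 = if (is.null(native)) NA_real_ else vapply(confs, `[[`, 0, "rmsd3"),
    closure_residual = vapply(confs, `[[`, 0, "closure_residual"),
    restarts = vapply(confs, `[[`, 0L, "restarts"),
    flags = vapply(confs, function(cf) paste(cf$flags, collapse = ";"), ""))
  structure(list(conformations = confs, report = report, seed = seed,
                 config = config, failures = failures, loop = loop),
            class = "lg_ensemble")
}

#' Ensemble summary statistics
#'
#' The three headline ensemble statistics: the minimum backbone RMSD over
#' the ensemble (sampling quality bound), the ensemble mean RMSD, and the
#' RMSD of the lowest-energy conformation (blind-selection quality; energy
#' ties broken by lower model index), plus the energy-ranked report table.
#'
#' @param ensemble An `lg_ensemble`.
#' @return A list with `min_rmsd`, `mean_rmsd`, `rmsd_lowest_energy`,
#'   `ranked` (report sorted by energy). RMSD fields are absent (NA) when no
#'   native was supplied.
#' @export
rank_and_report <- function(ensemble) {
  rep <- ensemble$report
  ord <- order(rep$energy, rep$model)
  ranked <- rep[ord, ]
  has_rmsd <- !all(is.na(rep$rmsd4))
  list(min_rmsd = if (has_rmsd) min(rep$rmsd4) else NA_real_,
       mean_rmsd = if (has_rmsd) mean(rep$rmsd4) else NA_real_,
       rmsd_lowest_energy = if (has_rmsd) ranked$rmsd4[1] else NA_real_,
       ranked = ranked)
}
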