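# Fitting and serializing the parameter bundle: distance KDEs per residue
# separation for both placement models, residue-typed dihedral and chi
# tables, the residue radius table, and the pair potential with its
# geometry-only decoy reference state. The bundle is a single JSON archive
# so fitted parameters travel as plain text.

#' Fit the full parameter bundle from a loop database
#'
#' Fits, in order: the (d_prev, d_new) KDEs per separation `g` (both the
#' C-placement and the CA-placement model; separations with fewer than 10
#' pairs are skipped and longer separations reuse the largest fitted `g`),
#' the residue-typed (phi, psi) and chi tables, the residue radius table;
#' then generates geometry-only decoys (growth with a zero potential) for
#' every loop and builds the pair potential from observed vs expected
#' counts.
#'
#' @param db An `lg_loopdb`.
#' @param winsor Winsorization level for KDE fitting.
#' @param bw_factor Bandwidth scale factor.
#' @param spec Distance-bin scheme (`lg_binspec`).
#' @param n_decoys Decoys per loop for the reference state.
#' @param seed Seed for decoy generation.
#' @param decoy_config Sampler configuration for decoys; the default uses a
#'   reduced trial count and no clash restarts (the reference state is
#'   deliberately geometry-only).
#' @return An object of class `lg_bundle`.
#' @export
fit_bundle <- function(db, winsor = 99, bw_factor = 1, spec = bin_spec(),
                       n_decoys = 5, seed = 1,
                       decoy_config = NULL) {
  models <- list(c = list(), ca = list())
  for (mdl in c("c", "ca")) {
    for (g in names(db$pairs[[mdl]])) {
      pm <- db$pairs[[mdl]][[g]]
      if (nrow(pm) < 10) next
      ## short separations can be geometry-determined (zero variance);
      ## those separations are handled by the closure, not the KDE
      fit <- tryCatch(fit_kde2d(pm, winsor = winsor, bw_factor = bw_factor),
                      error = function(e) NULL)
      if (!is.null(fit)) models[[mdl]][[g]] <- fit
    }
    ## keep only a contiguous leading range of g so clamping is well defined
    gs <- sort(as.integer(names(models[[mdl]])))
    models[[mdl]] <- models[[mdl]][as.character(gs)]
  }
  if (length(models$c) == 0 || length(models$ca) == 0)
    stop("too few distance pairs to fit any conditional model", call. = FALSE)
  dihedral <- lapply(db$dihedrals, function(m) dihedral_table(m))
  for (ty in names(dihedral)) dihedral[[ty]]$residue_type <- ty
  chi <- list()
  for (ty in unique(names(db$chis)))
    chi[[ty]] <- chi_table(db$chis[[ty]], ty)
  radius <- residue_radius_table(db)
  bundle <- structure(list(models = models, dihedral = dihedral, chi = chi,
                           radius = radius, s_max = max_sidechain_length(),
                           potential = NULL,
                           options = list(winsor = winsor,
                                          bw_factor = bw_factor,
                                          r_lo = spec$r_lo, r_hi = spec$r_hi,
                                          w = spec$w, n_decoys = n_decoys),
                           meta = list(n_loops = length(db$loops),
                                       decoy_seed = seed)),
                      class = "lg_bundle")
  ## geometry-only decoys for the reference state
  if (is.null(decoy_config))
    decoy_config <- sampler_config(m = 8L, k = 4L, max_restarts = 10L,
                                   side_chains = TRUE,
                                   require_clash_free = FALSE)
  null_pot <- null_potential(spec)
  decoy_bundle <- bundle
  decoy_bundle$potential <- null_pot
  decoys <- vector("list", length(db$loops))
  set.seed(seed)
  loop_seeds <- sample.int(.Machine$integer.max - 1L, length(db$loops),
                           replace = TRUE)
  for (li in seq_along(db$loops)) {
    rec <- db$loops[[li]]
    st <- db$structures[[rec$structure_index]]
    truncated <- drop_residues(st, rec$chain, rec$start, rec$end)
    loop <- list(chain = rec$chain, start = rec$start, end = rec$end,
                 sequence = rec$sequence)
    target <- tryCatch(prepare_target(truncated, loop, decoy_bundle,
                                      decoy_config),
                       error = function(e) NULL)
    if (is.null(target)) next
    dl <- list()
    set.seed(loop_seeds[li])
    for (d in seq_len(n_decoys)) {
      cf <- sample_loop(truncated, loop, decoy_bundle, decoy_config,
                        target = target)
      if (!inherits(cf, "lg_failure")) dl[[length(dl) + 1L]] <- cf$atoms
    }
    decoys[[li]] <- dl
  }
  obs <- count_observed(db, spec)
  expd <- count_expected(db, decoys, spec)
  bundle$potential <- build_potential(obs, expd, spec)
  bundle
}

#' A zero-energy potential on a bin scheme
#'
#' All energies are zero, including the sub-contact bin; used for
#' geometry-only decoy growth where the potential term is disabled.
#'
#' @param spec An `lg_binspec`.
#' @return An `lg_potential` whose `E` is identically 0.
#' @export
null_potential <- function(spec = bin_spec()) {
  z <- array(0, dim = c(20, 20, spec$n_bins))
  structure(list(E = z, n_obs = z, n_exp = z, N_obs = 1, N_exp = 1,
                 spec = spec, cap = 0, clash = 0),
            class = "lg_potential")
}

#' @export
print.lg_bundle <- function(x, ...) {
  cat("<lg_bundle> g(c):", paste(names(x$models$c), collapse = ","),
      "; dihedral types:", length(x$dihedral),
      "; potential:", if (is.null(x$potential)) "none" else "fitted", "\n")
  invisible(x)
}

## ---- JSON serialization ----------------------------------------------------

kde_to_list <- function(k) list(grid = as.vector(k$grid), x = k$x, y = k$y,
                                h = k$h, n = k$n, winsor = k$winsor,
                                bw_factor = k$bw_factor)

kde_from_list <- function(l) {
  structure(list(grid = matrix(l$grid, length(l$x), length(l$y)), x = l$x,
                 y = l$y, h = l$h, n = l$n, winsor = l$winsor,
                 bw_factor = l$bw_factor), class = "lg_kde2d")
}

#' Write a parameter bundle as a JSON archive
#'
#' @param bundle An `lg_bundle`.
#' @param path Output path (single JSON file).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  pot <- bundle$potential
  out <- list(
    version = "1",
    options = bundle$options,
    meta = bundle$meta,
    s_max = bundle$s_max,
    radius = as.list(bundle$radius),
    models = lapply(bundle$models, function(mm) lapply(mm, kde_to_list)),
    dihedral = lapply(bundle$dihedral, function(t)
      list(counts = as.vector(t$counts), bin_width = t$bin_width,
           eps = t$eps, total = t$total, residue_type = t$residue_type)),
    chi = lapply(bundle$chi, function(t)
      list(bins = if (is.null(t$bins)) NULL else as.vector(t$bins),
           n_rows = if (is.null(t$bins)) 0L else nrow(t$bins),
           counts = t$counts, bin_width = t$bin_width, n_chi = t$n_chi,
           residue_type = t$residue_type)),
    potential = list(E = as.vector(pot$E), n_obs = as.vector(pot$n_obs),
                     n_exp = as.vector(pot$n_exp), N_obs = pot$N_obs,
                     N_exp = pot$N_exp, cap = pot$cap, clash = pot$clash,
                     r_lo = pot$spec$r_lo, r_hi = pot$spec$r_hi,
                     w = pot$spec$w))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a parameter bundle from a JSON archive
#'
#' @param path Path written by [write_bundle()].
#' @return An `lg_bundle`.
#' @export
read_bundle <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- bin_spec(l$potential$r_lo, l$potential$r_hi, l$potential$w)
  nb <- spec$n_bins
  dihedral <- lapply(l$dihedral, function(t) {
    nbb <- as.integer(round(360 / t$bin_width))
    structure(list(counts = matrix(t$counts, nbb, nbb),
                   bin_width = t$bin_width, eps = t$eps, total = t$total,
                   residue_type = t$residue_type,
                   logZ = log(t$total + t$eps * nbb * nbb)),
              class = "lg_dihedral_table")
  })
  chi <- lapply(l$chi, function(t) {
    bins <- if (t$n_rows == 0) NULL else matrix(t$bins, t$n_rows, t$n_chi)
    structure(list(bins = bins, counts = t$counts, bin_width = t$bin_width,
                   n_chi = t$n_chi, residue_type = t$residue_type),
              class = "lg_chi_table")
  })
  pot <- structure(list(E = array(l$potential$E, dim = c(20, 20, nb)),
                        n_obs = array(l$potential$n_obs, dim = c(20, 20, nb)),
                        n_exp = array(l$potential$n_exp, dim = c(20, 20, nb)),
                        N_obs = l$potential$N_obs, N_exp = l$potential$N_exp,
                        spec = spec, cap = l$potential$cap,
                        clash = l$potential$clash),
                   class = "lg_potential")
  structure(list(models = lapply(l$models, function(mm)
    lapply(mm, kde_from_list)),
    dihedral = dihedral, chi = chi,
    radius = unlist(l$radius), s_max = l$s_max, potential = pot,
    options = l$options, meta = l$meta), class = "lg_bundle")
}
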