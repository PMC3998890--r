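# Synthetic-fixture generator: ideal-geometry polypeptides with prescribed
# secondary-structure plans (helix / strand / coil runs), full side chains
# from canonical rotamers, excisable loop targets with retained natives, and
# a corpus builder that runs the whole fitting pipeline so every model in
# the package can be exercised without external data.

## coil (phi, psi) generator: mixture of broad Gaussians on the three
## classic Ramachandran basins (alpha, beta, left-handed alpha)
.coil_basins <- list(list(c = c(-63, -43), sd = 15, w = 0.35),
                     list(c = c(-110, 130), sd = 20, w = 0.45),
                     list(c = c(60, 45), sd = 15, w = 0.20))

sample_coil_phipsi <- function(n) {
  w <- vapply(.coil_basins, `[[`, 0, "w")
  b <- sample.int(length(.coil_basins), n, replace = TRUE, prob = w)
  t(vapply(b, function(j) {
    bb <- .coil_basins[[j]]
    wrap_angle(bb$c + stats::rnorm(2, 0, bb$sd))
  }, numeric(2)))
}

plan_phipsi <- function(labels) {
  n <- length(labels)
  out <- matrix(NA_real_, n, 2)
  nh <- sum(labels == "H"); ne <- sum(labels == "E"); nc <- sum(labels == "C")
  if (nh) out[labels == "H", ] <- matrix(c(-57, -47), nh, 2, byrow = TRUE)
  if (ne) out[labels == "E", ] <- matrix(c(-120, 130), ne, 2, byrow = TRUE)
  if (nc) out[labels == "C", ] <- sample_coil_phipsi(nc)
  out
}

## fully vectorized pairwise clash matrix machinery
clash_matrix <- function(xyz, rad, res, bb, ratio) {
  n <- nrow(xyz)
  g <- xyz %*% t(xyz)
  sq <- diag(g)
  d2 <- outer(sq, sq, `+`) - 2 * g
  lim <- (ratio * outer(rad, rad, `+`))^2
  close <- d2 < lim
  same <- outer(res, res, `==`)
  dfwd <- outer(res, res, function(a, b) b - a == 1L)
  exF <- .excl_fwd[bb + 1L, bb + 1L]
  excl <- same | (dfwd & exF) | (t(dfwd) & t(exF))
  m <- close & !excl
  m[lower.tri(m, diag = TRUE)] <- FALSE
  m
}

#' Count steric self-clashes within an atom table
#'
#' All unordered heavy-atom pairs below the vdW-ratio threshold, excluding
#' pairs within one residue and 1-2/1-3 pairs across the peptide bond.
#'
#' @param atoms Atom data frame (`chain`, `resno`, `resid`, `elety`, x/y/z).
#' @param ratio Clash ratio threshold.
#' @return A list with `count` and the offending residue numbers `resnos`.
#' @export
structure_clashes <- function(atoms, ratio = 0.7) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- vdw_radius(atoms$elety)
  bb <- match(atoms$elety, c("N", "CA", "C", "O"))
  bb[is.na(bb)] <- 0L
  res <- match(atoms$chain, sort(unique(atoms$chain))) * 100000L + atoms$resno
  m <- clash_matrix(xyz, rad, res, bb, ratio)
  hit <- which(m, arr.ind = TRUE)
  list(count = nrow(hit),
       resnos = sort(unique(atoms$resno[unique(as.vector(hit))])))
}

## greedy rotamer repacking: for each clashing residue, try every canonical
## rotamer (with jitter) and keep the variant whose side chain clashes
## least against the rest of the structure; a couple of passes
repack_side_chains <- function(atoms, ratio = 0.7, chi_jitter = 8,
                               passes = 2L) {
  bbnames <- c("N", "CA", "C", "O")
  sc_clashes <- function(scm, rn, others) {
    ## side-chain atoms of residue rn vs all atoms of other residues
    cnt <- 0L
    orad <- others$rad
    for (a in seq_len(nrow(scm))) {
      d2 <- (others$xyz[, 1] - scm[a, 1])^2 + (others$xyz[, 2] - scm[a, 2])^2 +
        (others$xyz[, 3] - scm[a, 3])^2
      lim <- (ratio * (vdw_radius(rownames(scm)[a]) + orad))^2
      cnt <- cnt + sum(d2 < lim & others$res != rn)
    }
    cnt
  }
  for (p in seq_len(passes)) {
    cl <- structure_clashes(atoms, ratio)
    if (cl$count == 0L) break
    for (rn in cl$resnos) {
      sel <- atoms$resno == rn
      ty <- atoms$resid[sel][1]
      if (chi_count(ty) == 0L) next
      sc_sel <- sel & !atoms$elety %in% bbnames
      if (!any(sc_sel)) next
      others <- list(xyz = as.matrix(atoms[!sel, c("x", "y", "z")]),
                     rad = vdw_radius(atoms$elety[!sel]),
                     res = atoms$resno[!sel])
      geta <- function(nm) as.numeric(atoms[sel & atoms$elety == nm,
                                            c("x", "y", "z")])
      n <- geta("N"); ca <- geta("CA"); cc <- geta("C")
      cur_m <- as.matrix(atoms[sc_sel, c("x", "y", "z"), drop = FALSE])
      rownames(cur_m) <- atoms$elety[sc_sel]
      cur <- sc_clashes(cur_m, rn, others)
      if (cur == 0L) next
      best <- cur; best_m <- NULL
      rot <- canonical_rotamers(ty)
      for (r in seq_len(nrow(rot))) {
        chis <- wrap_angle(rot[r, ] + stats::rnorm(ncol(rot), 0, chi_jitter))
        m <- build_side_chain(ty, n, ca, cc, chis)
        cnt <- sc_clashes(m, rn, others)
        if (cnt < best) { best <- cnt; best_m <- m }
        if (cnt == 0L) break
      }
      if (!is.null(best_m)) {
        ord <- match(atoms$elety[sc_sel], rownames(best_m))
        atoms[sc_sel, c("x", "y", "z")] <- best_m[ord, , drop = FALSE]
      }
    }
  }
  atoms
}

build_fixture_once <- function(labels, sequence, chi_jitter) {
  n <- length(labels)
  pp <- plan_phipsi(labels)
  N <- CA <- C <- O <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(backbone_geometry(sequence[1], "b_NCA"), 0, 0)
  C[[1]] <- place_atom(c(0, 1, 0), N[[1]], CA[[1]],
                       bb_geom(sequence[1], "b_CAC", "a_NCAC"), pp[1, 1])
  for (i in seq_len(n)[-1]) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         bb_geom(sequence[i - 1], "b_CN", "a_CACN"),
                         pp[i - 1, 2])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          bb_geom(sequence[i], "b_NCA", "a_CNCA"), 180)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                         bb_geom(sequence[i], "b_CAC", "a_NCAC"), pp[i, 1])
  }
  for (i in seq_len(n))
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         bb_geom(sequence[i], "b_CO", "a_CACO"),
                         wrap_angle(pp[i, 2] + 180))
  rows <- list()
  for (i in seq_len(n)) {
    ty <- sequence[i]
    bbm <- rbind(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O[[i]])
    scm <- NULL
    if (ty != "GLY") {
      rot <- canonical_rotamers(ty)
      chis <- rot[sample.int(nrow(rot), 1L), ]
      nch <- chi_count(ty)
      if (nch > 0) chis <- wrap_angle(chis + stats::rnorm(nch, 0, chi_jitter))
      scm <- build_side_chain(ty, N[[i]], CA[[i]], C[[i]], chis)
    }
    m <- rbind(bbm, scm)
    rows[[i]] <- data.frame(chain = "A", resno = i, insert = "", resid = ty,
                            elety = rownames(m), x = m[, 1], y = m[, 2],
                            z = m[, 3], stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  atoms
}

#' Generate an ideal-geometry synthetic protein
#'
#' Builds a single-chain polypeptide with ideal backbone bond geometry,
#' trans peptide bonds, canonical (phi, psi) per secondary-structure label
#' (helix (-57, -47); strand (-120, 130); coil drawn from a mixture of broad
#' Gaussians over the three classic Ramachandran basins), and full side
#' chains from canonical rotamers with a little chi jitter. The generator
#' is self-avoiding: folds with steric clashes (vdW ratio below
#' `clash_ratio`) are redrawn and side chains greedily repacked, so native
#' fixtures satisfy the same clash criterion the sampler enforces.
#' Optionally adds isotropic Gaussian coordinate noise. Deterministic under
#' `seed`.
#'
#' @param plan Character string of per-residue labels in H/E/C (defines the
#'   length), e.g. `"HHHHHCCCCCCHHHHH"`.
#' @param sequence Vector of three-letter residue codes, or NULL for a
#'   random sequence.
#' @param noise_sd Gaussian noise added to every coordinate (Angstrom).
#' @param chi_jitter Standard deviation (degrees) around the canonical
#'   rotamer chis.
#' @param seed Integer seed; NULL leaves the RNG stream untouched.
#' @param id Structure identifier.
#' @param clash_ratio Self-avoidance threshold; 0 disables the retry loop.
#' @param max_tries Redraws before accepting the least-clashing fold.
#' @return A list with `structure` (an `lg_structure`), `assignment` (chain
#'   / resno / label data frame), and the generating parameters.
#' @export
make_protein <- function(plan, sequence = NULL, noise_sd = 0, chi_jitter = 8,
                         seed = NULL, id = "fixture", clash_ratio = 0.7,
                         max_tries = 80L) {
  if (!is.null(seed)) set.seed(seed)
  labels <- strsplit(plan, "")[[1]]
  stopifnot(all(labels %in% c("H", "E", "C")))
  n <- length(labels)
  if (is.null(sequence)) sequence <- sample(setdiff(AA3, "PRO"), n, replace = TRUE)
  stopifnot(length(sequence) == n, all(sequence %in% AA3))
  best_atoms <- NULL; best_count <- Inf
  for (try in seq_len(max(1L, max_tries))) {
    atoms <- build_fixture_once(labels, sequence, chi_jitter)
    if (clash_ratio <= 0) { best_atoms <- atoms; best_count <- 0L; break }
    ## backbone collisions cannot be repaired by repacking: redraw the fold
    bb_only <- atoms[atoms$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
    if (structure_clashes(bb_only, clash_ratio)$count > 0L) next
    cnt <- structure_clashes(atoms, clash_ratio)$count
    if (cnt > 0L) {
      atoms <- repack_side_chains(atoms, clash_ratio, chi_jitter)
      cnt <- structure_clashes(atoms, clash_ratio)$count
    }
    if (cnt < best_count) { best_count <- cnt; best_atoms <- atoms }
    if (cnt == 0L) break
  }
  if (is.null(best_atoms)) {  # every try had a backbone collision
    atoms <- build_fixture_once(labels, sequence, chi_jitter)
    best_atoms <- repack_side_chains(atoms, clash_ratio, chi_jitter)
    best_count <- structure_clashes(best_atoms, clash_ratio)$count
  }
  atoms <- best_atoms
  if (noise_sd > 0) {
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noise_sd)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noise_sd)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noise_sd)
  }
  list(structure = lg_structure(atoms, id = id),
       assignment = data.frame(chain = "A", resno = seq_len(n),
                               label = labels, stringsAsFactors = FALSE),
       plan = plan, sequence = sequence, noise_sd = noise_sd, seed = seed,
       n_clashes = best_count)
}

#' Excise a loop from a structure to form a modeling target
#'
#' Removes the loop residues' atoms from a copy of the structure, keeping
#' the anchors intact, and returns the native loop atoms as ground truth
#' for RMSD evaluation.
#'
#' @param structure An `lg_structure`.
#' @param chain,start,end Loop region (must be interior: anchor residues on
#'   both sides).
#' @return A list with `structure` (truncated), `loop` (spec with `chain`,
#'   `start`, `end`, `sequence`), and `native` (atom data frame of the
#'   excised loop, with a `resi` index column).
#' @export
make_loop_target <- function(structure, chain, start, end) {
  res <- chain_residues(structure, chain)
  i0 <- match(start, res$resno); i1 <- match(end, res$resno)
  if (is.na(i0) || is.na(i1) || i0 > i1)
    stop("loop region not found in chain ", chain, call. = FALSE)
  if (i0 <= 1 || i1 >= nrow(res))
    stop("loop region touches a chain terminus; anchors required on both sides",
         call. = FALSE)
  sequence <- res$resid[i0:i1]
  at <- structure$atoms
  sel <- at$chain == chain & at$resno >= start & at$resno <= end
  native <- at[sel, , drop = FALSE]
  native$resi <- native$resno - start + 1L
  rownames(native) <- NULL
  truncated <- drop_residues(structure, chain, start, end)
  loop <- list(chain = chain, start = start, end = end, sequence = sequence)
  loop_ellipsoid(truncated, loop)  # errors early on infeasible anchors
  list(structure = truncated, loop = loop, native = native)
}

random_plan <- function() {
  seg <- function(l, lab) paste(rep(lab, l), collapse = "")
  n_coils <- 2L
  p <- seg(sample(5:8, 1), "H")
  for (k in seq_len(n_coils)) {
    p <- paste0(p, seg(sample(4:12, 1), "C"),
                seg(sample(5:8, 1), sample(c("H", "E"), 1)))
  }
  p
}

#' Generate a synthetic corpus and fit the full parameter bundle
#'
#' Generates `n_structures` diverse coil-containing fixtures, builds the
#' loop database, fits the distance KDEs, dihedral and chi tables and the
#' residue radius table, generates geometry-only decoys for the reference
#' state, and builds the pair potential. Byte-identical output for a fixed
#' seed.
#'
#' @param n_structures Number of fixtures (>= 20 for stable KDE fits).
#' @param seed Master seed.
#' @param n_decoys Decoys per loop for the reference state.
#' @param winsor Winsorization level for the distance KDEs.
#' @param spec Distance-bin scheme of the potential.
#' @param noise_sd Coordinate noise of the fixtures.
#' @return A list with `bundle` (class `lg_bundle`), `db` (the
#'   `lg_loopdb`), and the fixture lists.
#' @export
make_corpus <- function(n_structures = 40, seed = 1, n_decoys = 5,
                        winsor = 99, spec = bin_spec(), noise_sd = 0) {
  stopifnot(n_structures >= 20)
  set.seed(seed)
  fixtures <- lapply(seq_len(n_structures), function(s)
    make_protein(random_plan(), noise_sd = noise_sd, seed = NULL,
                 id = sprintf("fix%03d", s)))
  structures <- lapply(fixtures, `[[`, "structure")
  assignments <- lapply(fixtures, `[[`, "assignment")
  db <- build_loop_db(structures, assignments)
  bundle <- fit_bundle(db, winsor = winsor, spec = spec, n_decoys = n_decoys,
                       seed = seed + 1)
  bundle$meta$corpus_seed <- seed
  bundle$meta$n_structures <- n_structures
  list(bundle = bundle, db = db, fixtures = fixtures)
}
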