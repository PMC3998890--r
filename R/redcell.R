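# Redcell: REsidue-residue Distance Cutoff and ELLipsoid criterion. Bounds
# the set of atoms that can ever interact with a sampled loop conformation,
# so energy evaluation cost is independent of protein size, and provides the
# growth-pruning test. The enlarged ellipsoid is defined by the
# sum-of-distances threshold to the two anchor foci: backbone loop atoms
# satisfy sum <= L (sum of the loop's backbone bond lengths, by the triangle
# inequality along the chain), side-chain atoms add at most 2*s_max, and
# interaction partners at most 2*d_cut more — hence semi-axes enlarged by
# s_max + d_cut, i.e. threshold L + 2*(s_max + d_cut), which makes the
# filtered energy exactly equal to the unfiltered one.

#' Effective residue radii from a loop database
#'
#' The effective radius of a residue type is the largest distance from a
#' residue's geometric center (over heavy atoms) to any of its heavy atoms,
#' maximized over all instances in the database structures. Types absent
#' from the database fall back to a radius computed from the shipped
#' side-chain topology in an extended conformation.
#'
#' @param db An `lg_loopdb` (or a list of `lg_structure`s).
#' @return Named numeric vector of radii (Angstrom) for all 20 residue
#'   types.
#' @export
residue_radius_table <- function(db) {
  structures <- if (inherits(db, "lg_loopdb")) db$structures else db
  rad <- setNames(rep(0, length(AA3)), AA3)
  for (st in structures) {
    at <- st$atoms
    key <- paste(at$chain, at$resno, at$insert)
    for (grp in split(seq_len(nrow(at)), key)) {
      ty <- at$resid[grp[1]]
      if (!ty %in% AA3) next
      xyz <- as.matrix(at[grp, c("x", "y", "z")])
      ctr <- colMeans(xyz)
      r <- sqrt(max(rowSums(sweep(xyz, 2, ctr)^2)))
      if (r > rad[ty]) rad[ty] <- r
    }
  }
  ## fallback for unseen types: extended side chain from the topology
  for (ty in names(rad)[rad == 0]) rad[ty] <- topology_radius(ty)
  pmin(pmax(rad, 1.01), 7.99)
}

topology_radius <- function(residue_type) {
  n <- c(0, 0, 0); ca <- c(1.458, 0, 0)
  cc <- place_atom(c(0, 0, 1), n, ca, bond_geometry(1.525, 111.2), 0)
  o <- place_atom(n, ca, cc, bond_geometry(1.231, 120.8), 45)
  m <- rbind(n, ca, cc, o)
  sc <- build_side_chain(residue_type, n, ca, cc,
                         rep(180, max(1L, chi_count(residue_type))))
  if (nrow(sc)) m <- rbind(m, sc)
  ctr <- colMeans(m)
  sqrt(max(rowSums(sweep(m, 2, ctr)^2)))
}

#' Residue-residue distance cutoff
#'
#' `r_i + r_j + c`: two residues can only contribute interacting atom pairs
#' when their geometric centers are within the sum of their effective radii
#' plus the interaction constant `c`.
#'
#' @param type_i,type_j Three-letter residue codes.
#' @param table Named radius vector from [residue_radius_table()].
#' @param c Interaction constant in Angstrom (default 8, at least the
#'   potential range).
#' @return Cutoff distance in Angstrom; symmetric in the two types.
#' @export
residue_cutoff <- function(type_i, type_j, table, c = 8) {
  if (!all(c(type_i, type_j) %in% names(table)))
    stop("residue type missing from the radius table", call. = FALSE)
  unname(table[type_i] + table[type_j] + c)
}

#' Build the enlarged loop ellipsoid
#'
#' Foci are the two fixed anchor atoms flanking the loop. The base
#' sum-of-distances threshold is `L`, the sum of the loop's backbone bond
#' lengths along the anchor-to-anchor path; the semi-axes are enlarged by
#' `s_max + d_cut` (maximum side-chain extension plus interaction cutoff),
#' giving the membership threshold `L + 2 (s_max + d_cut)`.
#'
#' @param f1,f2 Coordinates of the two anchor atoms.
#' @param bond_lengths Backbone bond lengths of the loop path (Angstrom).
#' @param s_max Maximum side-chain length; default from the geometry table.
#' @param d_cut Interaction distance cutoff (default 8, the potential range).
#' @return An object of class `lg_ellipsoid` with fields `f1`, `f2`, `L`,
#'   `threshold`, semi-axes `a`, `b`.
#' @export
build_ellipsoid <- function(f1, f2, bond_lengths, s_max = max_sidechain_length(),
                            d_cut = 8) {
  L <- sum(bond_lengths)
  threshold <- L + 2 * (s_max + d_cut)
  f12 <- vnorm(f2 - f1)
  if (f12 >= threshold)
    stop("infeasible anchors: focal separation ", round(f12, 2),
         " exceeds the ellipsoid threshold ", round(threshold, 2), call. = FALSE)
  a <- threshold / 2
  b <- sqrt(max(a^2 - (f12 / 2)^2, 0))
  structure(list(f1 = f1, f2 = f2, L = L, s_max = s_max, d_cut = d_cut,
                 threshold = threshold, a = a, b = b),
            class = "lg_ellipsoid")
}

#' Ellipsoid membership test
#'
#' @param points Length-3 vector or `n x 3` matrix.
#' @param ellipsoid An `lg_ellipsoid`.
#' @return Logical vector: TRUE when the sum of distances to the foci is
#'   strictly below the threshold.
#' @export
in_ellipsoid <- function(points, ellipsoid) {
  m <- matrix(points, ncol = 3)
  d1 <- sqrt(rowSums(sweep(m, 2, ellipsoid$f1)^2))
  d2 <- sqrt(rowSums(sweep(m, 2, ellipsoid$f2)^2))
  d1 + d2 < ellipsoid$threshold
}

#' Growth-pruning test
#'
#' A placed atom outside the enlarged ellipsoid can never belong to a closed
#' loop conformation, so the growth attempt is aborted. Boundary tangency
#' aborts (strict inequality keeps).
#'
#' @param point Length-3 coordinates.
#' @param ellipsoid An `lg_ellipsoid`.
#' @return TRUE to keep growing, FALSE to abort.
#' @export
prune_growth <- function(point, ellipsoid) {
  as.logical(in_ellipsoid(point, ellipsoid))
}

#' Precompute the environment atom set for a loop target
#'
#' Retains an atom when it lies inside the enlarged ellipsoid, or when its
#' residue's geometric center passes the residue cutoff against either
#' anchor (anchors bound the positions of the yet-unsampled loop residues).
#' The ellipsoid term alone already guarantees that filtered energies equal
#' unfiltered energies; the cutoff term only ever adds atoms. Computed once
#' per loop target and reused for every conformation.
#'
#' @param structure An `lg_structure`.
#' @param loop Loop region list with `chain`, `start`, `end`.
#' @param ellipsoid An `lg_ellipsoid` for the loop.
#' @param radius_table Named radii from [residue_radius_table()].
#' @param c Residue-cutoff constant (default 8).
#' @return A list with `arrays` (energy arrays of the retained atoms),
#'   `chains`, and `n_atoms`.
#' @export
environment_atoms <- function(structure, loop, ellipsoid, radius_table,
                              c = 8) {
  at <- structure$atoms
  in_loop <- at$chain == loop$chain & at$resno >= loop$start &
    at$resno <= loop$end
  at <- at[!in_loop, , drop = FALSE]
  chains <- sort(unique(structure$atoms$chain))
  keep_atom <- in_ellipsoid(as.matrix(at[, c("x", "y", "z")]), ellipsoid)
  ## residue-cutoff term against the anchors
  r_loop <- max(radius_table)
  key <- paste(at$chain, at$resno, at$insert)
  for (grp in split(seq_len(nrow(at)), key)) {
    if (all(keep_atom[grp])) next
    ty <- at$resid[grp[1]]
    xyz <- as.matrix(at[grp, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    cut <- radius_table[ty] + r_loop + c
    if (vnorm(ctr - ellipsoid$f1) <= cut || vnorm(ctr - ellipsoid$f2) <= cut)
      keep_atom[grp] <- TRUE
  }
  kept <- at[keep_atom, , drop = FALSE]
  list(arrays = energy_arrays(kept, chains = chains), chains = chains,
       n_atoms = nrow(kept), atoms = kept)
}
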