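# Loop-specific atom-pair distance-dependent statistical potential: a
# 20-class atom typing (4 backbone + 16 side-chain classes), a binned
# distance range with a single sub-contact bin, observed counts from native
# loops, expected counts from geometry-only decoy loops, and the log-ratio
# energy E = -ln[(n_obs/N_obs) / (n_exp/N_exp)] with capped sparse cells and
# a constant clash energy in the sub-contact bin.

## 20 atom classes: 1..4 backbone N, CA, C, O; 5..10 carbon classes
## (CH3, CH2, CH1, aromatic, amide/guanidinium, carboxylate); 11..16 nitrogen
## classes (amide, protonated ring, ring, Lys, Arg, Pro backbone N);
## 17..19 oxygen classes (hydroxyl, amide, carboxylate); 20 sulfur.
.type_names <- c("N_bb", "CA_bb", "C_bb", "O_bb",
                 "C_ali3", "C_ali2", "C_ali1", "C_aro", "C_amide", "C_carboxyl",
                 "N_amide", "N_aroH", "N_aro", "N_lys", "N_arg", "N_pro",
                 "O_hydroxyl", "O_amide", "O_carboxyl", "S")

.sidechain_classes <- list(
  C_ali3 = c("ALA:CB", "VAL:CG1", "VAL:CG2", "LEU:CD1", "LEU:CD2", "ILE:CG2",
             "ILE:CD1", "THR:CG2", "MET:CE"),
  C_ali2 = c("ARG:CB", "ARG:CG", "ARG:CD", "ASN:CB", "ASP:CB", "CYS:CB",
             "GLN:CB", "GLN:CG", "GLU:CB", "GLU:CG", "HIS:CB", "ILE:CG1",
             "LEU:CB", "LYS:CB", "LYS:CG", "LYS:CD", "LYS:CE", "MET:CB",
             "MET:CG", "PHE:CB", "PRO:CB", "PRO:CG", "PRO:CD", "SER:CB",
             "TRP:CB", "TYR:CB"),
  C_ali1 = c("VAL:CB", "ILE:CB", "LEU:CG", "THR:CB"),
  C_aro = c("PHE:CG", "PHE:CD1", "PHE:CD2", "PHE:CE1", "PHE:CE2", "PHE:CZ",
            "TYR:CG", "TYR:CD1", "TYR:CD2", "TYR:CE1", "TYR:CE2", "TYR:CZ",
            "TRP:CG", "TRP:CD1", "TRP:CD2", "TRP:CE2", "TRP:CE3", "TRP:CZ2",
            "TRP:CZ3", "TRP:CH2", "HIS:CG", "HIS:CD2", "HIS:CE1"),
  C_amide = c("ASN:CG", "GLN:CD", "ARG:CZ"),
  C_carboxyl = c("ASP:CG", "GLU:CD"),
  N_amide = c("ASN:ND2", "GLN:NE2"),
  N_aroH = c("TRP:NE1", "HIS:ND1"),
  N_aro = c("HIS:NE2"),
  N_lys = c("LYS:NZ"),
  N_arg = c("ARG:NE", "ARG:NH1", "ARG:NH2"),
  O_hydroxyl = c("SER:OG", "THR:OG1", "TYR:OH"),
  O_amide = c("ASN:OD1", "GLN:OE1"),
  O_carboxyl = c("ASP:OD1", "ASP:OD2", "GLU:OE1", "GLU:OE2"),
  S = c("CYS:SG", "MET:SD")
)

.type_env <- new.env(parent = emptyenv())

type_lookup <- function() {
  if (is.null(.type_env$map)) {
    map <- new.env(parent = emptyenv(), size = 512L)
    for (cls in names(.sidechain_classes)) {
      id <- match(cls, .type_names)
      for (key in .sidechain_classes[[cls]]) assign(key, id, envir = map)
    }
    .type_env$map <- map
  }
  .type_env$map
}

#' The 20-class atom-type scheme
#'
#' @return A list with `n_types`, the class `names`, and the side-chain
#'   class membership lists.
#' @export
atom_type_scheme <- function() {
  list(n_types = 20L, names = .type_names, sidechain = .sidechain_classes)
}

#' Assign the atom-type id of a heavy atom
#'
#' Backbone N, CA, C, O map to the four backbone ids (proline's backbone N
#' maps to the dedicated Pro-N class); all side-chain heavy atoms map to one
#' of 16 classes partitioned into 6 carbon, 6 nitrogen, 3 oxygen and 1
#' sulfur types. `OXT` is treated as backbone O.
#'
#' @param residue_type Three-letter code(s).
#' @param atom_name PDB atom name(s).
#' @return Integer type id(s) in 1..20.
#' @export
assign_atom_type <- function(residue_type, atom_name) {
  k <- max(length(residue_type), length(atom_name))
  residue_type <- rep_len(residue_type, k)
  atom_name <- rep_len(atom_name, k)
  out <- integer(k)
  bb <- match(atom_name, c("N", "CA", "C", "O", "OXT"))
  bb[!is.na(bb) & bb == 5L] <- 4L
  out[!is.na(bb)] <- bb[!is.na(bb)]
  out[atom_name == "N" & residue_type == "PRO"] <- 16L
  map <- type_lookup()
  for (i in which(is.na(bb))) {
    id <- map[[paste0(residue_type[i], ":", atom_name[i])]]
    if (is.null(id))
      stop("cannot type atom ", atom_name[i], " of ", residue_type[i],
           call. = FALSE)
    out[i] <- id
  }
  out
}

## ---- distance bins ---------------------------------------------------------

#' Distance bin scheme of the pair potential
#'
#' One sub-contact bin `[0, r_lo)` (always assigned the clash energy),
#' uniform bins of width `w` from `r_lo` to `r_hi`, no interaction beyond
#' `r_hi`.
#'
#' @param r_lo,r_hi Short-range and interaction cutoffs in Angstrom.
#' @param w Bin width in Angstrom.
#' @return An object of class `lg_binspec` with `n_bins` total bins.
#' @export
bin_spec <- function(r_lo = 2.0, r_hi = 8.0, w = 0.2) {
  stopifnot(r_lo < r_hi, w > 0)
  n <- as.integer(round((r_hi - r_lo) / w))
  if (abs(n * w - (r_hi - r_lo)) > 1e-9)
    stop("bin width must divide r_hi - r_lo", call. = FALSE)
  structure(list(r_lo = r_lo, r_hi = r_hi, w = w, n_bins = n + 1L),
            class = "lg_binspec")
}

#' Distance-to-bin mapping
#'
#' Half-open convention: `[0, r_lo)` is bin 1 (sub-contact); `[r_lo + k w,
#' r_lo + (k+1) w)` is bin `k + 2`; distances at or beyond `r_hi` return
#' `NA` (no interaction).
#'
#' @param distance Numeric vector of distances (>= 0).
#' @param spec An `lg_binspec`.
#' @return Integer bin indices (1-based) or `NA`.
#' @export
bin_of <- function(distance, spec) {
  out <- rep(NA_integer_, length(distance))
  out[distance < spec$r_lo] <- 1L
  mid <- distance >= spec$r_lo & distance < spec$r_hi
  out[mid] <- 2L + as.integer(floor((distance[mid] - spec$r_lo) / spec$w))
  out[out > spec$n_bins & !is.na(out)] <- spec$n_bins  # guard fp edge
  out
}

## ---- energy-array representation of atom sets ------------------------------

## Flat arrays for fast pair evaluation: coordinates, type id, a global
## residue serial (chain-aware), and a backbone code (1 N, 2 CA, 3 C, 4 O,
## 0 side chain) used by the bonded-neighbour exclusion rules.
energy_arrays <- function(df, chains = NULL) {
  if (is.null(chains)) chains <- sort(unique(df$chain))
  bb <- match(df$elety, c("N", "CA", "C", "O"))
  bb[is.na(bb)] <- 0L
  list(xyz = as.matrix(df[, c("x", "y", "z")]),
       type = assign_atom_type(df$resid, df$elety),
       res = match(df$chain, chains) * 100000L + df$resno,
       bb = bb,
       resid = df$resid, elety = df$elety, chains = chains)
}

## exclusion tables for residues (i, i+1): pairs within 1-2/1-3 of the
## peptide bond; rows = bb code of the earlier residue's atom (+1), cols =
## later residue's atom (+1)
.excl_fwd <- {
  m <- matrix(FALSE, 5, 5)
  m[3 + 1, 1 + 1] <- TRUE  # C  - N   (1-2)
  m[3 + 1, 2 + 1] <- TRUE  # C  - CA  (1-3)
  m[2 + 1, 1 + 1] <- TRUE  # CA - N   (1-3)
  m[4 + 1, 1 + 1] <- TRUE  # O  - N   (1-3)
  m
}

## Energy (or count) contribution of atom i of set A against every atom of
## set B. Shared kernel of score_loop / fragment_energy / pair counting.
pair_kernel <- function(ai_xyz, ai_type, ai_res, ai_bb, B, pot, spec,
                        counts = NULL) {
  d2 <- (B$xyz[, 1] - ai_xyz[1])^2 + (B$xyz[, 2] - ai_xyz[2])^2 +
    (B$xyz[, 3] - ai_xyz[3])^2
  sel <- d2 < spec$r_hi^2
  if (!any(sel)) return(if (is.null(counts)) 0 else counts)
  keep <- which(sel)
  bres <- B$res[keep]
  excl <- bres == ai_res
  fwd <- bres == ai_res + 1L
  if (any(fwd)) excl[fwd] <- excl[fwd] | .excl_fwd[cbind(ai_bb + 1L, B$bb[keep][fwd] + 1L)]
  bwd <- bres == ai_res - 1L
  if (any(bwd)) excl[bwd] <- excl[bwd] | .excl_fwd[cbind(B$bb[keep][bwd] + 1L, ai_bb + 1L)]
  keep <- keep[!excl]
  if (!length(keep)) return(if (is.null(counts)) 0 else counts)
  bins <- bin_of(sqrt(d2[keep]), spec)
  t1 <- pmin(ai_type, B$type[keep]); t2 <- pmax(ai_type, B$type[keep])
  if (is.null(counts)) return(sum(pot$E[cbind(t1, t2, bins)]))
  idx <- t1 + 20L * (t2 - 1L) + 400L * (bins - 1L)
  tab <- tabulate(idx, nbins = 400L * spec$n_bins)
  counts + array(tab, dim = c(20, 20, spec$n_bins))
}

## All-pairs evaluation: A x B plus (optionally) unordered pairs within A.
## The energy path goes through the compiled kernel; counting (used once
## per fit) and the R reference path stay in R.
pairs_eval <- function(A, B, pot, spec, within_A = TRUE, counts = FALSE) {
  if (!counts) {
    empty <- list(xyz = matrix(numeric(), 0, 3), type = integer(),
                  res = integer(), bb = integer())
    BB <- if (!is.null(B) && nrow(B$xyz) > 0) B else empty
    return(.pair_energy_cpp(A$xyz, as.integer(A$type), as.integer(A$res),
                            as.integer(A$bb), BB$xyz, as.integer(BB$type),
                            as.integer(BB$res), as.integer(BB$bb),
                            as.numeric(pot$E), spec$r_lo, spec$r_hi, spec$w,
                            spec$n_bins, isTRUE(within_A)))
  }
  pairs_eval_r(A, B, pot, spec, within_A, counts)
}

## pure-R reference implementation (also the counting path)
pairs_eval_r <- function(A, B, pot, spec, within_A = TRUE, counts = FALSE) {
  acc <- if (counts) array(0, dim = c(20, 20, spec$n_bins)) else 0
  nA <- nrow(A$xyz)
  if (!is.null(B) && nrow(B$xyz) > 0) {
    for (i in seq_len(nA)) {
      r <- pair_kernel(A$xyz[i, ], A$type[i], A$res[i], A$bb[i], B, pot, spec,
                       if (counts) acc * 0 else NULL)
      acc <- acc + r
    }
  }
  if (within_A && nA > 1) {
    for (i in seq_len(nA - 1L)) {
      tailB <- list(xyz = A$xyz[(i + 1L):nA, , drop = FALSE],
                    type = A$type[(i + 1L):nA], res = A$res[(i + 1L):nA],
                    bb = A$bb[(i + 1L):nA])
      r <- pair_kernel(A$xyz[i, ], A$type[i], A$res[i], A$bb[i], tailB, pot,
                       spec, if (counts) acc * 0 else NULL)
      acc <- acc + r
    }
  }
  acc
}


## ---- observed / expected counts -------------------------------------------

#' Count observed atom pairs in the loop database
#'
#' For every loop, counts unordered heavy-atom pairs with at least one atom
#' in the loop region and distance below `r_hi`, excluding pairs within one
#' residue and 1-2/1-3 pairs across the peptide bond. Loop-loop pairs are
#' counted once.
#'
#' @param db An `lg_loopdb`.
#' @param spec An `lg_binspec`.
#' @return A list with the count array `n` (`20 x 20 x n_bins`, upper-triangle
#'   type storage) and the normalizer `N` (total count).
#' @export
count_observed <- function(db, spec = bin_spec()) {
  acc <- array(0, dim = c(20, 20, spec$n_bins))
  for (rec in db$loops) {
    st <- db$structures[[rec$structure_index]]
    sets <- split_loop_environment(st, rec$chain, rec$start, rec$end)
    acc <- acc + pairs_eval(sets$loop, sets$other, NULL, spec, counts = TRUE)
  }
  list(n = acc, N = sum(acc))
}

#' Count expected atom pairs from decoy ensembles
#'
#' Per loop, averages the pair-count array over that loop's decoys
#' (geometry-only conformations), then sums over loops. Loops with no decoys
#' are dropped with a warning.
#'
#' @param db An `lg_loopdb`.
#' @param decoys List parallel to `db$loops`; each element a list of decoy
#'   conformations (atom data frames with `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z`).
#' @param spec An `lg_binspec`.
#' @return A list with the count array `n` and the normalizer `N`.
#' @export
count_expected <- function(db, decoys, spec = bin_spec()) {
  acc <- array(0, dim = c(20, 20, spec$n_bins))
  for (li in seq_along(db$loops)) {
    dec <- decoys[[li]]
    if (is.null(dec) || length(dec) == 0) {
      warning("loop ", li, " has no decoys; excluded from the reference state")
      next
    }
    rec <- db$loops[[li]]
    st <- db$structures[[rec$structure_index]]
    sets <- split_loop_environment(st, rec$chain, rec$start, rec$end)
    loop_acc <- array(0, dim = c(20, 20, spec$n_bins))
    for (cf in dec) {
      A <- energy_arrays(conformation_atoms(cf), chains = sets$chains)
      loop_acc <- loop_acc + pairs_eval(A, sets$other, NULL, spec, counts = TRUE)
    }
    acc <- acc + loop_acc / length(dec)
  }
  list(n = acc, N = sum(acc))
}

## split a structure into loop-region arrays and everything-else arrays
split_loop_environment <- function(structure, chain, start, end) {
  at <- structure$atoms
  in_loop <- at$chain == chain & at$resno >= start & at$resno <= end
  chains <- sort(unique(at$chain))
  list(loop = energy_arrays(at[in_loop, , drop = FALSE], chains),
       other = energy_arrays(at[!in_loop, , drop = FALSE], chains),
       chains = chains)
}

## accept lg_conformation or plain atom data frame
conformation_atoms <- function(x) {
  if (is.data.frame(x)) x else x$atoms
}

#' Build the pair potential from observed and expected counts
#'
#' `E(i, j, bin) = -ln[(n_obs/N_obs) / (n_exp/N_exp)]`. Cells with zero
#' observed or expected count receive the cap energy; the sub-contact bin is
#' the constant clash energy regardless of counts. The table is symmetric
#' under type swap.
#'
#' @param obs,exp Lists from [count_observed()] / [count_expected()].
#' @param spec The `lg_binspec` both were counted on.
#' @param cap Energy for zero-count cells (default +3).
#' @param clash Sub-contact clash energy per pair (default +10).
#' @return An object of class `lg_potential`.
#' @export
build_potential <- function(obs, exp, spec = bin_spec(), cap = 3, clash = 10) {
  if (obs$N <= 0 || exp$N <= 0)
    stop("cannot build a potential from all-zero counts", call. = FALSE)
  E <- array(cap, dim = dim(obs$n))
  pos <- obs$n > 0 & exp$n > 0
  E[pos] <- -log((obs$n[pos] / obs$N) / (exp$n[pos] / exp$N))
  E[, , 1] <- clash
  ## symmetrize (counts are stored on ordered type pairs)
  for (b in seq_len(dim(E)[3])) {
    Eb <- E[, , b]
    low <- lower.tri(Eb)
    Eb[low] <- t(Eb)[low]
    E[, , b] <- Eb
  }
  structure(list(E = E, n_obs = obs$n, n_exp = exp$n, N_obs = obs$N,
                 N_exp = exp$N, spec = spec, cap = cap, clash = clash),
            class = "lg_potential")
}

#' Export the potential as a readable table
#'
#' @param potential An `lg_potential`.
#' @param path Optional TSV output path.
#' @return Data frame with one row per (type_i <= type_j, bin) cell.
#' @export
potential_table <- function(potential, path = NULL) {
  spec <- potential$spec
  lo <- c(0, spec$r_lo + spec$w * (seq_len(spec$n_bins - 1L) - 1L))
  hi <- c(spec$r_lo, spec$r_lo + spec$w * seq_len(spec$n_bins - 1L))
  idx <- which(upper.tri(matrix(0, 20, 20), diag = TRUE), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(spec$n_bins), function(b) {
    data.frame(type_i = .type_names[idx[, 1]], type_j = .type_names[idx[, 2]],
               bin_lo = lo[b], bin_hi = hi[b],
               n_obs = potential$n_obs[cbind(idx[, 1], idx[, 2], b)],
               n_exp = potential$n_exp[cbind(idx[, 1], idx[, 2], b)],
               E = potential$E[cbind(idx[, 1], idx[, 2], b)])
  }))
  if (!is.null(path))
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rows
}

## ---- scoring ---------------------------------------------------------------

#' Total potential energy of a loop conformation
#'
#' Sum of pair energies over unordered heavy-atom pairs with at least one
#' atom in the loop, distance below `r_hi`, with the same-residue and
#' peptide-bond 1-2/1-3 exclusions. The environment may be the full
#' structure minus the loop, or a precomputed Redcell environment (the two
#' give identical energies by construction of the enlarged ellipsoid).
#'
#' @param conformation An `lg_conformation` or atom data frame of the loop.
#' @param structure The `lg_structure` (used when `environment` is NULL).
#' @param potential An `lg_potential`.
#' @param environment Optional environment arrays from [environment_atoms()].
#' @param loop Loop region list (`chain`, `start`, `end`); required when
#'   `environment` is NULL.
#' @return Total energy (dimensionless).
#' @export
score_loop <- function(conformation, structure, potential, environment = NULL,
                       loop = NULL) {
  df <- conformation_atoms(conformation)
  if (is.null(environment)) {
    if (is.null(loop)) stop("either environment or loop must be given", call. = FALSE)
    sets <- split_loop_environment(structure, loop$chain, loop$start, loop$end)
    env <- sets$other
    chains <- sets$chains
  } else {
    env <- environment$arrays
    chains <- environment$chains
  }
  A <- energy_arrays(df, chains = chains)
  pairs_eval(A, env, potential, potential$spec, within_A = TRUE)
}

#' Interaction energy of a newly placed fragment
#'
#' Pairwise energy between the new atoms (a backbone fragment of up to four
#' atoms, or a side chain) and the context (fixed protein environment plus
#' previously grown loop atoms), plus unordered pairs among the new atoms.
#' Summing fragment energies over all growth steps and closure telescopes to
#' [score_loop()] of the finished loop exactly, because every unordered pair
#' is counted exactly once, when its later atom appears.
#'
#' @param new Arrays (from internal growth state) or an atom data frame of
#'   the new atoms.
#' @param context List of array sets to score against (each with `xyz`,
#'   `type`, `res`, `bb`); NULL entries are skipped.
#' @param potential An `lg_potential`.
#' @return Fragment energy.
#' @export
fragment_energy <- function(new, context, potential) {
  A <- if (is.data.frame(new)) energy_arrays(new) else new
  e <- pairs_eval(A, NULL, potential, potential$spec, within_A = TRUE)
  for (B in context) {
    if (is.null(B) || nrow(B$xyz) == 0) next
    e <- e + pairs_eval(A, B, potential, potential$spec, within_A = FALSE)
  }
  e
}
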