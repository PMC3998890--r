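# Shared fixtures built in code. The small bundle is reused by every test
# file that needs fitted models; built once when the helper is sourced.

## ideal backbone chain from explicit (phi, psi); returns coordinate lists
build_ideal_chain <- function(types, phi, psi) {
  n <- length(types)
  N <- CA <- C <- O <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(backbone_geometry(types[1], "b_NCA"), 0, 0)
  C[[1]] <- place_atom(c(0, 1, 0), N[[1]], CA[[1]],
                       bond_geometry(backbone_geometry(types[1], "b_CAC"),
                                     backbone_geometry(types[1], "a_NCAC")),
                       phi[1])
  for (i in seq_len(n)[-1]) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         bond_geometry(backbone_geometry(types[i - 1], "b_CN"),
                                       backbone_geometry(types[i - 1], "a_CACN")),
                         psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          bond_geometry(backbone_geometry(types[i], "b_NCA"),
                                        backbone_geometry(types[i], "a_CNCA")),
                          180)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                         bond_geometry(backbone_geometry(types[i], "b_CAC"),
                                       backbone_geometry(types[i], "a_NCAC")),
                         phi[i])
  }
  for (i in seq_len(n))
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         bond_geometry(backbone_geometry(types[i], "b_CO"),
                                       backbone_geometry(types[i], "a_CACO")),
                         wrap_angle(psi[i] + 180))
  list(N = N, CA = CA, C = C, O = O, types = types, phi = phi, psi = psi)
}

## closure problem cut from an ideal chain: residues (j, j+1, j+2) with
## anchors j-1 and j+3
chain_closure_problem <- function(ch, j) {
  closure_problem(ch$C[[j - 1]], ch$N[[j]], ch$CA[[j]],
                  ch$N[[j + 3]], ch$CA[[j + 3]], ch$C[[j + 3]],
                  ch$types[j:(j + 2)], ch$types[j + 3],
                  phi_post = measure_dihedral(ch$C[[j + 2]], ch$N[[j + 3]],
                                              ch$CA[[j + 3]], ch$C[[j + 3]]))
}

native_tripeptide <- function(ch, j) {
  rbind(ch$C[[j]], ch$N[[j + 1]], ch$CA[[j + 1]], ch$C[[j + 1]],
        ch$N[[j + 2]], ch$CA[[j + 2]], ch$C[[j + 2]])
}

closure_best_rmsd <- function(sols, native) {
  nm <- c("C1", "N2", "CA2", "C2", "N3", "CA3", "C3")
  best <- Inf
  for (s in sols)
    best <- min(best, sqrt(mean(rowSums((s$atoms[nm, ] - native)^2))))
  best
}

## brute-force KDE oracle: explicit kernel sum at one point
kde_brute <- function(xw, yw, h, px, py) {
  mean(exp(-0.5 * ((px - xw) / h[1])^2 - 0.5 * ((py - yw) / h[2])^2)) /
    (2 * pi * h[1] * h[2])
}

## brute-force O(n^2) loop energy oracle, independent of pair_kernel
brute_score <- function(loop_atoms, other_atoms, potential) {
  all_at <- rbind(loop_atoms[, c("chain", "resno", "insert", "resid", "elety",
                                 "x", "y", "z")],
                  other_atoms[, c("chain", "resno", "insert", "resid", "elety",
                                  "x", "y", "z")])
  n_loop <- nrow(loop_atoms)
  chains <- sort(unique(all_at$chain))
  res <- match(all_at$chain, chains) * 100000L + all_at$resno
  bb <- match(all_at$elety, c("N", "CA", "C", "O"))
  bb[is.na(bb)] <- 0L
  ty <- assign_atom_type(all_at$resid, all_at$elety)
  spec <- potential$spec
  excl_set <- list(c(3L, 1L), c(3L, 2L), c(2L, 1L), c(4L, 1L))
  total <- 0
  for (i in seq_len(nrow(all_at) - 1L)) {
    for (j in (i + 1L):nrow(all_at)) {
      if (i > n_loop && j > n_loop) next
      if (res[i] == res[j]) next
      lo <- if (res[i] < res[j]) i else j
      hi_ <- if (res[i] < res[j]) j else i
      if (abs(res[i] - res[j]) == 1L) {
        pair <- list(c(bb[lo], bb[hi_]))
        if (any(vapply(excl_set, function(e) identical(e, c(bb[lo], bb[hi_])),
                       TRUE))) next
      }
      d <- sqrt((all_at$x[i] - all_at$x[j])^2 + (all_at$y[i] - all_at$y[j])^2 +
                  (all_at$z[i] - all_at$z[j])^2)
      if (d >= spec$r_hi) next
      b <- bin_of(d, spec)
      total <- total + potential$E[min(ty[i], ty[j]), max(ty[i], ty[j]), b]
    }
  }
  total
}

## shared corpus + fitted bundle, built once per test run and reused by the
## module tests and the end-to-end checks (40 structures, fixed seed)
lg_test_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ## the occasional loop without decoys is expected at this corpus size
      corpus <- suppressWarnings(
        make_corpus(n_structures = 40, seed = 42, n_decoys = 5))
      cache <<- corpus
    }
    cache
  }
})

## a small held-out loop target shared across sampler tests
lg_test_target <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- make_protein("HHHHHHCCCCHHHHHH", seed = 424, id = "t4")
      cache <<- make_loop_target(fx$structure, "A", 7, 10)
    }
    cache
  }
})
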