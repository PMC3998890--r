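# Loop database construction: identify loop regions from secondary-structure
# assignments, walk each loop in growth order to collect the (d_prev, d_new)
# anchor-distance pairs for both placement models, and record backbone and
# side-chain dihedrals per residue type. Everything downstream (distance
# KDEs, dihedral tables, the pair potential) is fitted from this database.

#' Identify loop regions from a secondary-structure assignment
#'
#' Takes a per-residue H/E/C assignment and returns the maximal coil runs.
#' Short helices and strands (length at most `short_element`) are first
#' relabeled as coil and merged into adjoining coil, mirroring the practice
#' of treating all irregular regions, including short regular elements, as
#' loop. Regions must have complete backbone (N, CA, C, O) in every residue
#' and are filtered to `min_len`..`max_len`.
#'
#' @param structure An `lg_structure`.
#' @param assignment Data frame with columns `chain`, `resno`, `label`
#'   (values in H/E/C), covering the chain's residues.
#' @param min_len,max_len Length bounds on reported regions.
#' @param short_element Maximum length of an H/E run still counted as loop.
#' @return Data frame with columns `chain`, `start`, `end`, `length`.
#' @export
identify_loops <- function(structure, assignment, min_len = 4, max_len = 12,
                           short_element = 4) {
  out <- list()
  for (ch in unique(assignment$chain)) {
    res <- chain_residues(structure, ch)
    asn <- assignment[assignment$chain == ch, , drop = FALSE]
    lab <- asn$label[match(res$resno, asn$resno)]
    if (anyNA(lab))
      stop("assignment does not cover all residues of chain ", ch, call. = FALSE)
    r <- rle(lab)
    r$values[r$values %in% c("H", "E") & r$lengths <= short_element] <- "C"
    lab <- inverse.rle(r)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values == "C")) {
      len <- r$lengths[j]
      if (len < min_len || len > max_len) next
      rs <- res$resno[starts[j]]; re <- res$resno[ends[j]]
      ok <- all(vapply(res$resno[starts[j]:ends[j]],
                       function(rn) backbone_complete(structure, ch, rn),
                       logical(1)))
      if (!ok) next
      out[[length(out) + 1L]] <- data.frame(chain = ch, start = rs, end = re,
                                            length = len)
    }
  }
  if (length(out) == 0)
    return(data.frame(chain = character(), start = integer(), end = integer(),
                      length = integer()))
  do.call(rbind, out)
}

## chi-defining atom quadruples of a residue type, from the topology
chi_atom_quads <- function(residue_type) {
  topo <- sidechain_topology(residue_type)
  nch <- chi_count(residue_type)
  if (nch == 0L) return(list())
  lapply(seq_len(nch), function(k) {
    at <- Filter(function(a) !is.na(a$chi) && a$chi == k && a$offset == 0, topo)[[1]]
    c(at$frame, at$name)
  })
}

## measure chi vector of a residue; NA entries when atoms are missing
measure_chis <- function(structure, chain, resno, residue_type) {
  quads <- chi_atom_quads(residue_type)
  vapply(quads, function(q) {
    pts <- lapply(q, function(nm) residue_atom(structure, chain, resno, nm))
    if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
    tryCatch(measure_dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
             error = function(e) NA_real_)
  }, numeric(1))
}

## Walk a single loop in N-to-C growth order; returns per-residue dihedrals
## and the (d_prev, d_new) pairs of both placement models keyed by g, or NULL
## when the loop (or its anchors) is unusable.
extract_loop_record <- function(structure, chain, start, end) {
  res <- chain_residues(structure, chain)
  i0 <- match(start, res$resno); i1 <- match(end, res$resno)
  if (is.na(i0) || is.na(i1)) return(NULL)
  if (i0 <= 1 || i1 >= nrow(res)) return(NULL)  # need anchors on both sides
  pre <- res$resno[i0 - 1]; post <- res$resno[i1 + 1]
  anchor <- residue_atom(structure, chain, post, "N")
  c_pre <- residue_atom(structure, chain, pre, "C")
  if (is.null(anchor) || is.null(c_pre)) return(NULL)
  L <- i1 - i0 + 1L
  resnos <- res$resno[i0:i1]
  types <- res$resid[i0:i1]
  get <- function(rn, nm) residue_atom(structure, chain, rn, nm)
  dih <- data.frame(resno = resnos, resid = types,
                    phi = NA_real_, psi = NA_real_, omega = NA_real_)
  pairs_ca <- vector("list", L); pairs_c <- vector("list", L)
  chis <- vector("list", L)
  for (i in seq_len(L)) {
    rn <- resnos[i]
    n <- get(rn, "N"); ca <- get(rn, "CA"); cc <- get(rn, "C")
    if (is.null(n) || is.null(ca) || is.null(cc)) return(NULL)
    prevC <- if (i == 1) c_pre else get(resnos[i - 1], "C")
    nextN <- if (i == L) anchor else get(resnos[i + 1], "N")
    dih$phi[i] <- measure_dihedral(prevC, n, ca, cc)
    if (!is.null(nextN)) dih$psi[i] <- measure_dihedral(n, ca, cc, nextN)
    if (i < L) {
      nextCA <- get(resnos[i + 1], "CA")
      if (!is.null(nextCA))
        dih$omega[i] <- measure_dihedral(ca, cc, nextN, nextCA)
    }
    g <- L - i + 1L
    pairs_ca[[i]] <- c(g = g, d_prev = vnorm(prevC - anchor),
                       d_new = vnorm(ca - anchor))
    pairs_c[[i]] <- c(g = g, d_prev = vnorm(ca - anchor),
                      d_new = vnorm(cc - anchor))
    chis[[i]] <- list(resid = types[i],
                      chi = measure_chis(structure, chain, rn, types[i]))
  }
  list(chain = chain, start = start, end = end, length = L,
       sequence = types, dihedrals = dih,
       pairs_ca = do.call(rbind, pairs_ca), pairs_c = do.call(rbind, pairs_c),
       chis = chis)
}

#' Build the loop database from structures and assignments
#'
#' Identifies loop regions in every structure, walks each loop in growth
#' order and collects: anchor-distance pairs `(d_prev, d_new)` per residue
#' separation `g` for both placement models (placing C conditional on the CA
#' distance, and placing the next CA conditional on the C distance), backbone
#' dihedral pairs per residue type, and side-chain chi vectors per residue
#' type. The anchor atom for all distances is the first fixed backbone atom
#' after the loop: the N of the residue following it. The output is
#' independent of input order up to ordering of the collected sets (pair sets
#' are sorted before fitting).
#'
#' @param structures List of `lg_structure` objects.
#' @param assignments List of assignment data frames, parallel to
#'   `structures`.
#' @param min_len,max_len,short_element Passed to [identify_loops()].
#' @param exclude_ids Optional character vector of structure ids to skip.
#' @return An object of class `lg_loopdb` with elements `pairs` (per model,
#'   per g, sorted two-column matrices), `dihedrals` (per residue type,
#'   phi/psi matrix), `chis` (per residue type, list of chi vectors), `loops`
#'   (manifest data frame), and `structures` (the inputs, retained for pair
#'   counting by the potential).
#' @export
build_loop_db <- function(structures, assignments, min_len = 4, max_len = 12,
                          short_element = 4, exclude_ids = NULL) {
  stopifnot(length(structures) >= 1, length(structures) == length(assignments))
  pairs <- list(ca = list(), c = list())
  dihedrals <- list(); chis <- list()
  manifest <- list(); records <- list()
  skipped <- character()
  for (s in seq_along(structures)) {
    st <- structures[[s]]
    if (!is.null(exclude_ids) && !is.na(st$id) && st$id %in% exclude_ids) next
    regions <- identify_loops(st, assignments[[s]], min_len, max_len,
                              short_element)
    nl <- 0L
    for (j in seq_len(nrow(regions))) {
      rec <- extract_loop_record(st, regions$chain[j], regions$start[j],
                                 regions$end[j])
      if (is.null(rec)) {
        skipped <- c(skipped, sprintf("%s:%s:%d-%d broken backbone or anchors",
                                      st$id, regions$chain[j],
                                      regions$start[j], regions$end[j]))
        next
      }
      nl <- nl + 1L
      rec$structure_index <- s
      records[[length(records) + 1L]] <- rec
      for (mdl in c("ca", "c")) {
        pm <- rec[[paste0("pairs_", mdl)]]
        for (r in seq_len(nrow(pm))) {
          g <- as.character(pm[r, "g"])
          pairs[[mdl]][[g]] <- rbind(pairs[[mdl]][[g]], pm[r, c("d_prev", "d_new")])
        }
      }
      d <- rec$dihedrals
      keep <- !is.na(d$phi) & !is.na(d$psi)
      for (r in which(keep)) {
        ty <- d$resid[r]
        dihedrals[[ty]] <- rbind(dihedrals[[ty]], c(phi = d$phi[r], psi = d$psi[r]))
      }
      for (cv in rec$chis) {
        if (length(cv$chi) && !anyNA(cv$chi))
          chis[[cv$resid]] <- c(chis[[cv$resid]], list(cv$chi))
      }
    }
    manifest[[length(manifest) + 1L]] <-
      data.frame(index = s, id = if (is.na(st$id)) sprintf("structure%03d", s) else st$id,
                 n_loops = nl)
  }
  ## sort pair sets so fits are order-insensitive
  for (mdl in c("ca", "c")) {
    gs <- names(pairs[[mdl]])
    pairs[[mdl]] <- pairs[[mdl]][order(as.integer(gs))]
    pairs[[mdl]] <- lapply(pairs[[mdl]], function(m) {
      m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
      rownames(m) <- NULL
      m
    })
  }
  structure(list(pairs = pairs, dihedrals = dihedrals, chis = chis,
                 loops = records,
                 manifest = do.call(rbind, manifest), skipped = skipped,
                 structures = structures),
            class = "lg_loopdb")
}

#' @export
print.lg_loopdb <- function(x, ...) {
  cat("<lg_loopdb> ", length(x$loops), " loops from ",
      nrow(x$manifest), " structures; g up to ",
      max(c(0L, as.integer(names(x$pairs$c)))), "\n", sep = "")
  invisible(x)
}
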