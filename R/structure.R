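# Protein structures as flat atom tables (class `lg_structure`), PDB reading
# and writing (via bio3d), and residue-level accessors. Only heavy atoms of
# the 20 standard residues take part in modeling; waters and heteroatoms are
# parked in `$het`.

#' Construct a structure from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `x`, `y`, `z`, and optionally `o` (occupancy), `b` (B-factor),
#'   `alt` (altloc).
#' @param het Optional data frame of non-modeled records (waters,
#'   heteroatoms), same columns.
#' @param id Optional structure identifier.
#' @return An object of class `lg_structure`.
#' @export
lg_structure <- function(atoms, het = NULL, id = NA_character_) {
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table lacks columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "), call. = FALSE)
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$alt)) atoms$alt <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, atoms$alt)
  if (anyDuplicated(key))
    stop("duplicate atom records (chain/resno/icode/name/altloc)", call. = FALSE)
  structure(list(atoms = atoms, het = het, id = id), class = "lg_structure")
}

#' @export
print.lg_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "insert")]))
  cat("<lg_structure", if (!is.na(x$id)) x$id else "", "> ",
      nres, " residues, ", nrow(x$atoms), " heavy atoms\n", sep = "")
  invisible(x)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM coordinate records (through bio3d). Hydrogens are
#' dropped; for alternate locations only the highest-occupancy altloc is
#' retained (ties resolved alphabetically, so 'A' wins). Waters and
#' heteroatoms are kept in `$het` but excluded from modeling and energies.
#'
#' @param path Path to a PDB file.
#' @return An `lg_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- "A"
  df <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                   resid = at$resid, elety = at$elety, x = at$x, y = at$y,
                   z = at$z, o = ifelse(is.na(at$o), 1, at$o),
                   b = ifelse(is.na(at$b), 0, at$b), alt = at$alt,
                   type = at$type, stringsAsFactors = FALSE)
  is_mod <- df$type == "ATOM" & df$resid %in% AA3 &
    atom_element(df$elety) %in% names(.vdw_by_element)
  het <- df[!is_mod, setdiff(names(df), "type"), drop = FALSE]
  df <- df[is_mod, , drop = FALSE]
  ## altloc: keep highest occupancy per (chain, resno, icode, name)
  if (any(df$alt != "")) {
    key <- paste(df$chain, df$resno, df$insert, df$elety)
    ord <- order(key, -df$o, df$alt)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(paste(df$chain, df$resno, df$insert, df$elety)), ,
             drop = FALSE]
    df <- df[order(as.integer(rownames(df))), , drop = FALSE]
  }
  df$alt <- ""
  df$type <- NULL
  rownames(df) <- NULL
  lg_structure(df, het = if (nrow(het)) het else NULL,
               id = sub("\\.pdb$", "", basename(path)))
}

#' Write a structure to a PDB file
#'
#' Standard fixed-column coordinate records. Optionally tags a loop region
#' with a `REMARK 999 LOOP` line and/or writes per-atom energies into the
#' B-factor column.
#'
#' @param structure An `lg_structure`.
#' @param path Output path.
#' @param loop Optional list with `chain`, `start`, `end` to record as a
#'   REMARK.
#' @param bfactor Optional numeric vector (one per atom) written to the
#'   B-factor column, e.g. per-atom energies.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, loop = NULL, bfactor = NULL) {
  at <- structure$atoms
  if (nrow(at) > 0 && (max(at$x, at$y, at$z) > 9999.999 ||
                       min(at$x, at$y, at$z) < -999.999))
    stop("coordinates overflow the fixed 8.3 PDB field", call. = FALSE)
  b <- if (!is.null(bfactor)) bfactor else at$b
  if (nrow(at) == 0) {
    writeLines(c(remark_lines(structure, loop), "END"), path)
    return(invisible(path))
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)), resno = at$resno,
                   resid = at$resid, elety = at$elety, chain = at$chain,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   o = at$o, b = b)
  rl <- remark_lines(structure, loop)
  if (length(rl)) writeLines(c(rl, readLines(path)), path)
  invisible(path)
}

remark_lines <- function(structure, loop) {
  out <- character()
  if (!is.null(loop))
    out <- sprintf("REMARK 999 LOOP %s %d %d", loop$chain, loop$start, loop$end)
  out
}

## ---- residue-level helpers -------------------------------------------------

## Ordered residue table of one chain: chain, resno, insert, resid.
chain_residues <- function(structure, chain) {
  at <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  res <- unique(at[, c("chain", "resno", "insert", "resid")])
  res[order(res$resno, res$insert), , drop = FALSE]
}

## Coordinates of one named atom of one residue (or NULL).
residue_atom <- function(structure, chain, resno, elety) {
  at <- structure$atoms
  i <- which(at$chain == chain & at$resno == resno & at$elety == elety)
  if (length(i) == 0) return(NULL)
  as.numeric(at[i[1], c("x", "y", "z")])
}

## TRUE when residue has complete backbone (N, CA, C, O).
backbone_complete <- function(structure, chain, resno) {
  at <- structure$atoms
  sel <- at$chain == chain & at$resno == resno
  all(c("N", "CA", "C", "O") %in% at$elety[sel])
}

## Drop all atoms of residues start..end of a chain.
drop_residues <- function(structure, chain, start, end) {
  at <- structure$atoms
  keep <- !(at$chain == chain & at$resno >= start & at$resno <= end)
  lg_structure(at[keep, , drop = FALSE], het = structure$het, id = structure$id)
}
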