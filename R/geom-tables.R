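# Residue-typed geometry data: backbone bond lengths/angles (Engh--Huber-style
# idealized values), an internal-coordinate side-chain topology for the 20
# standard amino acids, van der Waals radii, and the 20-class atom-type
# scheme. These tables are the package's versioned stand-in for the standard
# stereochemical dictionaries; every consumer reads them through the
# accessors below so the values stay in one place.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

#' Three-letter codes of the 20 standard amino acids
#' @return Character vector of length 20.
#' @export
amino_acids <- function() AA3

## ---- backbone geometry -----------------------------------------------------

.bb_default <- c(
  b_NCA  = 1.458,  # N-CA bond
  b_CAC  = 1.525,  # CA-C bond
  b_CN   = 1.329,  # C-N(+1) peptide bond
  b_CO   = 1.231,  # C=O
  b_CACB = 1.530,  # CA-CB
  a_NCAC  = 111.2, # N-CA-C
  a_CACN  = 116.2, # CA-C-N(+1)
  a_CNCA  = 121.7, # C(-1)-N-CA
  a_CACO  = 120.8, # CA-C=O
  a_NCACB = 110.4  # N-CA-CB
)

.bb_override <- list(
  GLY = c(b_CAC = 1.516, a_NCAC = 112.5),
  PRO = c(b_NCA = 1.466, a_NCAC = 111.8, a_CNCA = 122.6, a_NCACB = 103.0),
  VAL = c(a_NCACB = 111.5), ILE = c(a_NCACB = 111.5), THR = c(a_NCACB = 111.5)
)

## Improper dihedral C-N-CA-CB fixing L-chirality of the CB branch.
.cb_dihedral <- 122.55

#' Backbone geometry parameter lookup
#'
#' Residue-typed idealized backbone bond lengths (Angstrom) and angles
#' (degrees). Keys: `b_NCA`, `b_CAC`, `b_CN`, `b_CO`, `b_CACB` (lengths);
#' `a_NCAC`, `a_CACN`, `a_CNCA`, `a_CACO`, `a_NCACB` (angles).
#'
#' @param residue_type Three-letter residue code (defaults apply to any other
#'   value).
#' @param key Parameter key; omit to get the full named vector.
#' @return Numeric value, or named vector when `key` is missing.
#' @export
backbone_geometry <- function(residue_type = "ALA", key = NULL) {
  v <- .bb_default
  ov <- .bb_override[[residue_type]]
  if (!is.null(ov)) v[names(ov)] <- ov
  if (is.null(key)) v else unname(v[[key]])
}

## bond_geometry helper for a backbone step
bb_geom <- function(residue_type, bond_key, angle_key) {
  bond_geometry(backbone_geometry(residue_type, bond_key),
                backbone_geometry(residue_type, angle_key))
}

## ---- side-chain topology ---------------------------------------------------

## Each atom: frame (3 previously available atom names), bond length, bond
## angle, and a dihedral rule: chi index with additive offset, or a fixed
## value. CB entries are implicit (added by sidechain_topology()).
sc_atom <- function(name, frame, len, ang, chi = NA_integer_, offset = 0,
                    fixed = NA_real_) {
  list(name = name, frame = frame, len = len, ang = ang,
       chi = chi, offset = offset, fixed = fixed)
}

.sc_topology <- list(
  GLY = list(),
  ALA = list(),
  SER = list(sc_atom("OG",  c("N", "CA", "CB"), 1.41, 110.5, 1)),
  CYS = list(sc_atom("SG",  c("N", "CA", "CB"), 1.81, 114.0, 1)),
  THR = list(sc_atom("OG1", c("N", "CA", "CB"), 1.43, 109.6, 1),
             sc_atom("CG2", c("N", "CA", "CB"), 1.52, 110.5, 1, offset = -122)),
  VAL = list(sc_atom("CG1", c("N", "CA", "CB"), 1.53, 110.5, 1),
             sc_atom("CG2", c("N", "CA", "CB"), 1.53, 110.5, 1, offset = -122)),
  LEU = list(sc_atom("CG",  c("N", "CA", "CB"), 1.53, 116.3, 1),
             sc_atom("CD1", c("CA", "CB", "CG"), 1.52, 110.7, 2),
             sc_atom("CD2", c("CA", "CB", "CG"), 1.52, 110.7, 2, offset = 122)),
  ILE = list(sc_atom("CG1", c("N", "CA", "CB"), 1.53, 110.4, 1),
             sc_atom("CG2", c("N", "CA", "CB"), 1.53, 110.5, 1, offset = -122),
             sc_atom("CD1", c("CA", "CB", "CG1"), 1.51, 113.8, 2)),
  MET = list(sc_atom("CG",  c("N", "CA", "CB"), 1.52, 114.1, 1),
             sc_atom("SD",  c("CA", "CB", "CG"), 1.80, 112.7, 2),
             sc_atom("CE",  c("CB", "CG", "SD"), 1.79, 100.2, 3)),
  PRO = list(sc_atom("CG",  c("N", "CA", "CB"), 1.49, 104.5, 1),
             sc_atom("CD",  c("CA", "CB", "CG"), 1.50, 106.1, 2)),
  PHE = list(sc_atom("CG",  c("N", "CA", "CB"), 1.50, 113.8, 1),
             sc_atom("CD1", c("CA", "CB", "CG"), 1.39, 120.8, 2),
             sc_atom("CD2", c("CA", "CB", "CG"), 1.39, 120.8, 2, offset = 180),
             sc_atom("CE1", c("CB", "CG", "CD1"), 1.39, 120.8, fixed = 180),
             sc_atom("CE2", c("CB", "CG", "CD2"), 1.39, 120.8, fixed = 180),
             sc_atom("CZ",  c("CG", "CD1", "CE1"), 1.39, 120.0, fixed = 0)),
  TYR = list(sc_atom("CG",  c("N", "CA", "CB"), 1.50, 113.8, 1),
             sc_atom("CD1", c("CA", "CB", "CG"), 1.39, 120.8, 2),
             sc_atom("CD2", c("CA", "CB", "CG"), 1.39, 120.8, 2, offset = 180),
             sc_atom("CE1", c("CB", "CG", "CD1"), 1.39, 120.8, fixed = 180),
             sc_atom("CE2", c("CB", "CG", "CD2"), 1.39, 120.8, fixed = 180),
             sc_atom("CZ",  c("CG", "CD1", "CE1"), 1.39, 120.0, fixed = 0),
             sc_atom("OH",  c("CD1", "CE1", "CZ"), 1.38, 119.9, fixed = 180)),
  TRP = list(sc_atom("CG",  c("N", "CA", "CB"), 1.50, 113.6, 1),
             sc_atom("CD1", c("CA", "CB", "CG"), 1.37, 126.9, 2),
             sc_atom("CD2", c("CA", "CB", "CG"), 1.43, 126.7, 2, offset = 180),
             sc_atom("NE1", c("CB", "CG", "CD1"), 1.38, 110.2, fixed = 180),
             sc_atom("CE2", c("CB", "CG", "CD2"), 1.41, 107.2, fixed = 180),
             sc_atom("CE3", c("CB", "CG", "CD2"), 1.40, 133.9, fixed = 0),
             sc_atom("CZ2", c("CG", "CD2", "CE2"), 1.40, 122.4, fixed = 180),
             sc_atom("CZ3", c("CG", "CD2", "CE3"), 1.39, 118.7, fixed = 180),
             sc_atom("CH2", c("CD2", "CE3", "CZ3"), 1.37, 121.1, fixed = 0)),
  HIS = list(sc_atom("CG",  c("N", "CA", "CB"), 1.49, 113.8, 1),
             sc_atom("ND1", c("CA", "CB", "CG"), 1.38, 122.7, 2),
             sc_atom("CD2", c("CA", "CB", "CG"), 1.35, 131.0, 2, offset = 180),
             sc_atom("CE1", c("CB", "CG", "ND1"), 1.32, 109.0, fixed = 180),
             sc_atom("NE2", c("CB", "CG", "CD2"), 1.37, 107.0, fixed = 180)),
  ASP = list(sc_atom("CG",  c("N", "CA", "CB"), 1.52, 113.0, 1),
             sc_atom("OD1", c("CA", "CB", "CG"), 1.25, 118.5, 2),
             sc_atom("OD2", c("CA", "CB", "CG"), 1.25, 118.5, 2, offset = 180)),
  ASN = list(sc_atom("CG",  c("N", "CA", "CB"), 1.52, 112.7, 1),
             sc_atom("OD1", c("CA", "CB", "CG"), 1.23, 120.8, 2),
             sc_atom("ND2", c("CA", "CB", "CG"), 1.33, 116.4, 2, offset = 180)),
  GLU = list(sc_atom("CG",  c("N", "CA", "CB"), 1.52, 114.1, 1),
             sc_atom("CD",  c("CA", "CB", "CG"), 1.52, 112.6, 2),
             sc_atom("OE1", c("CB", "CG", "CD"), 1.25, 118.5, 3),
             sc_atom("OE2", c("CB", "CG", "CD"), 1.25, 118.5, 3, offset = 180)),
  GLN = list(sc_atom("CG",  c("N", "CA", "CB"), 1.52, 114.1, 1),
             sc_atom("CD",  c("CA", "CB", "CG"), 1.52, 112.6, 2),
             sc_atom("OE1", c("CB", "CG", "CD"), 1.23, 120.8, 3),
             sc_atom("NE2", c("CB", "CG", "CD"), 1.33, 116.4, 3, offset = 180)),
  LYS = list(sc_atom("CG",  c("N", "CA", "CB"), 1.52, 114.1, 1),
             sc_atom("CD",  c("CA", "CB", "CG"), 1.52, 111.3, 2),
             sc_atom("CE",  c("CB", "CG", "CD"), 1.52, 111.3, 3),
             sc_atom("NZ",  c("CG", "CD", "CE"), 1.49, 111.9, 4)),
  ARG = list(sc_atom("CG",  c("N", "CA", "CB"), 1.52, 114.1, 1),
             sc_atom("CD",  c("CA", "CB", "CG"), 1.52, 111.3, 2),
             sc_atom("NE",  c("CB", "CG", "CD"), 1.46, 112.0, 3),
             sc_atom("CZ",  c("CG", "CD", "NE"), 1.33, 124.2, 4),
             sc_atom("NH1", c("CD", "NE", "CZ"), 1.33, 120.0, fixed = 0),
             sc_atom("NH2", c("CD", "NE", "CZ"), 1.33, 120.0, fixed = 180))
)

#' Side-chain internal-coordinate topology
#'
#' Build recipe for the side chain of a residue type: for every heavy atom
#' beyond CB, the three-frame atoms, bond length, bond angle, and dihedral
#' rule (a chi index plus offset, or a fixed planar value). CB itself is the
#' first entry for every residue except glycine.
#'
#' @param residue_type Three-letter code.
#' @return List of atom recipes (possibly empty for GLY).
#' @export
sidechain_topology <- function(residue_type) {
  topo <- .sc_topology[[residue_type]]
  if (is.null(topo)) stop("unknown residue type: ", residue_type, call. = FALSE)
  if (residue_type == "GLY") return(list())
  cb <- sc_atom("CB", c("C", "N", "CA"),
                backbone_geometry(residue_type, "b_CACB"),
                backbone_geometry(residue_type, "a_NCACB"),
                fixed = .cb_dihedral)
  c(list(cb), topo)
}

#' Number of side-chain chi dihedrals of a residue type
#' @param residue_type Three-letter code.
#' @return Integer count (0 for GLY/ALA).
#' @export
chi_count <- function(residue_type) {
  topo <- sidechain_topology(residue_type)
  if (length(topo) == 0L) return(0L)
  chis <- vapply(topo, function(a) if (is.na(a$chi)) 0L else as.integer(a$chi), 0L)
  max(0L, chis)
}

#' Build side-chain heavy atoms from backbone and chi angles
#'
#' @param residue_type Three-letter code.
#' @param n,ca,c Backbone N, CA, C coordinates of the residue.
#' @param chis Numeric vector of chi dihedrals (degrees), length
#'   [chi_count()].
#' @return Matrix with one named row per side-chain atom (0 rows for GLY).
#' @export
build_side_chain <- function(residue_type, n, ca, c, chis = numeric()) {
  topo <- sidechain_topology(residue_type)
  if (length(topo) == 0L)
    return(matrix(numeric(), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  have <- list(N = n, CA = ca, C = c)
  out <- matrix(NA_real_, length(topo), 3,
                dimnames = list(vapply(topo, `[[`, "", "name"), c("x", "y", "z")))
  for (i in seq_along(topo)) {
    at <- topo[[i]]
    dih <- if (!is.na(at$fixed)) at$fixed else {
      if (length(chis) < at$chi)
        stop("residue ", residue_type, " needs chi", at$chi, call. = FALSE)
      chis[at$chi] + at$offset
    }
    p <- place_atom(have[[at$frame[1]]], have[[at$frame[2]]], have[[at$frame[3]]],
                    bond_geometry(at$len, at$ang), wrap_angle(dih))
    have[[at$name]] <- p
    out[i, ] <- p
  }
  out
}

#' Canonical rotamer chi vectors used by the fixture generator
#'
#' A small library of common rotamer states per residue type; the fixture
#' generator draws one row at random per residue.
#'
#' @param residue_type Three-letter code.
#' @return Numeric matrix, one rotamer per row ([chi_count()] columns;
#'   zero-column matrix for GLY/ALA).
#' @export
canonical_rotamers <- function(residue_type) {
  nch <- chi_count(residue_type)
  if (nch == 0L) return(matrix(numeric(), 1, 0))
  if (residue_type == "PRO") return(rbind(c(-26, 36), c(26, -34)))
  chi1 <- c(-65, 180, 62)
  chi2 <- switch(residue_type,
                 PHE = , TYR = , TRP = , HIS = c(90, 80, 90),
                 ASP = , ASN = c(-20, -15, -25),
                 c(180, 175, 65))
  base <- cbind(chi1, chi2, rep(180, 3), rep(180, 3))
  base[, seq_len(nch), drop = FALSE]
}

## ---- van der Waals radii ---------------------------------------------------

.vdw_by_element <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Element of a heavy atom from its PDB atom name
#' @param atom_name Character vector of PDB atom names (e.g. `"CA"`, `"OD1"`).
#' @return Character vector of element symbols.
#' @export
atom_element <- function(atom_name) {
  substr(gsub("[0-9]", "", toupper(atom_name)), 1, 1)
}

#' Van der Waals radius of a heavy atom
#' @param atom_name Character vector of PDB atom names.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(atom_name) {
  r <- .vdw_by_element[atom_element(atom_name)]
  if (anyNA(r)) stop("unknown element for atom name(s): ",
                     paste(atom_name[is.na(r)], collapse = ", "), call. = FALSE)
  unname(r)
}

#' Maximum side-chain extension (Angstrom)
#'
#' Largest distance from CA to any side-chain heavy atom over all residue
#' types, evaluated from the shipped topology with all chi angles extended
#' (180 degrees). Used as the `s_max` term of the enlarged loop ellipsoid.
#'
#' @return A single numeric value (attained by arginine).
#' @export
max_sidechain_length <- function() {
  if (!is.null(.lg_cache$s_max)) return(.lg_cache$s_max)
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  cc <- place_atom(c(0, 0, 1), n, ca, bond_geometry(1.525, 111.2), 0)
  s <- 0
  for (aa in AA3) {
    m <- build_side_chain(aa, n, ca, cc, rep(180, max(1L, chi_count(aa))))
    if (nrow(m)) s <- max(s, sqrt(max(rowSums(sweep(m, 2, ca)^2))))
  }
  .lg_cache$s_max <- s
  s
}

.lg_cache <- new.env(parent = emptyenv())
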