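# Internal-coordinate geometry: dihedral-driven atom placement, the analytic
# circle/sphere constructions used by distance-guided growth, and fixed-frame
# backbone RMSD. All angles are degrees at the interface, radians internally;
# dihedrals live in [-180, 180).

DEG <- pi / 180

#' Convert an angle to the canonical dihedral range
#'
#' Maps any angle in degrees to `[-180, 180)`, the convention used for all
#' dihedrals in this package (`+180` is reported as `-180`).
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in `[-180, 180)`.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y >= 180] <- -180
  y
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate (zero-length) vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## angle a-b-c in degrees
angle3 <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

## Rotate points (rows of m, or a length-3 vector) about the axis through
## `origin` with unit direction `axis`, by `theta` degrees (right-handed).
rotate_about_axis <- function(m, origin, axis, theta) {
  u <- unitv(axis)
  th <- theta * DEG
  ct <- cos(th); st <- sin(th)
  one <- matrix(m, ncol = 3)
  p <- sweep(one, 2, origin)
  ## Rodrigues formula, vectorized over rows
  dotu <- drop(p %*% u)
  cr <- cbind(u[2] * p[, 3] - u[3] * p[, 2],
              u[3] * p[, 1] - u[1] * p[, 3],
              u[1] * p[, 2] - u[2] * p[, 1])
  out <- p * ct + cr * st + outer(dotu * (1 - ct), u)
  out <- sweep(out, 2, origin, `+`)
  if (is.null(dim(m))) drop(out) else out
}

#' Bond geometry descriptor
#'
#' Bundles a bond length and a bond angle for placing one atom from an
#' existing frame. Values typically come from [backbone_geometry()].
#'
#' @param bond_length Bond length in Angstrom; must lie in `[0.8, 2.0]`.
#' @param bond_angle Bond angle in degrees; must lie in `[60, 180]`.
#' @param residue_type Optional three-letter residue code the values apply to.
#' @param atoms Optional character naming the atom pair/triple.
#' @return An object of class `bond_geometry`.
#' @export
bond_geometry <- function(bond_length, bond_angle, residue_type = NA_character_,
                          atoms = NA_character_) {
  stopifnot(is.finite(bond_length), is.finite(bond_angle))
  if (bond_length < 0.8 || bond_length > 2.0)
    stop("bond_length out of physical range [0.8, 2.0] Angstrom", call. = FALSE)
  if (bond_angle < 60 || bond_angle > 180)
    stop("bond_angle out of physical range [60, 180] degrees", call. = FALSE)
  structure(list(bond_length = bond_length, bond_angle = bond_angle,
                 residue_type = residue_type, atoms = atoms),
            class = "bond_geometry")
}

check_frame <- function(a, b, c) {
  ab <- b - a; bc <- c - b
  area2 <- vnorm(cross3(ab, bc))
  if (!all(is.finite(c(a, b, c)))) stop("non-finite frame coordinates", call. = FALSE)
  if (area2 < 2e-9) stop("degenerate frame: the three points are (near-)collinear",
                         call. = FALSE)
  invisible(TRUE)
}

#' Place an atom from three reference atoms and internal coordinates
#'
#' NeRF-style placement: given previously placed atoms `a`, `b`, `c`, returns
#' the point `d` at `geom$bond_length` from `c`, forming `geom$bond_angle`
#' with the `b`-`c` bond, with dihedral `a`-`b`-`c`-`d` equal to `dihedral`.
#' The construction round-trips with [measure_dihedral()] to well below 1e-6
#' degrees.
#'
#' @param a,b,c Length-3 numeric coordinates (Angstrom) of the frame atoms,
#'   in chain order; they must not be collinear.
#' @param geom A [bond_geometry()] object.
#' @param dihedral Target dihedral in degrees.
#' @return Length-3 numeric coordinates of the new atom.
#' @export
place_atom <- function(a, b, c, geom, dihedral) {
  check_frame(a, b, c)
  l <- geom$bond_length
  th <- geom$bond_angle * DEG
  tau <- dihedral * DEG
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))   # normal of the a-b-c plane
  m <- cross3(n, bc)              # completes right-handed frame (bc, m, n)
  d2 <- c(-l * cos(th), l * sin(th) * cos(tau), -l * sin(th) * sin(tau))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Measure a dihedral angle
#'
#' Dihedral of the four points `a`-`b`-`c`-`d` with the IUPAC sign convention
#' (positive for a right-handed rotation about the `b`-to-`c` axis), reported
#' in `[-180, 180)`.
#'
#' @param a,b,c,d Length-3 numeric coordinates.
#' @return Dihedral angle in degrees.
#' @export
measure_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("collinear points: dihedral undefined", call. = FALSE)
  m1 <- cross3(n1, unitv(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
  wrap_angle(ang)
}

#' Circle of admissible positions for the next atom
#'
#' With the previous two atoms fixed and the new bond length and bond angle
#' prescribed, the next atom is constrained to a circle: its center lies on
#' the `prev2`-`prev1` axis and its plane is perpendicular to it. This is the
#' locus swept by the free dihedral.
#'
#' @param prev2,prev1 Length-3 coordinates of the two previous atoms
#'   (`prev1` is the bonded one).
#' @param geom A [bond_geometry()] object for the new bond.
#' @return An object of class `circle3` with fields `center`, `radius`,
#'   `normal` (unit vector along `prev1 - prev2`).
#' @export
placement_circle <- function(prev2, prev1, geom) {
  if (vnorm(prev1 - prev2) < 1e-9) stop("prev2 and prev1 coincide", call. = FALSE)
  th <- geom$bond_angle
  if (th <= 1e-9 || th >= 180 - 1e-9)
    stop("degenerate circle: bond angle of 0 or 180 degrees", call. = FALSE)
  n <- unitv(prev1 - prev2)
  l <- geom$bond_length
  structure(list(center = prev1 - l * cos(th * DEG) * n,
                 radius = l * sin(th * DEG),
                 normal = n),
            class = "circle3")
}

## Orthonormal in-plane basis for a circle3.
circle_basis <- function(circle) {
  n <- circle$normal
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(cross3(n, ref))
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}

#' Point on a circle at a given turn angle
#'
#' @param circle A `circle3` from [placement_circle()].
#' @param phi Angle(s) in degrees around the circle (arbitrary origin).
#' @return A length-3 vector, or an `n x 3` matrix when `phi` is a vector.
#' @export
circle_point <- function(circle, phi) {
  b <- circle_basis(circle)
  ph <- phi * DEG
  out <- outer(cos(ph) * circle$radius, b$e1) +
    outer(sin(ph) * circle$radius, b$e2)
  out <- sweep(out, 2, circle$center, `+`)
  if (length(phi) == 1L) drop(out) else out
}

#' Intersect a circle with a sphere
#'
#' Returns the 0, 1 (tangency) or 2 points that lie on `circle` and at
#' distance `dist` from `anchor`. This is the operation that converts a
#' sampled atom-to-anchor distance into candidate atom positions during
#' chain growth.
#'
#' @param circle A `circle3`.
#' @param anchor Length-3 coordinates of the sphere center.
#' @param dist Sphere radius in Angstrom (> 0).
#' @param tol Tolerance for the tangency / degeneracy decisions.
#' @return A list of 0--2 length-3 points. An empty list signals an
#'   infeasible distance. An anchor on the circle axis at exactly the
#'   compatible distance makes every circle point a solution; that degenerate
#'   case raises an error.
#' @export
intersect_circle_sphere <- function(circle, anchor, dist, tol = 1e-9) {
  stopifnot(dist > 0)
  w <- anchor - circle$center
  n <- circle$normal
  wn <- sum(w * n)
  wp <- w - wn * n
  rho <- vnorm(wp)
  r <- circle$radius
  rhs <- r^2 + sum(w * w) - dist^2
  if (rho < tol) {
    if (abs(rhs) < tol)
      stop("degenerate: anchor on the circle axis at the compatible distance",
           call. = FALSE)
    return(list())
  }
  cosv <- rhs / (2 * r * rho)
  if (cosv > 1 + tol || cosv < -1 - tol) return(list())
  cosv <- max(-1, min(1, cosv))
  e1 <- wp / rho
  e2 <- cross3(n, e1)
  delta <- acos(cosv)
  p1 <- circle$center + r * (cos(delta) * e1 + sin(delta) * e2)
  if (abs(abs(cosv) - 1) < tol) return(list(p1))
  p2 <- circle$center + r * (cos(delta) * e1 - sin(delta) * e2)
  list(p1, p2)
}

#' Fixed-frame backbone RMSD between two loop conformations
#'
#' Root-mean-square deviation over the backbone atoms of the loop residues,
#' computed in the common coordinate frame of the fixed protein body --
#' deliberately without superposition, so displacement relative to the
#' anchors is penalized.
#'
#' @param a,b Loop conformations: either `lg_conformation` objects (see
#'   [sample_loop()]), atom data frames with columns `resi`, `elety`, `x`,
#'   `y`, `z`, or plain `n x 3` matrices of matched atoms.
#' @param atoms `"NCACO"` (default) uses N, CA, C and O; `"NCAC"` uses the
#'   three-atom variant.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(a, b, atoms = c("NCACO", "NCAC")) {
  atoms <- match.arg(atoms)
  sel <- if (atoms == "NCACO") c("N", "CA", "C", "O") else c("N", "CA", "C")
  ma <- conformation_xyz(a, sel)
  mb <- conformation_xyz(b, sel)
  if (nrow(ma) != nrow(mb))
    stop("conformations have different numbers of backbone atoms", call. = FALSE)
  sqrt(mean(rowSums((ma - mb)^2)))
}

## Extract an ordered backbone coordinate matrix from the accepted inputs.
conformation_xyz <- function(x, sel) {
  if (is.matrix(x)) return(x)
  df <- if (is.data.frame(x)) x else x$atoms
  df <- df[df$elety %in% sel, , drop = FALSE]
  df <- df[order(df$resi, match(df$elety, sel)), , drop = FALSE]
  as.matrix(df[, c("x", "y", "z")])
}
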