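# Empirical models guiding chain growth: a two-dimensional Gaussian kernel
# density estimate of (d_prev, d_new) anchor-distance pairs per residue
# separation, evaluated on a 32 x 32 grid and interpolated bilinearly, with
# exact conditional (inverse-CDF) sampling along the d_new axis; plus
# residue-typed (phi, psi) frequency tables and side-chain chi tables.

#' Winsorize a numeric vector at an upper percentile
#'
#' Values above the `level`-th percentile (type-7 linear interpolation, the R
#' default) are replaced by that percentile value. Count and order are
#' preserved; nothing is changed below.
#'
#' @param values Numeric vector (non-empty).
#' @param level Percentile in (0, 100].
#' @return Winsorized vector of the same length.
#' @export
winsorize <- function(values, level = 99) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  stopifnot(level > 0, level <= 100)
  q <- stats::quantile(values, level / 100, names = FALSE)
  pmin(values, q)
}

#' Fit a 2D Gaussian kernel density estimate of distance pairs
#'
#' Fits the bivariate density of `(d_prev, d_new)` pairs with a diagonal
#' bandwidth matrix built from the per-axis standard deviations by Scott's
#' rule for two dimensions, `h_i = sigma_i * n^(-1/6)`, optionally scaled.
#' Both axes are Winsorized at `winsor` before fitting. The density is
#' evaluated on a 32 x 32 grid spanning the Winsorized data range padded by
#' two bandwidths per axis; off-grid queries are interpolated bilinearly by
#' [eval_density()].
#'
#' @param pairs Two-column numeric matrix of `(d_prev, d_new)` observations
#'   (at least 10 rows).
#' @param winsor Winsorization percentile (default 99).
#' @param bw_factor Multiplier on the Scott's-rule bandwidths.
#' @param grid_n Grid points per axis (default 32).
#' @return An object of class `lg_kde2d`: `grid` (grid_n x grid_n density
#'   values, rows indexing d_prev), `x`, `y` (grid node coordinates), `h`
#'   (bandwidths), `n`.
#' @export
fit_kde2d <- function(pairs, winsor = 99, bw_factor = 1, grid_n = 32L) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  if (nrow(pairs) < 10)
    stop("need at least 10 pairs to fit a distance KDE", call. = FALSE)
  if (any(pairs <= 0)) stop("distances must be positive", call. = FALSE)
  xw <- winsorize(pairs[, 1], winsor)
  yw <- winsorize(pairs[, 2], winsor)
  n <- length(xw)
  sx <- stats::sd(xw); sy <- stats::sd(yw)
  if (sx < 1e-9 || sy < 1e-9)
    stop("zero variance on an axis; add jitter to the data before fitting",
         call. = FALSE)
  h <- c(sx, sy) * n^(-1 / 6) * bw_factor
  gx <- seq(min(xw) - 2 * h[1], max(xw) + 2 * h[1], length.out = grid_n)
  gy <- seq(min(yw) - 2 * h[2], max(yw) + 2 * h[2], length.out = grid_n)
  ## separable Gaussian kernel: grid = Ax %*% t(Ay) / (2 pi h1 h2 n)
  ax <- exp(-0.5 * (outer(gx, xw, `-`) / h[1])^2)
  ay <- exp(-0.5 * (outer(gy, yw, `-`) / h[2])^2)
  grid <- (ax %*% t(ay)) / (2 * pi * h[1] * h[2] * n)
  structure(list(grid = grid, x = gx, y = gy, h = h, n = n,
                 winsor = winsor, bw_factor = bw_factor),
            class = "lg_kde2d")
}

#' Evaluate the fitted density by bilinear interpolation
#'
#' Exact grid-node queries return the stored value; interior points are the
#' bilinear blend of the four surrounding nodes; points outside the grid
#' domain have density 0.
#'
#' @param kde An `lg_kde2d`.
#' @param d_prev,d_new Query coordinates (vectors of equal length recycle).
#' @return Numeric vector of densities.
#' @export
eval_density <- function(kde, d_prev, d_new) {
  k <- max(length(d_prev), length(d_new))
  d_prev <- rep_len(d_prev, k); d_new <- rep_len(d_new, k)
  out <- numeric(k)
  inside <- d_prev >= kde$x[1] & d_prev <= kde$x[length(kde$x)] &
    d_new >= kde$y[1] & d_new <= kde$y[length(kde$y)]
  if (!any(inside)) return(out)
  xi <- pmin(findInterval(d_prev[inside], kde$x), length(kde$x) - 1L)
  yi <- pmin(findInterval(d_new[inside], kde$y), length(kde$y) - 1L)
  tx <- (d_prev[inside] - kde$x[xi]) / (kde$x[xi + 1L] - kde$x[xi])
  ty <- (d_new[inside] - kde$y[yi]) / (kde$y[yi + 1L] - kde$y[yi])
  g <- kde$grid
  out[inside] <-
    (1 - tx) * (1 - ty) * g[cbind(xi, yi)] +
    tx * (1 - ty) * g[cbind(xi + 1L, yi)] +
    (1 - tx) * ty * g[cbind(xi, yi + 1L)] +
    tx * ty * g[cbind(xi + 1L, yi + 1L)]
  out
}

## Conditional slice f(d_new | d_prev) on the 32 d_new nodes (unnormalized);
## zero vector when d_prev is outside the grid domain.
conditional_slice <- function(kde, d_prev) {
  nx <- length(kde$x)
  if (d_prev < kde$x[1] || d_prev > kde$x[nx]) return(numeric(length(kde$y)))
  xi <- min(findInterval(d_prev, kde$x), nx - 1L)
  tx <- (d_prev - kde$x[xi]) / (kde$x[xi + 1L] - kde$x[xi])
  (1 - tx) * kde$grid[xi, ] + tx * kde$grid[xi + 1L, ]
}

## Draw from a piecewise-linear density given node values f on nodes xs.
## Exact inverse-CDF within cells (quadratic solve); uses R's RNG stream.
sample_piecewise_linear <- function(xs, f, n = 1L) {
  dx <- diff(xs)
  w <- (f[-length(f)] + f[-1]) / 2 * dx
  tot <- sum(w)
  if (tot <= 0 || !is.finite(tot))
    stop("all-zero density slice", call. = FALSE)
  cw <- cumsum(w)
  u <- stats::runif(n) * tot
  cell <- findInterval(u, cw) + 1L
  cell <- pmin(cell, length(w))
  u_rem <- u - c(0, cw)[cell]
  f0 <- f[cell]; s <- (f[cell + 1L] - f[cell])
  a <- u_rem / dx[cell]
  t <- ifelse(abs(s) < 1e-12 * pmax(f0, 1e-300),
              a / pmax(f0, 1e-300),
              (-f0 + sqrt(pmax(f0^2 + 2 * s * a, 0))) / s)
  xs[cell] + pmin(pmax(t, 0), 1) * dx[cell]
}

#' Sample the new anchor distance from the conditional density
#'
#' Draws `d_new` from the normalized one-dimensional slice
#' `f(d_new | d_prev)` of the fitted grid: the slice is obtained by bilinear
#' interpolation along the `d_prev` axis, then sampled exactly as a
#' piecewise-linear density over the `d_new` nodes (inverse CDF with a
#' quadratic within-cell solve). Uses R's RNG stream, so draws are
#' reproducible under `set.seed()`.
#'
#' @param kde An `lg_kde2d`.
#' @param d_prev Conditioning distance.
#' @param n Number of draws.
#' @return Numeric vector of `d_new` draws.
#' @export
sample_conditional <- function(kde, d_prev, n = 1L) {
  f <- conditional_slice(kde, d_prev)
  if (sum(f) <= 0)
    stop(structure(class = c("lg_empty_slice", "error", "condition"),
                   list(message = sprintf(
                     "conditional slice at d_prev = %.3f has zero mass", d_prev),
                     call = NULL)))
  sample_piecewise_linear(kde$y, f, n)
}

#' Sample from the marginal of d_new
#'
#' Fallback used when the conditional slice is empty (d_prev far outside the
#' fitted domain): draws from the trapezoid-integrated marginal of `d_new`.
#'
#' @param kde An `lg_kde2d`.
#' @param n Number of draws.
#' @return Numeric vector of draws.
#' @export
sample_marginal <- function(kde, n = 1L) {
  dx <- diff(kde$x)
  g <- kde$grid
  marg <- colSums((g[-nrow(g), , drop = FALSE] + g[-1, , drop = FALSE]) / 2 * dx)
  sample_piecewise_linear(kde$y, marg, n)
}

## Precompiled piecewise-linear sampler: does the slice bookkeeping once
## and returns a cheap function(n). Used by the growth engine, which draws
## many distances from the same conditional slice.
pl_sampler <- function(xs, f) {
  dx <- diff(xs)
  w <- (f[-length(f)] + f[-1]) / 2 * dx
  tot <- sum(w)
  if (tot <= 0 || !is.finite(tot)) return(NULL)
  cw <- cumsum(w)
  cw0 <- c(0, cw)
  nmax <- length(w)
  function(n) {
    u <- stats::runif(n) * tot
    cell <- pmin(findInterval(u, cw) + 1L, nmax)
    u_rem <- u - cw0[cell]
    f0 <- f[cell]; s <- f[cell + 1L] - f[cell]
    a <- u_rem / dx[cell]
    t <- ifelse(abs(s) < 1e-12 * pmax(f0, 1e-300),
                a / pmax(f0, 1e-300),
                (-f0 + sqrt(pmax(f0^2 + 2 * s * a, 0))) / s)
    xs[cell] + pmin(pmax(t, 0), 1) * dx[cell]
  }
}

## conditional (or marginal-fallback) sampler factory for one d_prev
cond_sampler <- function(kde, d_prev) {
  sp <- pl_sampler(kde$y, conditional_slice(kde, d_prev))
  if (!is.null(sp)) return(sp)
  dx <- diff(kde$x)
  g <- kde$grid
  marg <- colSums((g[-nrow(g), , drop = FALSE] + g[-1, , drop = FALSE]) / 2 * dx)
  pl_sampler(kde$y, marg)
}

#' Analytic CDF of the conditional slice
#'
#' The exact CDF of the piecewise-linear conditional density sampled by
#' [sample_conditional()]; used for distributional checks.
#'
#' @param kde An `lg_kde2d`.
#' @param d_prev Conditioning distance.
#' @return A vectorized function `F(q)`.
#' @export
conditional_cdf <- function(kde, d_prev) {
  f <- conditional_slice(kde, d_prev)
  xs <- kde$y
  dx <- diff(xs)
  w <- (f[-length(f)] + f[-1]) / 2 * dx
  tot <- sum(w)
  cw <- c(0, cumsum(w))
  function(q) {
    vapply(q, function(qq) {
      if (qq <= xs[1]) return(0)
      if (qq >= xs[length(xs)]) return(1)
      j <- min(findInterval(qq, xs), length(dx))
      t <- (qq - xs[j]) / dx[j]
      (cw[j] + dx[j] * (f[j] * t + (f[j + 1] - f[j]) * t^2 / 2)) / tot
    }, numeric(1))
  }
}

## ---- dihedral frequency tables --------------------------------------------

#' Residue-typed backbone dihedral frequency table
#'
#' Two-dimensional histogram of (phi, psi) pairs on fixed-width bins over
#' `[-180, 180)`, with a pseudocount floor so every bin has finite
#' log-probability.
#'
#' @param phi_psi Two-column matrix of (phi, psi) in degrees (may have zero
#'   rows: the table is then uniform).
#' @param residue_type Three-letter code the table describes.
#' @param bin_width Bin width in degrees (default 10, i.e. 36 x 36 bins).
#' @param pseudocount Fraction of the total mass used as the per-bin floor.
#' @return An object of class `lg_dihedral_table`.
#' @export
dihedral_table <- function(phi_psi, residue_type = NA_character_,
                           bin_width = 10, pseudocount = 1e-6) {
  nb <- as.integer(round(360 / bin_width))
  counts <- matrix(0, nb, nb)
  if (!is.null(phi_psi) && nrow(phi_psi) > 0) {
    bi <- dihedral_bin(phi_psi[, 1], bin_width)
    bj <- dihedral_bin(phi_psi[, 2], bin_width)
    for (r in seq_along(bi)) counts[bi[r], bj[r]] <- counts[bi[r], bj[r]] + 1
  }
  total <- sum(counts)
  eps <- if (total > 0) pseudocount * total else 1
  structure(list(counts = counts, bin_width = bin_width, eps = eps,
                 total = total, residue_type = residue_type,
                 logZ = log(total + eps * nb * nb)),
            class = "lg_dihedral_table")
}

dihedral_bin <- function(angle, bin_width) {
  a <- wrap_angle(angle)
  pmin(as.integer(floor((a + 180) / bin_width)) + 1L,
       as.integer(round(360 / bin_width)))
}

#' Log-probability of a (phi, psi) pair under a dihedral table
#'
#' `log((count + eps) / Z)` of the bin containing the pair, normalized over
#' all bins; finite for any input.
#'
#' @param table An `lg_dihedral_table`.
#' @param phi,psi Dihedrals in degrees (vectors recycle).
#' @return Numeric vector of log-probabilities.
#' @export
dihedral_log_prob <- function(table, phi, psi) {
  k <- max(length(phi), length(psi))
  bi <- dihedral_bin(rep_len(phi, k), table$bin_width)
  bj <- dihedral_bin(rep_len(psi, k), table$bin_width)
  log(table$counts[cbind(bi, bj)] + table$eps) - table$logZ
}

#' Select k of m trial states by their backbone dihedrals
#'
#' Draws `k` distinct candidates without replacement with probability
#' proportional to the dihedral-table probability of their (phi, psi) pair.
#' Uses R's RNG stream.
#'
#' @param trials Data frame (or list) with elements `phi` and `psi`, one per
#'   candidate.
#' @param table An `lg_dihedral_table` for the residue type.
#' @param k Number to keep (`1 <= k <= m`).
#' @return Integer indices of the selected candidates.
#' @export
select_k_trials <- function(trials, table, k) {
  m <- length(trials$phi)
  if (k > m) stop("k exceeds the number of trials", call. = FALSE)
  if (k == m) return(seq_len(m))
  w <- exp(dihedral_log_prob(table, trials$phi, trials$psi))
  sample.int(m, k, replace = FALSE, prob = w)
}

## ---- side-chain chi tables -------------------------------------------------

#' Residue-typed side-chain chi frequency table
#'
#' Joint empirical distribution of the chi vector, discretized into
#' fixed-width bins; only observed bins are stored (and only those can be
#' sampled, mirroring the retain-non-zero-bins practice).
#'
#' @param chi_list List of numeric chi vectors (degrees) observed for this
#'   residue type.
#' @param residue_type Three-letter code.
#' @param bin_width Bin width in degrees (default 10).
#' @return An object of class `lg_chi_table`.
#' @export
chi_table <- function(chi_list, residue_type, bin_width = 10) {
  nch <- chi_count(residue_type)
  bins <- NULL; counts <- integer()
  if (nch > 0 && length(chi_list)) {
    keep <- vapply(chi_list, function(v) length(v) == nch && !anyNA(v), logical(1))
    if (any(keep)) {
      m <- do.call(rbind, chi_list[keep])
      bm <- matrix(dihedral_bin(m, bin_width), nrow(m), nch)
      key <- apply(bm, 1, paste, collapse = ",")
      tab <- table(key)
      bins <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
      counts <- as.integer(tab)
    }
  }
  structure(list(bins = bins, counts = counts, bin_width = bin_width,
                 n_chi = nch, residue_type = residue_type),
            class = "lg_chi_table")
}

#' Sample chi vectors from a chi table
#'
#' Draws an occupied bin with probability proportional to its count, then a
#' uniform value within the bin per chi. An empty table (residue type never
#' observed) falls back to the canonical rotamer library.
#'
#' @param table An `lg_chi_table`.
#' @param n Number of vectors to draw.
#' @return `n x n_chi` matrix of chi angles (0 columns for GLY/ALA).
#' @export
sample_chi <- function(table, n = 1L) {
  nch <- table$n_chi
  if (nch == 0L) return(matrix(numeric(), n, 0))
  bw <- table$bin_width
  if (is.null(table$bins)) {
    rot <- canonical_rotamers(table$residue_type)
    idx <- sample.int(nrow(rot), n, replace = TRUE)
    return(rot[idx, , drop = FALSE] +
             matrix(stats::runif(n * nch, -bw / 2, bw / 2), n, nch))
  }
  idx <- if (nrow(table$bins) == 1L) rep(1L, n)
         else sample.int(nrow(table$bins), n, replace = TRUE, prob = table$counts)
  centers <- (table$bins[idx, , drop = FALSE] - 1) * bw - 180 + bw / 2
  wrap_angle(centers + matrix(stats::runif(n * nch, -bw / 2, bw / 2), n, nch))
}
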