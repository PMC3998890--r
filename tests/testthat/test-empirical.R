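# Distance-pair KDEs, conditional sampling, and the dihedral / chi
# frequency tables.

test_that("winsorize matches the direct percentile computation", {
  x <- 1:100
  w <- winsorize(x, 95)
  q <- unname(quantile(x, 0.95))  # 95.05 by linear interpolation
  expect_equal(q, 95.05)
  expect_true(all(w[x > q] == q))
  expect_identical(w[x <= q], as.numeric(x[x <= q]))
  expect_identical(winsorize(x, 100), as.numeric(x))
  expect_identical(winsorize(rep(3, 10), 50), rep(3, 10))
  ## count and element positions preserved
  wr <- winsorize(rev(x), 90)
  expect_length(wr, 100)
  expect_identical(wr[11:100], as.numeric(rev(x))[11:100])
  expect_error(winsorize(numeric(0)), "empty")
})

test_that("fit_kde2d equals the brute-force kernel sum at every grid node", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(20:80, 1)
    pairs <- cbind(rlnorm(n, log(8), 0.3), rlnorm(n, log(7), 0.3))
    k <- fit_kde2d(pairs, winsor = 99)
    xw <- winsorize(pairs[, 1], 99); yw <- winsorize(pairs[, 2], 99)
    ## check a row and a column of nodes against the explicit sum
    for (i in c(1, 7, 19, 32)) for (j in c(3, 15, 32)) {
      expect_equal(k$grid[i, j], kde_brute(xw, yw, k$h, k$x[i], k$y[j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("grid mass stays near 1 and the peak sits on the data", {
  set.seed(12)
  ints <- replicate(60, {
    n <- 150
    pairs <- cbind(rnorm(n, 9, 1.2), rnorm(n, 8, 0.9))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0, , drop = FALSE]
    k <- fit_kde2d(pairs)
    dx <- diff(k$x); dy <- diff(k$y)
    gi <- k$grid
    colint <- (gi[-nrow(gi), ] + gi[-1, ]) / 2
    colint <- colSums(colint * dx)
    sum((colint[-length(colint)] + colint[-1]) / 2 * dy)
  })
  expect_true(all(ints > 0.95 & ints < 1.05))
  ## tight cluster: argmax at the node nearest the cluster
  cl <- cbind(rnorm(40, 5, 0.05), rnorm(40, 5.5, 0.05))
  k <- fit_kde2d(cl)
  am <- which(k$grid == max(k$grid), arr.ind = TRUE)
  expect_equal(k$x[am[1]], 5, tolerance = 0.3)
  expect_equal(k$y[am[2]], 5.5, tolerance = 0.3)
  expect_error(fit_kde2d(cbind(rep(5, 20), 1:20 / 2)), "variance")
  expect_error(fit_kde2d(cbind(1:5, 1:5)), "at least 10")
})

test_that("eval_density is exact at nodes, bilinear inside, zero outside", {
  set.seed(13)
  k <- fit_kde2d(cbind(rnorm(50, 9, 1), rnorm(50, 8, 1)))
  for (i in c(1, 10, 32)) for (j in c(2, 20, 32))
    expect_equal(eval_density(k, k$x[i], k$y[j]), k$grid[i, j])
  ## cell-center query equals the mean of the 4 corners
  i <- 5; j <- 9
  xm <- (k$x[i] + k$x[i + 1]) / 2; ym <- (k$y[j] + k$y[j + 1]) / 2
  expect_equal(eval_density(k, xm, ym),
               mean(k$grid[i:(i + 1), j:(j + 1)]), tolerance = 1e-12)
  expect_identical(eval_density(k, k$x[1] - 1, ym), 0)
  expect_identical(eval_density(k, xm, k$y[32] + 0.01), 0)
})

test_that("conditional sampling tracks correlated data and passes a KS check", {
  set.seed(14)
  x <- runif(4000, 3, 9)
  pairs <- cbind(x, x + rnorm(4000, 0, 0.05))
  k <- fit_kde2d(pairs)
  set.seed(15)
  draws <- sample_conditional(k, 6, n = 1e4)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 6), 3 * se + 0.05)
  ## KS against the analytic slice CDF
  cdf <- conditional_cdf(k, 6)
  D <- suppressWarnings(ks.test(draws, cdf)$statistic)
  expect_lt(unname(D), 0.02)
})

test_that("conditional sampling is seed-reproducible and fails cleanly off-domain", {
  set.seed(16)
  k <- fit_kde2d(cbind(rnorm(60, 8, 1), rnorm(60, 7, 1)))
  set.seed(99); a <- sample_conditional(k, 8, n = 50)
  set.seed(99); b <- sample_conditional(k, 8, n = 50)
  expect_identical(a, b)
  expect_error(sample_conditional(k, 1e3), class = "lg_empty_slice")
  set.seed(1)
  m <- sample_marginal(k, 100)
  expect_true(all(m >= k$y[1] & m <= k$y[32]))
})

test_that("dihedral tables normalize and floor empty bins", {
  tab <- dihedral_table(cbind(c(-60, -61, 120), c(-45, -44, 130)), "ALA")
  ## sum of exp(log-prob) over all bin centers is 1
  centers <- seq(-175, 175, by = 10)
  gridc <- expand.grid(phi = centers, psi = centers)
  expect_equal(sum(exp(dihedral_log_prob(tab, gridc$phi, gridc$psi))), 1,
               tolerance = 1e-9)
  ## empty bin gets the pseudocount floor log(eps/Z)
  expect_equal(dihedral_log_prob(tab, 0, 0), log(tab$eps) - tab$logZ)
  ## uniform (empty) table: same value everywhere
  u <- dihedral_table(NULL, "GLY")
  expect_equal(dihedral_log_prob(u, -60, -45), dihedral_log_prob(u, 100, 10))
})

test_that("select_k_trials is without replacement and respects the weights", {
  tab <- dihedral_table(cbind(rep(-60, 50), rep(-45, 50)), "ALA")
  trials <- list(phi = c(-60, 100, 70), psi = c(-45, 100, 90))
  expect_identical(select_k_trials(trials, tab, 3), 1:3)
  expect_error(select_k_trials(trials, tab, 4), "exceeds")
  ## the in-basin candidate dominates single draws
  set.seed(17)
  hits <- sum(replicate(2000, select_k_trials(trials, tab, 1) == 1L))
  expect_gt(hits, 1990)
  ## uniform table: frequencies uniform within 4 sigma
  u <- dihedral_table(NULL, "ALA")
  set.seed(18)
  picks <- replicate(3000, select_k_trials(list(phi = c(0, 50, -120),
                                                psi = c(10, -30, 80)), u, 1))
  cnt <- tabulate(picks, 3)
  expect_true(all(abs(cnt - 1000) < 4 * sqrt(3000 * (1 / 3) * (2 / 3))))
})

test_that("chi tables bin jointly, sample within occupied bins, and fall back", {
  chis <- list(c(-63, 175), c(-64, 176), c(58, 174))
  tab <- chi_table(chis, "LEU")
  expect_equal(tab$n_chi, 2L)
  expect_equal(sum(tab$counts), 3L)
  set.seed(19)
  s <- sample_chi(tab, 200)
  expect_equal(ncol(s), 2L)
  ## every draw lies within half a bin of an observed bin center
  centers1 <- unique((tab$bins[, 1] - 1) * 10 - 180 + 5)
  expect_true(all(vapply(s[, 1], function(v)
    min(abs(v - centers1)) <= 5 + 1e-9, logical(1))))
  ## unseen residue type: canonical rotamer fallback, correct width
  empty <- chi_table(list(), "LYS")
  s2 <- sample_chi(empty, 10)
  expect_equal(dim(s2), c(10L, 4L))
  ## GLY: zero columns
  expect_equal(ncol(sample_chi(chi_table(list(), "GLY"), 5)), 0L)
})
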