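test_that("Bartlett sphericity matches its closed form", {
  id <- diag(4)
  b <- bartlett_sphericity(id, n = 50)
  expect_equal(b$chisq, 0)
  expect_equal(b$p_value, 1)

  R2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  b2 <- bartlett_sphericity(R2, n = 100)
  expect_equal(b2$chisq, -(99 - 9 / 6) * log(0.75), tolerance = 1e-12)
  expect_equal(b2$df, 1)

  R6 <- matrix(0.3, 6, 6); diag(R6) <- 1
  expect_lt(bartlett_sphericity(R6, n = 131)$p_value, 0.05)

  expect_error(bartlett_sphericity(R2), class = "mc_validation_error")
})

test_that("KMO equals 0.5 for two items and detects common-factor structure", {
  R2 <- matrix(c(1, 0.61, 0.61, 1), 2)
  expect_equal(kmo(R2)$overall, 0.5, tolerance = 1e-12)

  set.seed(8)
  f <- rnorm(2000)
  X <- outer(f, rep(0.8, 6)) + matrix(rnorm(12000, 0, 0.6), 2000)
  expect_gt(kmo(X)$overall, 0.8)

  # two independent blocks have lower per-item adequacy than one block
  g <- rnorm(2000)
  Xb <- cbind(outer(f, rep(0.8, 3)), outer(g, rep(0.8, 3))) +
    matrix(rnorm(12000, 0, 0.6), 2000)
  expect_lt(mean(kmo(Xb)$msa), mean(kmo(X)$msa))
})

test_that("parallel analysis counts factors against permutation nulls", {
  set.seed(14)
  noise <- matrix(rnorm(200 * 8), 200)
  pa <- parallel_analysis(noise, n_reps = 120, seed = 5)
  expect_lte(pa$n_factors, 1)

  L <- matrix(0, 9, 3); L[1:3, 1] <- 0.8; L[4:6, 2] <- 0.8; L[7:9, 3] <- 0.8
  Fs <- matrix(rnorm(500 * 3), 500)
  X <- Fs %*% t(L) + matrix(rnorm(4500, 0, 0.6), 500)
  pa3 <- parallel_analysis(X, n_reps = 150, seed = 5)
  expect_equal(pa3$n_factors, 3L)

  expect_identical(parallel_analysis(X, n_reps = 120, seed = 9),
                   parallel_analysis(X, n_reps = 120, seed = 9))
  expect_error(parallel_analysis(X, n_reps = 50), class = "mc_validation_error")
})

test_that("least-squares extraction recovers a perfect single factor exactly", {
  lam <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  R <- tcrossprod(lam); diag(R) <- 1
  fm <- efa(R, 1, rotation = "none", n_obs = 500)
  expect_equal(unname(fm$loadings[, 1]), lam, tolerance = 1e-6)
  expect_equal(unname(fm$uniquenesses), 1 - lam^2, tolerance = 1e-6)
  expect_lt(fm$rmsr, 1e-6)
  expect_equal(fm$communalities + fm$uniquenesses, rep(1, 6), tolerance = 1e-6)
})

test_that("EFA recovers generating structure from sampled data", {
  set.seed(2)
  f <- rnorm(2000)
  X <- outer(f, rep(0.7, 6)) + matrix(rnorm(12000, 0, sqrt(1 - 0.49)), 2000)
  fm <- efa(X, 1, rotation = "none")
  expect_true(all(abs(fm$loadings[, 1] - 0.7) < 0.1))

  L <- matrix(0, 9, 3)
  L[1:3, 1] <- c(0.8, 0.75, 0.7); L[4:6, 2] <- c(0.8, 0.75, 0.7)
  L[7:9, 3] <- c(0.8, 0.75, 0.7)
  Fs <- matrix(rnorm(2000 * 3), 2000)
  X3 <- Fs %*% t(L) + matrix(rnorm(18000), 2000) %*% diag(sqrt(1 - rowSums(L^2)))
  fm3 <- efa(X3, 3, rotation = "promax")
  # simple structure: each item loads highest on its generating factor
  gen_factor <- rep(1:3, each = 3)
  top <- apply(abs(fm3$loadings), 1, which.max)
  expect_equal(length(unique(tapply(top, gen_factor, function(x) x[1]))), 3)
  # congruence with the generating loadings after column matching
  congr <- vapply(1:3, function(j) {
    cols <- abs(crossprod(L[, j], fm3$loadings)) /
      (sqrt(sum(L[, j]^2)) * sqrt(colSums(fm3$loadings^2)))
    max(cols)
  }, numeric(1))
  expect_true(all(congr >= 0.95))
  # orthogonal generator: promax intercorrelations near identity
  expect_lt(max(abs(fm3$phi[upper.tri(fm3$phi)])), 0.2)

  expect_error(efa(X3, 0), class = "mc_validation_error")
  expect_error(efa(X3, 9), class = "mc_validation_error")
})

test_that("Cronbach's alpha matches closed forms and simulations", {
  x <- cbind(1:10, 1:10)
  expect_equal(cronbach_alpha(x), 1)

  set.seed(6)
  ind <- matrix(rnorm(5000 * 4), 5000)
  expect_lt(abs(cronbach_alpha(ind)), 0.05)

  # 3 items with pairwise population r = 0.5: alpha -> 3*0.5/(1 + 2*0.5)
  f <- rnorm(20000)
  X <- outer(f, rep(sqrt(0.5), 3)) + matrix(rnorm(60000, 0, sqrt(0.5)), 20000)
  expect_equal(cronbach_alpha(X), 3 * 0.5 / (1 + 2 * 0.5), tolerance = 0.02)

  expect_error(cronbach_alpha(matrix(1, 5, 3)), class = "mc_numeric_error")
  expect_error(cronbach_alpha(matrix(1:4, 2, 2)), class = "mc_validation_error")
})

test_that("ICC(2,k) behaves as absolute agreement and matches ANOVA algebra", {
  m <- cbind(c(3, 7, 5, 9, 4, 6), c(3, 7, 5, 9, 4, 6))
  expect_equal(icc2k(m)$icc, 1)

  shift <- cbind(c(3, 7, 5, 9, 4, 6), c(3, 7, 5, 9, 4, 6) + 2)
  r <- icc2k(shift)
  expect_lt(r$icc, 1)   # absolute agreement penalizes the constant shift

  # independent route: mean squares from a two-way aov fit
  d <- data.frame(y = c(shift), subj = factor(rep(1:6, 2)),
                  occ = factor(rep(1:2, each = 6)))
  ms <- suppressWarnings(anova(stats::aov(y ~ subj + occ, data = d)))[["Mean Sq"]]
  icc_aov <- (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / 6)
  expect_equal(r$icc, icc_aov, tolerance = 1e-12)
  expect_equal(r$ms_rows, ms[1], tolerance = 1e-12)
  expect_equal(r$ms_cols, ms[2], tolerance = 1e-12)
  expect_equal(r$ms_error, ms[3], tolerance = 1e-12)

  # invariance to subject ordering
  perm <- shift[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(icc2k(perm)$icc, r$icc, tolerance = 1e-12)

  expect_error(icc2k(shift[1:3, ]), class = "mc_insufficient_data")
  expect_error(icc2k(matrix(1:6, 6, 1)), class = "mc_insufficient_data")
})

test_that("responsiveness battery runs paired signed-rank tests with Bonferroni", {
  base <- data.frame(patient_id = sprintf("p%02d", 1:40), a = rep(4, 40),
                     b = rnorm(40, 10))
  # identical measurements: p = 1 with the all-zero flag
  same <- responsiveness_battery(base, base)
  expect_true(all(same$p_raw == 1))
  expect_true(same$all_zero[same$item == "a"])

  # uniform 2-unit improvement in all 40 pairs
  fup <- base; fup$a <- base$a - 2; fup$b <- base$b - 2
  rb <- responsiveness_battery(base, fup, m_comparisons = 8)
  expect_true(all(rb$p_adjusted < 5e-4))
  expect_true(all(rb$direction == "decrease"))
  expect_true(all(rb$p_adjusted >= rb$p_raw))

  # Bonferroni is plain multiplication, capped at 1
  expect_equal(min(1, 0.02 * 8), 0.16)
  expect_true(all(rb$p_adjusted == pmin(1, rb$p_raw * 8)))
})

test_that("validity correlations flag hypotheses with sign and magnitude", {
  set.seed(13)
  n <- 120
  x <- data.frame(mcs = rnorm(n))
  y <- data.frame(self = x$mcs,
                  anchor = -0.8 * x$mcs + rnorm(n, 0, 0.5),
                  noise = rnorm(n),
                  ordinal = as.numeric(cut(x$mcs + rnorm(n, 0, 0.4), 5)))
  v <- validity_correlations(x, y, spearman_cols = "ordinal",
                             expected_sign = c(anchor = -1, ordinal = 1))
  expect_equal(v$r[v$y == "self"], 1)
  expect_true(v$hypothesis_met[v$y == "anchor"])
  expect_false(v$hypothesis_met[v$y == "noise"])
  expect_equal(v$method[v$y == "ordinal"], "spearman")
  expect_true(v$hypothesis_met[v$y == "ordinal"])
  expect_true(all(v$p_adjusted >= v$p_raw, na.rm = TRUE))

  yc <- data.frame(const = rep(1, n))
  vc <- validity_correlations(x, yc)
  expect_true(vc$constant)
  expect_true(is.na(vc$r))
})
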