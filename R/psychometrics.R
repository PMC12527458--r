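# The psychometric validation battery: factorability tests, exploratory
# factor analysis with promax rotation, internal consistency, test-retest
# reliability, responsiveness and convergent-validity hypotheses.

.as_corr <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && isTRUE(all.equal(unname(diag(x)), rep(1, ncol(x)))) &&
      isTRUE(all.equal(x, t(x), tolerance = 1e-8))) {
    list(R = x, n = NA_integer_)
  } else {
    list(R = stats::cor(x, use = "pairwise.complete.obs"), n = nrow(x))
  }
}

#' Bartlett's test of sphericity
#'
#' Tests the null that the correlation matrix is the identity:
#' chi2 = -(n - 1 - (2p + 5)/6) * log det(R), df = p(p-1)/2. Significance
#' (P < .05) is a precondition for factor analysis.
#'
#' @param R correlation matrix (or raw data matrix, from which a Pearson
#'   correlation matrix is computed).
#' @param n number of observations (taken from the data when a data matrix
#'   is supplied).
#' @return list with \code{chisq}, \code{df}, \code{p_value}.
#' @export
bartlett_sphericity <- function(R, n = NULL) {
  a <- .as_corr(R)
  if (is.null(n)) n <- a$n
  if (is.na(n)) .mc_error("n is required when a correlation matrix is supplied",
                          "mc_validation_error")
  p <- ncol(a$R)
  if (n <= p) .mc_error("need n > number of items", "mc_validation_error")
  detR <- det(a$R)
  if (detR <= 0)
    .mc_error("correlation matrix is numerically singular", "mc_numeric_error")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO = sum r^2 / (sum r^2 + sum q^2) over off-diagonal entries, where q
#' are the anti-image partial correlations obtained from the inverse
#' correlation matrix. Values of at least 0.6 are conventionally deemed
#' adequate for factor analysis.
#'
#' @param R correlation matrix or raw data matrix.
#' @return list with \code{overall} and per-item \code{msa}.
#' @export
kmo <- function(R) {
  a <- .as_corr(R)
  R <- a$R
  Rinv <- tryCatch(solve(R),
                   error = function(e) .mc_error("correlation matrix is not invertible",
                                                 "mc_numeric_error"))
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(d, d)        # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  overall <- sum(R0^2) / (sum(R0^2) + sum(Q^2))
  msa <- colSums(R0^2) / (colSums(R0^2) + colSums(Q^2))
  names(msa) <- colnames(R)
  list(overall = overall, msa = msa)
}

#' Parallel analysis for the number of factors
#'
#' Compares the eigenvalues of the observed correlation matrix with a null
#' built by permuting each column of the data independently (preserving
#' marginals while destroying correlation). The suggested dimensionality is
#' the number of leading observed eigenvalues exceeding the chosen null
#' quantile, counted until the first failure.
#'
#' @param data numeric data matrix (observations x items).
#' @param n_reps permutation replicates (default 500; at least 100).
#' @param quantile null quantile (default 0.95).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return list with \code{n_factors}, observed \code{eigenvalues} and the
#'   null \code{thresholds}.
#' @export
parallel_analysis <- function(data, n_reps = 500L, quantile = 0.95, seed = 1L) {
  if (n_reps < 100L) .mc_error("need n_reps >= 100", "mc_validation_error")
  data <- as.matrix(data)
  obs <- eigen(stats::cor(data), symmetric = TRUE, only.values = TRUE)$values
  p <- ncol(data)
  null_ev <- matrix(NA_real_, n_reps, p)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    perm <- apply(data, 2L, sample)
    null_ev[r, ] <- eigen(stats::cor(perm), symmetric = TRUE,
                          only.values = TRUE)$values
  }
  thr <- apply(null_ev, 2L, stats::quantile, probs = quantile, names = FALSE)
  exceed <- obs > thr
  n_factors <- if (!exceed[1]) 0L else which.min(c(exceed, FALSE)) - 1L
  list(n_factors = n_factors, eigenvalues = obs, thresholds = thr)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ordinary least-squares (minimum-residual) factor extraction: minimize the
# sum of squared off-diagonal residuals of R - LL' over the uniquenesses
.minres_extract <- function(R, m, max_iter = 2000L) {
  p <- ncol(R)
  smc <- 1 - 1 / diag(solve(R))
  start <- pmin(pmax(1 - smc, 0.005), 1)
  objective <- function(psi) {
    S <- R; diag(S) <- 1 - psi
    e <- eigen(S, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(m)], 0)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(ev), m)
    resid <- S - tcrossprod(L)
    sum(resid^2) - sum(diag(resid)^2)
  }
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = 0.005, upper = 1,
                      control = list(maxit = max_iter, factr = 10))
  psi <- opt$par
  S <- R; diag(S) <- 1 - psi
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(m)], 0)
  L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(ev), m)
  list(loadings = L, psi = psi, converged = opt$convergence == 0,
       objective = opt$value)
}

# principal-axis extraction: iterate communalities on the reduced matrix
.pa_extract <- function(R, m, max_iter = 200L, tol = 1e-9) {
  h2 <- 1 - 1 / diag(solve(R))
  for (i in seq_len(max_iter)) {
    S <- R; diag(S) <- h2
    e <- eigen(S, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(m)], 0)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(ev), m)
    h2_new <- rowSums(L^2)
    if (max(abs(h2_new - h2)) < tol) break
    h2 <- h2_new
  }
  list(loadings = L, psi = 1 - rowSums(L^2), converged = i < max_iter,
       objective = NA_real_)
}

# fix the sign convention: the largest-|loading| entry of each factor is
# positive
.fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Exploratory factor analysis
#'
#' Least-squares (minimum-residual) extraction by default, minimizing the
#' squared off-diagonal residuals of the reproduced correlation matrix;
#' principal-axis iteration is available as an alternative. Promax rotation
#' (varimax followed by an oblique power-4 target rotation) returns a
#' pattern matrix and the factor intercorrelation matrix phi. Heywood cases
#' (communalities above 1) are clamped with a warning.
#'
#' @param data raw data matrix or correlation matrix.
#' @param n_factors number of factors (at least 1, fewer than items).
#' @param rotation \code{"promax"} (default for multi-factor models) or
#'   \code{"none"}.
#' @param method \code{"minres"} (default) or \code{"pa"}.
#' @param n_obs number of observations when \code{data} is a correlation
#'   matrix (used for the factorability checks).
#' @param promax_m promax power parameter (default 4).
#' @return list of class \code{factor_model}: \code{loadings} (pattern
#'   matrix), \code{communalities}, \code{uniquenesses}, \code{phi},
#'   \code{eigenvalues} of R, \code{rmsr}, \code{heywood}, \code{method},
#'   \code{rotation}.
#' @export
efa <- function(data, n_factors, rotation = c("promax", "none"),
                method = c("minres", "pa"), n_obs = NULL, promax_m = 4) {
  rotation <- match.arg(rotation)
  method <- match.arg(method)
  a <- .as_corr(data)
  R <- a$R
  if (is.null(n_obs)) n_obs <- a$n
  p <- ncol(R)
  if (n_factors < 1L || n_factors >= p)
    .mc_error("n_factors must be >= 1 and fewer than items", "mc_validation_error")
  if (!is.na(n_obs)) {
    b <- bartlett_sphericity(R, n_obs)
    if (b$p_value >= 0.05)
      warning("Bartlett sphericity not significant; data may not be factorable")
    if (kmo(R)$overall < 0.6)
      warning("KMO < 0.6; sampling adequacy is below the conventional minimum")
  }
  ex <- switch(method, minres = .minres_extract(R, n_factors),
               pa = .pa_extract(R, n_factors))
  L <- .fix_signs(ex$loadings)
  h2 <- rowSums(L^2)
  heywood <- any(h2 > 1 + 1e-8)
  if (heywood) {
    warning("Heywood case: communality above 1, clamped")
    over <- h2 > 1
    L[over, ] <- L[over, , drop = FALSE] / sqrt(h2[over])
    h2 <- rowSums(L^2)
  }
  phi <- diag(n_factors)
  pattern <- L
  if (rotation == "promax" && n_factors > 1L) {
    pm <- stats::promax(L, m = promax_m)
    pattern <- .fix_signs(unclass(pm$loadings))
    ui <- solve(pm$rotmat)
    phi <- stats::cov2cor(tcrossprod(ui))
  }
  model <- pattern %*% phi %*% t(pattern)
  resid <- R - model; diag(resid) <- 0
  rmsr <- sqrt(sum(resid^2) / (p * (p - 1)))
  rownames(pattern) <- colnames(R)
  structure(list(loadings = pattern,
                 communalities = h2,
                 uniquenesses = if (method == "minres") ex$psi else 1 - h2,
                 phi = phi,
                 eigenvalues = eigen(R, symmetric = TRUE, only.values = TRUE)$values,
                 rmsr = rmsr, heywood = heywood,
                 method = method, rotation = rotation,
                 converged = ex$converged),
            class = "factor_model")
}

#' Cronbach's alpha
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the total
#' score).
#'
#' @param items numeric matrix or data.frame, observations x items (at
#'   least 2 items, 3 observations); incomplete rows are dropped.
#' @return alpha as a single number.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2L || nrow(x) < 3L)
    .mc_error("need at least 2 items and 3 observations", "mc_validation_error")
  k <- ncol(x)
  vt <- stats::var(rowSums(x))
  if (vt == 0)
    .mc_error("total-score variance is zero; alpha undefined", "mc_numeric_error")
  k / (k - 1) * (1 - sum(apply(x, 2L, stats::var)) / vt)
}

#' Test-retest reliability: ICC(2,k), absolute agreement
#'
#' Two-way random-effects intraclass correlation for the average of k
#' measurements with absolute agreement:
#' ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n), from the two-way ANOVA
#' mean squares (rows = subjects, columns = occasions). The 95\% confidence
#' interval uses the F-distribution method of Shrout & Fleiss / McGraw &
#' Wong. Incomplete subjects are removed listwise. Values above 0.75
#' indicate good reliability.
#'
#' @param mat numeric matrix, subjects x occasions.
#' @param conf_level confidence level (default 0.95).
#' @return list of class \code{reliability_result}: \code{icc},
#'   \code{ci_low}, \code{ci_high}, \code{ms_rows}, \code{ms_cols},
#'   \code{ms_error}, \code{n_subjects}, \code{k_occasions}.
#' @export
icc2k <- function(mat, conf_level = 0.95) {
  x <- as.matrix(mat)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (k < 2L) .mc_error("need at least 2 occasions", "mc_insufficient_data")
  if (n < 5L) .mc_error("need at least 5 complete subjects", "mc_insufficient_data")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  # CI: exact bounds for the single-rater ICC(2,1), then Spearman-Brown up
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  fa <- (k * icc1) / (n * (1 - icc1))
  fb <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
  v <- (fa * msc + fb * mse)^2 /
    ((fa * msc)^2 / (k - 1) + (fb * mse)^2 / ((n - 1) * (k - 1)))
  f_u <- stats::qf(1 - alpha / 2, n - 1, v)
  f_l <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  sb <- function(r) r * k / (1 + r * (k - 1))
  structure(list(icc = icc, ci_low = sb(l1), ci_high = sb(u1),
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n_subjects = n, k_occasions = k),
            class = "reliability_result")
}

#' Responsiveness battery: paired Wilcoxon tests per item
#'
#' For each item, a paired Wilcoxon signed-rank test compares baseline and
#' follow-up measurements of the same patients (exact null for 25 or fewer
#' non-zero differences, normal approximation with tie correction above),
#' with Bonferroni adjustment over \code{m_comparisons}.
#'
#' @param baseline,followup data.frames with a \code{patient_id} column and
#'   identical item columns; only patients present at both timepoints enter.
#' @param items character vector of item columns (default: all shared
#'   non-id columns).
#' @param m_comparisons Bonferroni multiplier (default: number of items).
#' @return data.frame of class \code{responsiveness_result}: item, n_pairs,
#'   statistic, p_raw, p_adjusted, direction, all_zero flag.
#' @export
responsiveness_battery <- function(baseline, followup, items = NULL,
                                   m_comparisons = NULL) {
  common <- intersect(baseline$patient_id, followup$patient_id)
  b <- baseline[match(common, baseline$patient_id), , drop = FALSE]
  f <- followup[match(common, followup$patient_id), , drop = FALSE]
  if (is.null(items))
    items <- setdiff(intersect(names(baseline), names(followup)),
                     c("patient_id", "timepoint"))
  if (is.null(m_comparisons)) m_comparisons <- length(items)
  rows <- lapply(items, function(it) {
    d <- f[[it]] - b[[it]]
    d <- d[!is.na(d)]
    nz <- d[d != 0]
    if (length(nz) == 0L)
      return(data.frame(item = it, n_pairs = length(d), statistic = NA_real_,
                        p_raw = 1, direction = "none", all_zero = TRUE))
    wt <- suppressWarnings(
      stats::wilcox.test(nz, exact = length(nz) <= 25L && !any(duplicated(abs(nz))),
                         correct = TRUE))
    data.frame(item = it, n_pairs = length(d),
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               direction = if (stats::median(d) < 0) "decrease"
                           else if (stats::median(d) > 0) "increase" else "mixed",
               all_zero = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * m_comparisons)
  class(out) <- c("responsiveness_result", "data.frame")
  out
}

#' Convergent-validity correlation matrix with hypothesis flags
#'
#' Correlates each column of \code{x} (MCSQ items, MCS) with each column of
#' \code{y} (IBDQ-32 total and domains, SHS dimensions, activity status,
#' patient ratings). Pearson is used for interval-scaled validators and
#' Spearman for ordinal ones, per an explicit policy; a hypothesis is
#' flagged as met when |r| reaches \code{r_threshold} with the expected
#' sign.
#'
#' @param x,y data.frames of paired observations.
#' @param spearman_cols columns of \code{y} treated as ordinal (Spearman);
#'   all others use Pearson.
#' @param expected_sign named numeric vector (+1/-1) per column of
#'   \code{y}; defaults to the empirical sign.
#' @param r_threshold hypothesis threshold on |r| (default 0.4).
#' @param m_comparisons Bonferroni multiplier for the significance flags
#'   (default: number of x-y pairs).
#' @return data.frame of class \code{validity_matrix}: x, y, method, r,
#'   p_raw, p_adjusted, hypothesis_met, constant flag.
#' @export
validity_correlations <- function(x, y, spearman_cols = character(),
                                  expected_sign = NULL, r_threshold = 0.4,
                                  m_comparisons = NULL) {
  xs <- names(x); ys <- names(y)
  if (is.null(m_comparisons)) m_comparisons <- length(xs) * length(ys)
  rows <- list()
  for (xv in xs) for (yv in ys) {
    method <- if (yv %in% spearman_cols) "spearman" else "pearson"
    ok <- stats::complete.cases(x[[xv]], y[[yv]])
    if (sum(ok) < 10L)
      .mc_error(sprintf("fewer than 10 complete pairs for %s vs %s", xv, yv),
                "mc_insufficient_data")
    a <- x[[xv]][ok]; b <- y[[yv]][ok]
    constant <- stats::sd(a) == 0 || stats::sd(b) == 0
    if (constant) {
      rows[[length(rows) + 1L]] <- data.frame(
        x = xv, y = yv, method = method, r = NA_real_, p_raw = NA_real_,
        hypothesis_met = FALSE, constant = TRUE)
      next
    }
    ct <- suppressWarnings(stats::cor.test(a, b, method = method))
    r <- unname(ct$estimate)
    sign_ok <- if (!is.null(expected_sign) && yv %in% names(expected_sign))
      sign(r) == sign(expected_sign[[yv]]) else TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      x = xv, y = yv, method = method, r = r, p_raw = ct$p.value,
      hypothesis_met = abs(r) >= r_threshold && sign_ok, constant = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * m_comparisons)
  class(out) <- c("validity_matrix", "data.frame")
  out
}
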