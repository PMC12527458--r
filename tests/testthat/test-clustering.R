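test_that("missingness filter removes rows first, then columns", {
  x <- as.data.frame(matrix(rnorm(100), 10))
  expect_identical(filter_missing(x)$table, x)

  x2 <- x; x2[1, 1:3] <- NA                  # 30% missing row
  f2 <- filter_missing(x2)
  expect_equal(f2$removed_rows, 1L)
  expect_equal(nrow(f2$table), 9)

  # engineered fixture: 129 rows, 2 bad rows, 1 bad column
  set.seed(31)
  big <- as.data.frame(matrix(rnorm(129 * 10), 129))
  big[1, 1:3] <- NA; big[2, 4:6] <- NA       # >20% missing rows
  big[10:40, 7] <- NA                        # ~24% missing column
  fb <- filter_missing(big)
  expect_equal(length(fb$removed_rows), 2)
  expect_equal(dim(fb$table), c(127, 9))
  expect_length(fb$log, 2)

  allna <- x; allna[] <- NA
  expect_error(filter_missing(allna), class = "mc_empty_output")
})

test_that("random-forest imputation preserves observed cells and converges", {
  x <- as.data.frame(matrix(rnorm(200), 20))
  r0 <- rf_impute(x, seed = 1)
  expect_equal(r0$iterations, 0L)
  expect_identical(r0$ximp, x)

  xc <- x; xc$V3 <- 5; xc$V3[4] <- NA        # constant column, one hole
  rc <- rf_impute(xc, n_trees = 30, seed = 1)
  expect_equal(rc$ximp$V3[4], 5, tolerance = 1e-9)

  set.seed(32)
  f <- rnorm(80)
  y <- as.data.frame(outer(f, rep(1, 6)) + matrix(rnorm(480, 0, 0.3), 80))
  holes <- y
  idx <- cbind(sample(80, 25), sample(6, 25, TRUE))
  holes[idx] <- NA
  ri <- rf_impute(holes, n_trees = 60, seed = 2)
  expect_true(all(!is.na(ri$ximp)))
  # observed cells unchanged bit-exactly
  m0 <- as.matrix(y); mi <- as.matrix(ri$ximp)
  expect_identical(mi[!ri$mask], m0[!ri$mask])
  expect_identical(rf_impute(holes, n_trees = 60, seed = 2)$ximp, ri$ximp)

  bad <- x; bad$V1 <- NA
  expect_error(rf_impute(bad), class = "mc_validation_error")
})

test_that("forest imputation beats column-mean imputation on structured data", {
  errs <- vapply(1:5, function(s) {
    set.seed(s)
    f <- rnorm(100)
    truth <- outer(f, seq(0.8, 1.2, length.out = 6)) +
      matrix(rnorm(600, 0, 0.3), 100)
    holes <- truth
    idx <- cbind(sample(100, 30), sample(6, 30, TRUE))
    holes[idx] <- NA
    ximp <- as.matrix(rf_impute(as.data.frame(holes), n_trees = 60,
                                seed = s)$ximp)
    meanimp <- apply(holes, 2, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE); col
    })
    c(rf = sqrt(mean((ximp[idx] - truth[idx])^2)),
      mn = sqrt(mean((meanimp[idx] - truth[idx])^2)))
  }, numeric(2))
  expect_true(all(errs["rf", ] < errs["mn", ]))
})

test_that("PCA embedding is scaled, sign-fixed and variance-ordered", {
  set.seed(33)
  v <- rnorm(50)
  rank1 <- outer(v, c(1, 2, 3))
  e1 <- embed_pca(rank1)
  expect_gt(e1$var_explained[1], 0.999)
  expect_true(all(abs(colMeans(e1$scores)) < 1e-10))
  expect_true(all(diff(e1$var_explained) <= 1e-12))

  noise <- matrix(rnorm(2000 * 5), 2000)
  en <- embed_pca(noise)
  expect_lt(max(en$var_explained) / min(en$var_explained), 1.5)

  withzero <- cbind(as.data.frame(noise[1:30, ]), zc = 1)
  expect_warning(ez <- embed_pca(withzero), "zero-variance")
  expect_false("zc" %in% rownames(ez$loadings))

  # sign convention: largest-|loading| positive, reproducible across calls
  e2 <- embed_pca(noise)
  expect_identical(e1$loadings, embed_pca(rank1)$loadings)
  expect_true(all(vapply(seq_len(ncol(e2$loadings)), function(j) {
    e2$loadings[which.max(abs(e2$loadings[, j])), j] > 0
  }, logical(1))))
})

test_that("JackStraw separates planted structure from pure noise", {
  hits <- vapply(1:10, function(s) {
    set.seed(s + 100)
    noise <- matrix(rnorm(150 * 10), 150)
    jackstraw(noise, n_perm = 150, seed = s)$n_significant
  }, integer(1))
  expect_gte(mean(hits <= 1), 0.9)

  set.seed(34)
  L <- matrix(0, 10, 2); L[1:5, 1] <- 0.8; L[6:10, 2] <- 0.8
  X <- matrix(rnorm(300 * 2), 300) %*% t(L) + matrix(rnorm(3000, 0, 0.6), 300)
  js <- jackstraw(X, n_perm = 300, seed = 4)
  expect_gte(js$n_significant, 2)

  expect_identical(jackstraw(X, n_perm = 120, seed = 7)$p_values,
                   jackstraw(X, n_perm = 120, seed = 7)$p_values)
  expect_error(jackstraw(X, n_perm = 50), class = "mc_validation_error")
})

test_that("SNN Jaccard weights match hand computation", {
  # five points on a line; k = 2 neighbourhoods include the point itself
  pts <- matrix(c(0, 1, 2, 10, 11), ncol = 1)
  g <- snn_graph(pts, k = 2, prune_threshold = 0)
  w <- igraph::as_data_frame(g)
  get_w <- function(a, b) {
    row <- w[(w$from == a & w$to == b) | (w$from == b & w$to == a), ]
    if (nrow(row) == 0) 0 else row$weight
  }
  # N(1)={1,2,3}, N(2)={1,2,3}, N(3)={1,2,3}, N(4)={3,4,5}, N(5)={3,4,5}
  expect_equal(get_w(1, 2), 1)
  expect_equal(get_w(2, 3), 1)
  expect_equal(get_w(4, 5), 1)
  expect_equal(get_w(3, 4), 1 / 5)   # share {3}: 1 / (3 + 3 - 1)
  expect_equal(get_w(1, 4), 1 / 5)
  expect_equal(get_w(1, 5), 1 / 5)

  # two well-separated blobs share no neighbourhoods at k = 10
  set.seed(35)
  blobs <- rbind(matrix(rnorm(60, 0, 0.5), 30),
                 matrix(rnorm(60, 50, 0.5), 30))
  gb <- snn_graph(blobs, k = 10)
  ends <- igraph::ends(gb, igraph::E(gb))
  expect_true(all((ends[, 1] <= 30) == (ends[, 2] <= 30)))

  # duplicated points are each other's twin with Jaccard 1
  dup <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40), 20)[1, , drop = FALSE])
  dup[21, ] <- dup[1, ]
  gd <- snn_graph(dup, k = 3, prune_threshold = 0)
  wd <- igraph::as_data_frame(gd)
  expect_equal(wd$weight[(wd$from == 1 & wd$to == 21)], 1)
})

test_that("Leiden partition finds components and planted communities", {
  g2 <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
  igraph::E(g2)$weight <- 1
  p2 <- leiden_partition(g2, seed = 1)
  expect_equal(p2$n_clusters, 2)
  expect_equal(sort(unique(p2$labels)), c(0L, 1L))

  aris <- vapply(1:3, function(s) {
    set.seed(s)
    pm <- matrix(0.02, 4, 4); diag(pm) <- 0.5
    g <- igraph::sample_sbm(120, pref.matrix = pm, block.sizes = rep(30, 4))
    igraph::E(g)$weight <- 1
    p <- leiden_partition(g, seed = s)
    ari(p$labels, rep(1:4, each = 30))
  }, numeric(1))
  expect_gte(mean(aris), 0.9)

  p <- leiden_partition(g2, seed = 42)
  expect_identical(leiden_partition(g2, seed = 42)$labels, p$labels)

  empty <- igraph::make_empty_graph(5, directed = FALSE)
  expect_warning(pe <- leiden_partition(empty), "no edges")
  expect_equal(pe$n_clusters, 5)
})

test_that("clusters are annotated by burden order from the extremes inward", {
  feats <- data.frame(mean_loose = c(rep(0, 10), rep(5, 10)),
                      ibdq_total = c(rep(210, 10), rep(120, 10)))
  ann <- annotate_clusters(rep(c(0, 1), each = 10), feats)
  expect_equal(ann$mapping$severity, c("remission", "severe"))
  expect_equal(unique(ann$annotation[1:10]), "remission")

  # five strictly ordered clusters use all five labels in order
  f5 <- data.frame(mean_loose = rep(0:4 * 2, each = 8),
                   ibdq_total = rep(seq(210, 120, length.out = 5), each = 8))
  a5 <- annotate_clusters(rep(0:4, each = 8), f5)
  expect_equal(a5$mapping$severity,
               c("remission", "partial remission", "mild", "moderate", "severe"))

  # exact burden ties break by size, deterministically
  ft <- data.frame(mean_loose = c(rep(1, 6), rep(1, 4)),
                   ibdq_total = c(rep(200, 6), rep(200, 4)))
  at <- annotate_clusters(rep(c(0, 1), c(6, 4)), ft)
  expect_equal(at$mapping$label[1], 0)   # larger cluster ranked first
  expect_length(at$tie_log, 1)
})

test_that("the full severity pipeline recovers planted strata", {
  sim <- generate_cohort(generator_config(seed = 101))
  tabl <- cohort_analysis_table(sim)
  bl <- tabl[tabl$timepoint == "baseline", ]
  cl <- suppressWarnings(cluster_severity(bl[, cluster_feature_cols()],
                                          jackstraw_n_perm = 200, seed = 101))
  truth <- sim$truth[sim$truth$timepoint == "baseline", ]
  strat <- truth$stratum[match(bl$patient_id[cl$kept_rows], truth$patient_id)]
  expect_gte(ari(cl$labels, strat), 0.7)
  expect_true(cl$n_clusters >= 4 && cl$n_clusters <= 7)
  expect_length(cl$annotation, length(cl$labels))
  # determinism of the whole chain under a fixed seed
  cl2 <- suppressWarnings(cluster_severity(bl[, cluster_feature_cols()],
                                           jackstraw_n_perm = 200, seed = 101))
  expect_identical(cl$labels, cl2$labels)
  expect_identical(cl$annotation, cl2$annotation)
})
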