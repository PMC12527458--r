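test_that("anchor regression recovers exact and null relations", {
  x <- seq(0, 5, length.out = 40)
  f <- suppressWarnings(fit_anchor_regression(x, 200 - 6 * x))
  expect_equal(f$slope, -6, tolerance = 1e-10)
  expect_equal(f$intercept, 200, tolerance = 1e-8)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-10)
  expect_true(f$ci_low <= f$slope && f$slope <= f$ci_high)

  expect_error(fit_anchor_regression(rep(2, 30), rnorm(30)),
               class = "mc_degenerate_predictor")
  expect_error(fit_anchor_regression(1:5, 1:5), class = "mc_validation_error")

  # permutation: with y detached from x the slope CI covers 0 ~95% of runs
  set.seed(21)
  y <- 200 - 6 * x + rnorm(40, 0, 10)
  cover <- vapply(1:60, function(i) {
    fp <- fit_anchor_regression(x, sample(y))
    fp$ci_low <= 0 && fp$ci_high >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("cut-off derivation recovers exact unit category boundaries", {
  # four exact categories, IBDQ drops 17.5 per category: the only partition
  # with all three adjacent gaps inside [15, 20] cuts at the unit mid-points
  x <- rep(0:3, each = 8)
  y <- 200 - 17.5 * x
  e <- suppressWarnings(derive_item_cutoffs(x, y, "mean_pain"))
  expect_equal(e$thresholds, c(0.5, 1.5, 2.5))
  expect_equal(e$points, 0:3)
  expect_equal(unname(attr(e, "gaps")), rep(17.5, 3))
  expect_true(all(attr(e, "in_window")))
})

test_that("flat and steep anchor relations degrade as designed", {
  set.seed(4)
  x <- runif(60, 0, 3)
  flat <- derive_item_cutoffs(x, rnorm(60, 180, 5), "mean_pain")
  expect_true(flat$flat)
  expect_equal(max(flat$points), 0L)

  # a 40-point-per-unit drop forces narrow categories; every reported
  # in-window gap must actually lie inside the window
  steep <- derive_item_cutoffs(x, 200 - 40 * x + rnorm(60, 0, 3), "mean_pain")
  gaps <- attr(steep, "gaps")
  expect_true(any(attr(steep, "in_window")))
  expect_true(all(gaps[attr(steep, "in_window")] >= 15 &
                  gaps[attr(steep, "in_window")] <= 20))
  expect_lte(max(steep$points), 3)
})

test_that("cut-off search is deterministic and respects occupancy", {
  set.seed(9)
  x <- rep(0:3, each = 10) + runif(40)
  y <- 202.3 - 17.5 * rep(0:3, each = 10) + rnorm(40, 0, 5)
  e1 <- derive_item_cutoffs(x, y, "mean_loose")
  e2 <- derive_item_cutoffs(x, y, "mean_loose")
  expect_identical(e1$thresholds, e2$thresholds)
  expect_true(all(attr(e1, "category_counts") >= 5))
})

test_that("diarrhea-item selection finds the generating predictor", {
  gen <- function(seed, driver = c("loose", "b7")) {
    driver <- match.arg(driver)
    set.seed(seed)
    n <- 150
    b6 <- rpois(n, 1.2); b7 <- rpois(n, 1.5)
    loose <- b6 + b7
    y <- if (driver == "loose") 210 - 9 * loose + rnorm(n, 0, 12)
         else 210 - 14 * b7 + rnorm(n, 0, 12)
    data.frame(mean_loose = loose, mean_b6 = b6, mean_b7 = b7, y = y)
  }
  hits <- vapply(1:20, function(s) {
    d <- gen(s, "loose")
    select_diarrhea_item(d, d$y)$chosen == "mean_loose"
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  d <- gen(1, "loose")
  sel <- select_diarrhea_item(d, d$y)
  expect_false(sel$meaningful_gain)
  expect_equal(nrow(sel$models), 6)   # 3 univariate + 3 bivariate, no triple

  hits_b7 <- vapply(1:20, function(s) {
    d <- gen(s, "b7")
    select_diarrhea_item(d, d$y)$chosen == "mean_b7"
  }, logical(1))
  expect_gte(mean(hits_b7), 0.9)

  set.seed(2)
  noise <- data.frame(mean_b6 = rpois(80, 1), mean_b7 = rpois(80, 1))
  noise$mean_loose <- noise$mean_b6 + noise$mean_b7
  expect_true(select_diarrhea_item(noise, rnorm(80, 180, 10))$flat)
})

test_that("score-table assembly drops excluded items and enforces 15 points", {
  mk <- function(it) score_table_entry(it, c(1, 2, 3))
  entries <- lapply(mcs_items(), mk)
  expect_s3_class(assemble_score_table(entries), "score_table")

  expect_warning(tab <- assemble_score_table(c(entries, list(mk("mean_solid")))),
                 "dropping excluded")
  expect_s3_class(tab, "score_table")

  expect_error(assemble_score_table(entries[1:4]), class = "mc_config_error")

  short <- entries
  short[[2]] <- score_table_entry("mean_nocturnal", c(1, 2), 0:2)
  expect_error(assemble_score_table(short), class = "mc_config_error")

  over <- entries
  over[[1]] <- score_table_entry("mean_loose", c(1, 2, 3, 4), 0:4)
  expect_warning(tab2 <- assemble_score_table(over), "merging top categories")
  expect_equal(max(tab2$mean_loose$points), 3L)
})

test_that("full calibration on a synthetic cohort mirrors the analysis logic", {
  sim <- generate_cohort(generator_config(n_patients = 250L, seed = 11))
  tabl <- cohort_analysis_table(sim)
  ok <- !is.na(tabl$ibdq_total)
  cal <- suppressWarnings(calibrate_score_table(tabl[ok, ], tabl$ibdq_total[ok],
                                                strict = FALSE))
  expect_equal(cal$selection$chosen, "mean_loose")
  expect_false(cal$selection$meaningful_gain)
  expect_true(all(vapply(cal$entries, function(e)
    all(attr(e, "gaps")[attr(e, "in_window")] >= 15), logical(1))))
  f <- cal$fits$mean_loose
  expect_lt(f$slope, 0)
  expect_gt(f$adjusted_r2, 0.3)
})
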