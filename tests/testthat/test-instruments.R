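test_that("diary summaries compute weekly aggregates correctly", {
  s0 <- summarize_diary(make_diary())
  expect_true(all(unlist(s0[1:9]) == 0))

  s <- summarize_diary(make_diary(b7 = 2, solid = 1))
  expect_equal(s$mean_b7, 2)
  expect_equal(s$mean_loose, 2)
  expect_equal(s$mean_solid, 1)
  expect_equal(s$mean_total, 3)

  s2 <- summarize_diary(make_diary(b7 = c(3, 1, 0, 2, 1, 0, 0)))
  expect_equal(s2$mean_b7, 1.0)
  expect_equal(s2$mean_loose, s2$mean_b6 + s2$mean_b7)
})

test_that("diary summaries are invariant to day order", {
  set.seed(5)
  for (i in 1:10) {
    d <- make_diary(b6 = sample(0:3, 7, TRUE), b7 = sample(0:4, 7, TRUE),
                    solid = sample(0:2, 7, TRUE), urgency = sample(0:1, 7, TRUE),
                    leakage = sample(0:1, 7, TRUE), pain = sample(0:3, 7, TRUE))
    d$nocturnal <- pmin(d$total, sample(0:2, 7, TRUE))
    perm <- d[sample(7), ]
    expect_equal(unclass(summarize_diary(d)), unclass(summarize_diary(perm)))
  }
})

test_that("partial diaries are averaged over recorded days and rescaled", {
  d <- make_diary(b7 = 2, urgency = 1, days = 4)
  s <- summarize_diary(d)
  expect_true(s$partial)
  expect_equal(s$n_days, 4)
  expect_equal(s$mean_b7, 2)
  expect_equal(s$urgency_days, 7)   # 4 of 4 days scaled to a full week

  expect_error(summarize_diary(make_diary(days = 3)),
               class = "mc_incomplete_diary")
  bad <- make_diary(); bad$bristol7[1] <- -1
  expect_error(summarize_diary(bad), class = "mc_validation_error")
  dup <- make_diary(); dup$day_index[2] <- 1
  expect_error(summarize_diary(dup), class = "mc_validation_error")
  over <- make_diary(b7 = 1); over$nocturnal <- 2   # nocturnal > total
  expect_error(summarize_diary(over), class = "mc_validation_error")
})

test_that("Hjortswang criteria fire at the printed thresholds", {
  expect_true(hjortswang_classify(make_summary(mean_total = 3))$active)
  expect_equal(hjortswang_classify(make_summary(mean_total = 3))$rule_fired,
               "stool_frequency")
  r <- hjortswang_classify(make_summary(mean_total = 2.9, mean_b7 = 0.9))
  expect_false(r$active)
  expect_equal(r$rule_fired, "none")
  w <- hjortswang_classify(make_summary(mean_total = 1, mean_b7 = 1))
  expect_true(w$active)
  expect_equal(w$rule_fired, "watery")
  expect_equal(hjortswang_classify(make_summary(mean_total = 4, mean_b7 = 2))$rule_fired,
               "both")
  # boundary exactness
  expect_false(hjortswang_classify(make_summary(mean_total = 3 - 1e-9))$active)
  expect_false(hjortswang_classify(make_summary(mean_b7 = 1 - 1e-9))$active)
  expect_true(hjortswang_classify(make_summary(mean_b7 = 1))$active)
})

test_that("activity classification is monotone in both criteria inputs", {
  grid <- expand.grid(mt = seq(0, 5, by = 0.25), b7 = seq(0, 2, by = 0.25))
  act <- mapply(function(mt, b7)
    hjortswang_classify(make_summary(mean_total = mt, mean_b7 = b7))$active,
    grid$mt, grid$b7)
  for (i in seq_len(nrow(grid))) {
    if (!act[i]) next
    worse <- grid$mt >= grid$mt[i] & grid$b7 >= grid$b7[i]
    expect_true(all(act[worse]))
  }
})

test_that("IBDQ-32 scoring reproduces instrument ranges and domain sums", {
  top <- score_ibdq(rep(7, 32))
  expect_equal(top$total, 224)
  bottom <- score_ibdq(rep(1, 32))
  expect_equal(bottom$total, 32)
  expect_equal(bottom$bowel, 10)
  expect_equal(bottom$systemic, 5)
  expect_equal(bottom$social, 5)
  expect_equal(bottom$emotional, 12)

  r <- rep(1, 32); r[ibdq_domain_map()$bowel] <- 7
  expect_equal(score_ibdq(r)$bowel, 70)

  set.seed(3)
  for (i in 1:20) {
    resp <- sample(1:7, 32, TRUE)
    sc <- score_ibdq(resp)
    expect_equal(sc$total, sc$bowel + sc$systemic + sc$social + sc$emotional)
    expect_true(sc$total >= 32 && sc$total <= 224)
  }

  expect_error(score_ibdq(c(rep(4, 31), NA)), class = "mc_missing_data")
  expect_error(score_ibdq(c(rep(4, 31), 9)), class = "mc_validation_error")
  expect_error(score_ibdq(rep(4, 31)), class = "mc_validation_error")
})

test_that("SHS dimensions map through unchanged", {
  expect_equal(unlist(score_shs(c(1, 1, 1, 1))), c(symptoms = 1, functioning = 1,
                                                   worry = 1, wellbeing = 1))
  expect_equal(score_shs(c(6, 6, 6, 6))$wellbeing, 6)
  s <- score_shs(c(3, 2, 5, 4))
  expect_equal(s$symptoms, 3); expect_equal(s$functioning, 2)
  expect_equal(s$worry, 5); expect_equal(s$wellbeing, 4)
  expect_error(score_shs(c(0, 2, 3, 4)), class = "mc_validation_error")
})

test_that("cohort table audit reports violations, duplicates, missingness", {
  tab <- data.frame(patient_id = c("a", "b"), timepoint = "baseline",
                    ibdq_01 = c(3, 4), shs_symptoms = c(2, 5),
                    patient_symptom_rating = c(0, 3))
  v <- validate_cohort_table(tab)
  expect_true(v$clean)
  expect_equal(nrow(v$violations), 0)

  tab$ibdq_01[2] <- 9
  v2 <- validate_cohort_table(tab)
  expect_equal(nrow(v2$violations), 1)
  expect_equal(v2$violations$column, "ibdq_01")

  tab$ibdq_01[2] <- 4
  tab2 <- rbind(tab, tab[1, ])
  v3 <- validate_cohort_table(tab2)
  expect_equal(length(v3$duplicates), 1)

  tab$shs_symptoms[1] <- NA
  expect_equal(unname(validate_cohort_table(tab)$col_missing["shs_symptoms"]), 0.5)
})

test_that("prorated sum scores tolerate sporadic missingness only", {
  m <- matrix(4, 3, 10)
  m[1, 1] <- NA            # 10% missing -> prorated
  m[2, 1:4] <- NA          # 40% missing -> NA
  ps <- prorated_score(m)
  expect_equal(ps[1], 40)
  expect_true(is.na(ps[2]))
  expect_equal(ps[3], 40)
})

test_that("CSV readers enforce schema and report missingness", {
  path <- tempfile(fileext = ".csv")
  d <- cbind(data.frame(patient_id = "p1", timepoint = "baseline"),
             make_diary(b7 = 1))
  utils::write.csv(d, path, row.names = FALSE)
  rd <- read_diary_csv(path)
  expect_equal(nrow(rd), 7)
  expect_true(all(attr(rd, "col_missing") == 0))

  utils::write.csv(d[, -4], path, row.names = FALSE)
  expect_error(read_diary_csv(path), class = "mc_schema_error")
})
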