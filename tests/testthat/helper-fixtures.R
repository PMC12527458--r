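# Fixture builders shared across the suite. All data are generated in code;
# the psychometric fixtures are literal so that the frozen reference values
# (computed once with an independent implementation) stay attached to
# exactly these numbers.

# one diary with constant (or recycled) per-day values
make_diary <- function(total = NULL, b6 = 0, b7 = 0, solid = 0, noct = 0,
                       urgency = 0, leakage = 0, pain = 0, days = 7) {
  b6 <- rep(b6, length.out = days); b7 <- rep(b7, length.out = days)
  solid <- rep(solid, length.out = days)
  if (is.null(total)) total <- b6 + b7 + solid
  data.frame(day_index = seq_len(days), total = rep(total, length.out = days),
             nocturnal = rep(noct, length.out = days),
             bristol6 = b6, bristol7 = b7, solid = solid,
             urgency = rep(urgency, length.out = days),
             leakage = rep(leakage, length.out = days),
             pain = rep(pain, length.out = days))
}

# weekly summary stub with overridable fields
make_summary <- function(...) {
  s <- list(mean_total = 0, mean_nocturnal = 0, mean_b6 = 0, mean_b7 = 0,
            mean_loose = 0, mean_solid = 0, urgency_days = 0,
            leakage_days = 0, mean_pain = 0)
  over <- list(...)
  s[names(over)] <- over
  structure(s, class = "mcsq_summary")
}

# 60 x 5 Likert fixture (single common factor); frozen reference values were
# computed once with pingouin / numpy / scikit-learn on these exact numbers
fx_items <- function() {
  matrix(c(
    5, 3, 5, 6, 4, 5, 6, 5, 7, 5, 5, 7, 3, 3, 3, 5, 4, 1, 1, 5, 5, 2, 4, 5,
    5, 4, 3, 2, 5, 4, 6, 4, 6, 4, 4, 1, 2, 2, 1, 5, 5, 4, 4, 5, 2, 5, 3, 6,
    4, 5, 4, 3, 6, 4, 3, 4, 4, 7, 1, 4, 4, 2, 5, 4, 4, 3, 5, 2, 5, 4, 6, 6,
    2, 5, 5, 4, 4, 2, 1, 6, 4, 1, 3, 5, 6, 4, 3, 1, 5, 2, 5, 3, 6, 3, 4, 1,
    3, 2, 1, 5, 4, 3, 5, 3, 3, 6, 2, 6, 4, 6, 4, 4, 4, 6, 5, 4, 4, 5, 1, 4,
    6, 3, 5, 5, 4, 3, 6, 4, 6, 2, 6, 6, 3, 3, 3, 6, 4, 2, 3, 6, 2, 2, 5, 7,
    5, 2, 3, 1, 4, 3, 3, 7, 5, 3, 5, 2, 3, 4, 1, 3, 5, 3, 4, 2, 3, 4, 4, 5,
    3, 6, 4, 4, 5, 4, 4, 4, 6, 4, 1, 3, 5, 4, 6, 6, 3, 6, 6, 4, 7, 3, 4, 6,
    1, 4, 5, 4, 3, 1, 1, 5, 4, 3, 4, 4, 6, 5, 4, 2, 2, 3, 5, 5, 5, 4, 4, 3,
    4, 2, 3, 5, 5, 2, 4, 4, 3, 5, 5, 5, 2, 5, 4, 4, 5, 7, 4, 4, 5, 5, 1, 3,
    5, 4, 4, 5, 4, 4, 6, 5, 5, 4, 5, 6, 2, 3, 4, 4, 3, 2, 1, 6, 3, 2, 4, 5,
    7, 3, 5, 2, 4, 3, 5, 4, 4, 4, 5, 2, 2, 2, 1, 4, 4, 4, 4, 2, 3, 5, 4, 4,
    4, 6, 5, 2, 6, 4, 4, 5, 4, 5, 1, 3), nrow = 60)
}

# 9 x 2 test-retest fixture; frozen pingouin ICC(2,k) reference
fx_icc <- function() {
  matrix(c(19.1, 6.8, 10.6, 11, 7.4, 9.1, 12.7, 8.8, 10.2,
           16.9, 7.4, 8.8, 9.5, 8.4, 5.8, 13.5, 9.8, 11.2), ncol = 2)
}

# tie-heavy ROC fixture; frozen scikit-learn AUC reference
fx_roc <- function() {
  list(scores = c(3, 1, 2, 4, 2, 5, 6, 2, 7, 3, 5, 1),
       labels = c(0, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 0))
}

# Mann-Whitney concordance probability, the pairwise oracle for AUC
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# analysis table (weekly summaries + scores + questionnaire scores) from a
# synthetic cohort, as assembled by the pipeline
cohort_analysis_table <- function(sim) {
  s <- summarize_diaries(sim$diary)
  sc <- score_cohort(s)
  q <- sim$cohort
  ic <- sprintf("ibdq_%02d", 1:32)
  q$ibdq_total <- prorated_score(q[ic])
  dm <- ibdq_domain_map()
  for (d in names(dm)) q[[paste0("ibdq_", d)]] <- prorated_score(q[ic[dm[[d]]]])
  merge(sc, q, by = c("patient_id", "timepoint"), sort = FALSE,
        suffixes = c("", ".q"))
}

cluster_feature_cols <- function() {
  c("mean_total", "mean_nocturnal", "mean_b6", "mean_b7", "mean_loose",
    "mean_solid", "urgency_days", "leakage_days", "mean_pain", "ibdq_total",
    "ibdq_bowel", "ibdq_systemic", "ibdq_social", "ibdq_emotional",
    "shs_symptoms", "shs_function", "shs_worry", "shs_wellbeing",
    "patient_symptom_rating", "age", "sex_female", "disease_duration")
}

# adjusted Rand index (contingency-table formula), kept independent of any
# clustering library
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab))); sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
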