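# Synthetic two-timepoint cohort generator. A latent severity stratum
# (remission, partial remission, mild, moderate, severe) drives the 7-day
# diary items; health-related quality of life follows the linear anchor
# relation IBDQ-32 total = 202.3 - 6.0 x MCS plus Gaussian noise; remission
# patients are retested unchanged while active patients are treated and
# shift down two strata at follow-up.

.strata <- c("remission", "partial remission", "mild", "moderate", "severe")

# per-stratum latent item-category centers, items in mcs_items() order
# (loose, nocturnal, urgency, leakage, pain); chosen so that expected MCS
# rises strictly across strata (~0.5 / 3 / 6 / 9 / 14) and the remission
# stratum virtually never meets the Hjortswang activity criteria
.stratum_centers <- rbind(
  remission           = c(-0.4, -0.3, -0.3, -0.4, -0.3),
  `partial remission` = c(1.0, 1.0, 1.0, 0.0, 1.0),
  mild                = c(2.0, 1.0, 1.0, 1.0, 1.0),
  moderate            = c(2.0, 2.0, 2.0, 2.0, 1.0),
  severe              = c(3.0, 3.0, 3.0, 3.0, 2.0)
)

# share of loose stools that are watery (Bristol 7) per stratum: moderate
# and severe disease are driven by watery rather than fluffy diarrhea
.b7_fraction <- c(0.15, 0.25, 0.60, 0.85, 0.90)

# solid stools recede as diarrhea takes over: per-stratum uniform range for
# the weekly mean of solid stools per day
.solid_range <- rbind(c(0.7, 1.5), c(0.3, 0.9), c(0.2, 0.8),
                      c(0.1, 0.6), c(0.0, 0.4))

#' Generator configuration for synthetic cohorts
#'
#' Defaults emulate the validation study's shape: 131 patients, roughly 1:1
#' remission to active disease at baseline, the IBDQ anchor relation with
#' intercept 202.3 and slope -6.0 IBDQ points per MCS point (noise SD 20),
#' a test-retest reliability target of ICC(2,k) = 0.88, 15\% IBS
#' comorbidity and ~3\% residual missingness.
#'
#' @param n_patients cohort size (default 131).
#' @param strata_weights probabilities of the five severity strata
#'   (remission, partial remission, mild, moderate, severe); the default
#'   puts ~0.49 of patients into Hjortswang-active states.
#' @param ibdq_intercept,ibdq_slope,ibdq_noise_sd the linear anchor
#'   relation from true MCS to IBDQ-32 total.
#' @param retest_icc target test-retest ICC(2,k) for the paired-occasion
#'   simulator.
#' @param treatment_shift strata by which treated active patients improve
#'   at follow-up (default 2).
#' @param followup_rate fraction of patients responding at follow-up.
#' @param missing_rate MCAR cell-masking rate applied to the wide table.
#' @param ibs_prevalence probability of the IBS comorbidity flag.
#' @param latent_sd,item_sd patient-level and item-level spread of the
#'   latent item categories around the stratum centers.
#' @param seed integer master seed.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_patients = 131L,
                             strata_weights = c(0.26, 0.25, 0.17, 0.17, 0.15),
                             ibdq_intercept = 202.3, ibdq_slope = -6.0,
                             ibdq_noise_sd = 20, retest_icc = 0.88,
                             treatment_shift = 2L, followup_rate = 0.87,
                             missing_rate = 0.033, ibs_prevalence = 0.15,
                             latent_sd = 0.10, item_sd = 0.15, seed = 1L) {
  if (length(strata_weights) != 5L || any(strata_weights < 0) ||
      abs(sum(strata_weights) - 1) > 1e-8)
    .mc_error("strata_weights must be 5 non-negative values summing to 1",
              "mc_config_error")
  if (ibdq_noise_sd <= 0) .mc_error("noise sd must be positive", "mc_config_error")
  if (missing_rate < 0 || missing_rate >= 0.5)
    .mc_error("missing_rate must lie in [0, 0.5)", "mc_config_error")
  structure(as.list(environment()), class = "generator_config")
}

# allocate `total` integer units over cells with per-cell caps, at random
.alloc_capped <- function(total, cap) {
  n <- length(cap)
  total <- min(total, sum(cap))
  alloc <- rep(0L, n)
  if (total == 0L) return(alloc)
  raw <- as.integer(stats::rmultinom(1L, total, rep(1, n)))
  alloc <- pmin(raw, cap)
  excess <- total - sum(alloc)
  while (excess > 0L) {
    room <- which(alloc < cap)
    take <- room[seq_len(min(excess, length(room)))]
    alloc[take] <- alloc[take] + 1L
    excess <- total - sum(alloc)
  }
  alloc
}

# draw a weekly target value inside category `cat` of a score-table entry,
# keeping a margin so that integer day counts cannot leave the interval
.target_in_category <- function(cat, thresholds, top_span) {
  edges <- c(0, thresholds, thresholds[length(thresholds)] + top_span)
  lo <- edges[cat + 1L]; hi <- edges[cat + 2L]
  lo + (0.3 + 0.4 * stats::runif(1)) * (hi - lo)
}

# one diary for a patient with latent offset u in stratum `stratum` (1-5);
# uses the ambient RNG stream
.gen_diary_days <- function(stratum, u, cfg) {
  centers <- .stratum_centers[stratum, ]
  cats <- pmin(pmax(round(centers + u + stats::rnorm(5, 0, cfg$item_sd)), 0), 3)
  tab <- default_score_table()
  # loose stools -> total = loose + solid
  t_loose <- round(7 * .target_in_category(cats[1], tab$mean_loose$thresholds, 3))
  b7_tot <- stats::rbinom(1L, t_loose, .b7_fraction[stratum])
  b6_tot <- t_loose - b7_tot
  t_solid <- round(7 * stats::runif(1, .solid_range[stratum, 1],
                                    .solid_range[stratum, 2]))
  b6 <- .alloc_capped(b6_tot, rep(20L, 7))
  b7 <- .alloc_capped(b7_tot, rep(20L, 7))
  solid <- .alloc_capped(t_solid, rep(20L, 7))
  total <- b6 + b7 + solid
  t_noct <- round(7 * .target_in_category(cats[2], tab$mean_nocturnal$thresholds, 2))
  noct <- .alloc_capped(t_noct, total)
  urg_sets <- list(0:1, 2:3, 4:5, 6:7)
  n_urg <- sample(urg_sets[[cats[3] + 1L]], 1L)
  urgency <- integer(7); urgency[sample.int(7, n_urg)] <- 1L
  leak_sets <- list(0L, 1:2, 3:4, 5:7)
  n_leak <- sample(leak_sets[[cats[4] + 1L]], 1L)
  leakage <- integer(7); leakage[sample.int(7, n_leak)] <- 1L
  t_pain <- round(7 * .target_in_category(cats[5], tab$mean_pain$thresholds, 0.5))
  pain <- .alloc_capped(t_pain, rep(3L, 7))
  data.frame(day_index = 1:7, total = total, nocturnal = noct,
             bristol6 = b6, bristol7 = b7, solid = solid,
             urgency = urgency, leakage = leakage, pain = pain)
}

#' Generate a single 7-day diary for a severity stratum
#'
#' @param stratum stratum name or index 1-5 (remission .. severe).
#' @param seed integer seed.
#' @param config a \code{\link{generator_config}}.
#' @return data.frame of 7 diary days (see \code{\link{summarize_diary}}).
#' @export
generate_diary <- function(stratum, seed = 1L, config = generator_config()) {
  if (is.character(stratum)) stratum <- match(stratum, .strata)
  if (is.na(stratum) || stratum < 1L || stratum > 5L)
    .mc_error("unknown severity stratum", "mc_config_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- stats::rnorm(1, 0, config$latent_sd)
  .gen_diary_days(stratum, u, config)
}

# allocate an IBDQ-32 target total to 32 item responses in 1..7: domain
# sub-totals get zero-sum wobble (domains covary imperfectly in real data
# while the instrument total is preserved exactly), then items realize each
# domain target with small jitter
.alloc_ibdq_items <- function(target, domain_sd = 5) {
  target <- round(min(max(target, 32), 224))
  dm <- ibdq_domain_map()
  sizes <- lengths(dm)
  share <- sizes / 32
  e <- stats::rnorm(4, 0, domain_sd)
  e <- e - share * sum(e)                          # zero-sum wobble
  dtarget <- round(share * target + e)
  dtarget <- pmin(pmax(dtarget, sizes), 7 * sizes)
  dtarget[1] <- dtarget[1] + (target - sum(dtarget))
  dtarget[1] <- min(max(dtarget[1], sizes[1]), 7 * sizes[1])
  v <- integer(32)
  for (d in seq_along(dm)) {
    idx <- dm[[d]]
    mu <- dtarget[d] / sizes[d]
    vi <- pmin(pmax(round(mu + stats::rnorm(sizes[d], 0, 0.7)), 1), 7)
    diff <- dtarget[d] - sum(vi)
    i <- 1L
    while (diff != 0L) {
      step <- sign(diff)
      if ((step > 0 && vi[i] < 7) || (step < 0 && vi[i] > 1)) {
        vi[i] <- vi[i] + step
        diff <- diff - step
      }
      i <- if (i == sizes[d]) 1L else i + 1L
    }
    v[idx] <- vi
  }
  # absorb any clamping shortfall anywhere with room
  diff <- target - sum(v)
  i <- 1L
  while (diff != 0L && i <= 64L) {
    j <- (i - 1L) %% 32L + 1L
    step <- sign(diff)
    if ((step > 0 && v[j] < 7) || (step < 0 && v[j] > 1)) {
      v[j] <- v[j] + step
      diff <- diff - step
    }
    i <- i + 1L
  }
  v
}

#' Generate HRQoL responses from a true MCS value
#'
#' IBDQ-32 item responses realize a target total of
#' intercept + slope x MCS + N(0, sd^2), clamped to the 32-224 instrument
#' range and allocated greedily across items within the 1-7 bounds. SHS
#' dimensions and the patient symptom rating are monotone noisy maps of the
#' MCS onto their ordinal scales.
#'
#' @param true_mcs integer 0-15; drives the IBDQ anchor relation.
#' @param config a \code{\link{generator_config}}.
#' @param seed integer seed (NULL to use the ambient RNG stream).
#' @param severity overall disease state on the 0-15 scale driving the SHS
#'   and patient-rating maps; defaults to \code{true_mcs}. The cohort
#'   generator passes the latent stratum here, reflecting that global
#'   health perception tracks the broader illness, not only the diary
#'   week.
#' @return list with \code{ibdq} (32 responses), \code{ibdq_total_target},
#'   \code{shs} (4 responses), \code{rating} (0-3).
#' @export
generate_hrqol <- function(true_mcs, config = generator_config(), seed = NULL,
                           severity = true_mcs) {
  if (true_mcs < 0 || true_mcs > 15)
    .mc_error("true_mcs must lie in 0-15", "mc_validation_error")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  target <- config$ibdq_intercept + config$ibdq_slope * true_mcs +
    stats::rnorm(1, 0, config$ibdq_noise_sd)
  target <- min(max(target, 32), 224)
  ibdq <- .alloc_ibdq_items(target)
  shs <- pmin(pmax(round(1 + 5 * severity / 15 + stats::rnorm(4, 0, 0.6)), 1), 6)
  rating <- pmin(pmax(round(3 * severity / 15 + stats::rnorm(1, 0, 0.4)), 0), 3)
  list(ibdq = ibdq, ibdq_total_target = target, shs = shs, rating = rating)
}

# one patient-timepoint row (wide) + diary block + truth row
.gen_patient_timepoint <- function(pid, timepoint, stratum, u, treated, cfg) {
  days <- .gen_diary_days(stratum, u, cfg)
  s <- summarize_diary(days)
  mcs <- compute_mcs(s)$mcs
  hr <- generate_hrqol(mcs, cfg, severity = (stratum - 1) * 15 / 4)
  transition <- if (treated) sample(c("much better", "better"), 1L)
    else sample(c("better", "same", "worse"), 1L, prob = c(0.15, 0.7, 0.15))
  wide <- data.frame(patient_id = pid, timepoint = timepoint,
                     as.data.frame(unclass(s)[1:9]),
                     stringsAsFactors = FALSE)
  ibdq <- as.data.frame(as.list(stats::setNames(hr$ibdq,
                                                sprintf("ibdq_%02d", 1:32))))
  shs <- as.data.frame(as.list(stats::setNames(hr$shs,
                                               c("shs_symptoms", "shs_function",
                                                 "shs_worry", "shs_wellbeing"))))
  wide <- cbind(wide, ibdq, shs,
                data.frame(patient_symptom_rating = hr$rating,
                           health_transition = transition,
                           stringsAsFactors = FALSE))
  diary <- cbind(data.frame(patient_id = pid, timepoint = timepoint,
                            stringsAsFactors = FALSE), days)
  truth <- data.frame(patient_id = pid, timepoint = timepoint,
                      stratum = .strata[stratum], true_mcs = mcs,
                      treated = treated, stringsAsFactors = FALSE)
  list(wide = wide, diary = diary, truth = truth)
}

#' Generate a synthetic two-timepoint cohort
#'
#' Per patient: a severity stratum is drawn, baseline diary and
#' questionnaires are generated, and a follow-up is produced for responders
#' - unchanged stratum for remission and partial-remission patients
#' (test-retest), a \code{treatment_shift}-strata improvement for treated
#' active patients. An MCAR missingness mask is applied to the wide table.
#' Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{generator_config}}.
#' @return list of class \code{synthetic_cohort}: \code{cohort} (wide
#'   data.frame with holes), \code{cohort_complete} (before masking),
#'   \code{diary} (long), \code{truth}, \code{mask}, \code{config}.
#' @export
generate_cohort <- function(config = generator_config()) {
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_patients
  strata <- sample.int(5L, n, replace = TRUE, prob = cfg$strata_weights)
  u <- stats::rnorm(n, 0, cfg$latent_sd)
  age <- pmin(pmax(round(stats::rnorm(n, 65, 11)), 18), 92)
  sex_female <- stats::rbinom(n, 1L, 0.82)
  duration <- round(pmin(stats::rlnorm(n, log(3), 0.9), 40), 1)
  ibs <- stats::rbinom(n, 1L, cfg$ibs_prevalence)
  responds <- stats::rbinom(n, 1L, cfg$followup_rate) == 1L
  wides <- list(); diaries <- list(); truths <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    bl <- .gen_patient_timepoint(pid, "baseline", strata[i], u[i], FALSE, cfg)
    wides[[length(wides) + 1L]] <- bl$wide
    diaries[[length(diaries) + 1L]] <- bl$diary
    truths[[length(truths) + 1L]] <- bl$truth
    if (responds[i]) {
      active <- strata[i] >= 3L            # mild or worse
      st_fu <- if (active) max(strata[i] - cfg$treatment_shift, 1L) else strata[i]
      fu <- .gen_patient_timepoint(pid, "followup", st_fu, u[i], active, cfg)
      wides[[length(wides) + 1L]] <- fu$wide
      diaries[[length(diaries) + 1L]] <- fu$diary
      truths[[length(truths) + 1L]] <- fu$truth
    }
  }
  wide <- do.call(rbind, wides)
  demo <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), age = age,
                     sex_female = sex_female, disease_duration = duration,
                     ibs = ibs, stringsAsFactors = FALSE)
  wide <- merge(wide, demo, by = "patient_id", sort = FALSE)
  wide <- wide[order(wide$patient_id, wide$timepoint), ]
  rownames(wide) <- NULL
  masked <- apply_missingness(wide, cfg$missing_rate, seed = cfg$seed + 1L)
  truth <- do.call(rbind, truths)
  truth <- truth[order(truth$patient_id, truth$timepoint), ]
  rownames(truth) <- NULL
  diary <- do.call(rbind, diaries)
  rownames(diary) <- NULL
  structure(list(cohort = masked$cohort, cohort_complete = wide,
                 diary = diary, truth = truth, mask = masked$mask,
                 config = cfg),
            class = "synthetic_cohort")
}

#' Punch MCAR holes into a wide cohort table
#'
#' Cells are masked uniformly at random at the given rate, over all columns
#' except the patient and timepoint identifiers. The mask is returned so
#' imputation can be scored against the held-out truth.
#'
#' @param cohort wide data.frame.
#' @param missing_rate cell-masking probability in [0, 0.5).
#' @param mechanism only \code{"MCAR"} is implemented.
#' @param seed integer seed.
#' @return list with \code{cohort} (holes punched) and logical \code{mask}.
#' @export
apply_missingness <- function(cohort, missing_rate, mechanism = "MCAR",
                              seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 0.5)
    .mc_error("missing_rate must lie in [0, 0.5)", "mc_config_error")
  if (mechanism != "MCAR")
    .mc_error("only MCAR masking is implemented", "mc_config_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  maskable <- setdiff(names(cohort), c("patient_id", "timepoint"))
  mask <- matrix(FALSE, nrow(cohort), ncol(cohort),
                 dimnames = list(NULL, names(cohort)))
  if (missing_rate > 0) {
    for (cl in maskable)
      mask[, cl] <- stats::runif(nrow(cohort)) < missing_rate
    for (cl in maskable) cohort[mask[, cl], cl] <- NA
  }
  list(cohort = cohort, mask = mask)
}

#' Simulate paired test-retest measurements at a target reliability
#'
#' Generates subject x occasion scores y_ij = b_i + e_ij with the
#' error-to-subject variance ratio solved in closed form so that the
#' population ICC(2,k) equals \code{icc_target}:
#' sigma_e^2 / sigma_b^2 = k (1 - rho) / rho.
#'
#' @param n subjects.
#' @param k occasions (default 2).
#' @param icc_target population ICC(2,k) (default 0.88).
#' @param seed integer seed.
#' @return numeric matrix n x k.
#' @export
simulate_retest <- function(n, k = 2L, icc_target = 0.88, seed = 1L) {
  if (icc_target <= 0 || icc_target >= 1)
    .mc_error("icc_target must lie in (0, 1)", "mc_config_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ratio <- k * (1 - icc_target) / icc_target
  b <- stats::rnorm(n, 0, 1)
  e <- matrix(stats::rnorm(n * k, 0, sqrt(ratio)), n, k)
  b + e
}
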