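# Raw-instrument parsing and scoring: MCSQ 7-day diary, Hjortswang activity
# criteria, IBDQ-32 and Short Health Scale.

#' MCSQ items entering the composite score
#'
#' Names of the five weekly diary aggregates that carry Microscopic Colitis
#' Score points. Mean solid stools and mean total stools are deliberately
#' excluded: total stools is fully determined by loose + solid stools and is
#' the weaker quality-of-life predictor, and solid stools do not contribute
#' to a diarrhea score.
#'
#' @return Character vector of length 5.
#' @export
mcs_items <- function() {
  c("mean_loose", "mean_nocturnal", "urgency_days", "leakage_days", "mean_pain")
}

# columns a diary day must carry
.diary_day_cols <- c("day_index", "total", "nocturnal", "bristol6", "bristol7",
                     "solid", "urgency", "leakage", "pain")

.mc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mc_error")))
}

.check_diary_days <- function(days) {
  missing_cols <- setdiff(.diary_day_cols, names(days))
  if (length(missing_cols) > 0L)
    .mc_error(paste0("diary is missing columns: ",
                     paste(missing_cols, collapse = ", ")), "mc_validation_error")
  counts <- c("total", "nocturnal", "bristol6", "bristol7", "solid")
  for (cl in counts) {
    v <- days[[cl]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
      .mc_error(sprintf("column '%s' must hold non-negative integer counts", cl),
                "mc_validation_error")
  }
  if (any(days$bristol6 + days$bristol7 + days$solid > days$total))
    .mc_error("bristol6 + bristol7 + solid exceeds total stools on some day",
              "mc_validation_error")
  if (any(days$nocturnal > days$total))
    .mc_error("nocturnal stools exceed total stools on some day",
              "mc_validation_error")
  if (anyDuplicated(days$day_index))
    .mc_error("duplicated day_index in diary", "mc_validation_error")
  if (any(days$day_index < 1 | days$day_index > 7))
    .mc_error("day_index must lie in 1..7", "mc_validation_error")
  if (any(!days$urgency %in% c(0, 1)) || any(!days$leakage %in% c(0, 1)))
    .mc_error("urgency and leakage are daily binary occurrences (0/1)",
              "mc_validation_error")
  if (any(!days$pain %in% 0:3))
    .mc_error("pain is a daily ordinal 0-3", "mc_validation_error")
  invisible(days)
}

#' Aggregate a 7-day MCSQ diary to weekly symptom summaries
#'
#' Computes the per-item weekly aggregates that feed both the Hjortswang
#' activity criteria and the Microscopic Colitis Score: daily means for stool
#' counts and pain, and days-per-week frequencies for urgency and leakage.
#' Diaries with 4-6 recorded days are accepted as partial completions; means
#' are taken over recorded days and the urgency/leakage day counts are
#' rescaled to a 7-day week.
#'
#' @param days data.frame with one row per recorded day and columns
#'   \code{day_index} (1-7), \code{total}, \code{nocturnal}, \code{bristol6},
#'   \code{bristol7}, \code{solid} (non-negative integer counts),
#'   \code{urgency}, \code{leakage} (0/1 occurrence that day) and
#'   \code{pain} (ordinal 0-3).
#' @param min_days minimum number of recorded days accepted (default 4).
#'
#' @return An object of class \code{mcsq_summary}: a list with fields
#'   \code{mean_total}, \code{mean_nocturnal}, \code{mean_b6},
#'   \code{mean_b7}, \code{mean_loose}, \code{mean_solid},
#'   \code{urgency_days}, \code{leakage_days}, \code{mean_pain},
#'   \code{n_days} and \code{partial}.
#' @export
summarize_diary <- function(days, min_days = 4L) {
  days <- as.data.frame(days)
  if (nrow(days) < min_days)
    .mc_error(sprintf("incomplete diary: %d day(s) recorded, need >= %d",
                      nrow(days), min_days), "mc_incomplete_diary")
  .check_diary_days(days)
  n <- nrow(days)
  out <- list(
    mean_total     = mean(days$total),
    mean_nocturnal = mean(days$nocturnal),
    mean_b6        = mean(days$bristol6),
    mean_b7        = mean(days$bristol7),
    mean_loose     = mean(days$bristol6 + days$bristol7),
    mean_solid     = mean(days$solid),
    urgency_days   = sum(days$urgency) / n * 7,
    leakage_days   = sum(days$leakage) / n * 7,
    mean_pain      = mean(days$pain),
    n_days         = n,
    partial        = n < 7L
  )
  structure(out, class = "mcsq_summary")
}

#' Summarize all diaries of a cohort
#'
#' Applies \code{\link{summarize_diary}} to every patient-timepoint block of
#' a long diary table.
#'
#' @param diary long data.frame with columns \code{patient_id},
#'   \code{timepoint} and the per-day columns of \code{summarize_diary}.
#' @param min_days passed on to \code{\link{summarize_diary}}.
#' @return data.frame with one row per patient-timepoint and the nine weekly
#'   summary columns plus \code{n_days} and \code{partial}.
#' @export
summarize_diaries <- function(diary, min_days = 4L) {
  key <- interaction(diary$patient_id, diary$timepoint, drop = TRUE)
  blocks <- split(diary, key)
  rows <- lapply(blocks, function(b) {
    s <- summarize_diary(b, min_days = min_days)
    data.frame(patient_id = b$patient_id[1], timepoint = b$timepoint[1],
               as.data.frame(unclass(s)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify disease activity by the Hjortswang criteria
#'
#' Active disease is defined as a mean of at least 3 stools per day or at
#' least 1 watery (Bristol type 7) stool per day over the diary week. Both
#' comparisons use \code{>=} with no rounding of the weekly means.
#'
#' @param summary an \code{mcsq_summary} (or any list with
#'   \code{mean_total} and \code{mean_b7}).
#' @return list with \code{active} (logical) and \code{rule_fired}, one of
#'   \code{"stool_frequency"}, \code{"watery"}, \code{"both"}, \code{"none"}.
#' @export
hjortswang_classify <- function(summary) {
  mt <- summary$mean_total
  b7 <- summary$mean_b7
  if (is.null(mt) || is.null(b7) || is.na(mt) || is.na(b7))
    .mc_error("summary must carry mean_total and mean_b7", "mc_validation_error")
  if (mt < 0 || b7 < 0)
    .mc_error("weekly means must be non-negative", "mc_validation_error")
  freq <- mt >= 3
  wat <- b7 >= 1
  rule <- if (freq && wat) "both" else if (freq) "stool_frequency" else if (wat) "watery" else "none"
  list(active = freq || wat, rule_fired = rule)
}

#' Default IBDQ-32 domain partition
#'
#' The published 32-item partition into bowel (10 items), systemic (5),
#' social (5) and emotional (12) domains. Licensed orderings that permute
#' item numbers can be accommodated by passing a different map to
#' \code{\link{score_ibdq}}.
#'
#' @return named list of integer item indices per domain.
#' @export
ibdq_domain_map <- function() {
  list(
    bowel     = c(1L, 5L, 9L, 13L, 17L, 20L, 22L, 24L, 26L, 29L),
    systemic  = c(2L, 6L, 10L, 14L, 18L),
    social    = c(4L, 8L, 12L, 16L, 28L),
    emotional = c(3L, 7L, 11L, 15L, 19L, 21L, 23L, 25L, 27L, 30L, 31L, 32L)
  )
}

#' Score the IBDQ-32
#'
#' Sums the 32 seven-point Likert responses into the total (32-224, higher =
#' better health-related quality of life) and the four domain scores: bowel
#' 10-70, systemic 5-35, social 5-35, emotional 12-84.
#'
#' @param responses numeric vector of 32 item responses, each in 1-7.
#' @param domain_map domain partition, as from \code{\link{ibdq_domain_map}}.
#' @return list with \code{total}, \code{bowel}, \code{systemic},
#'   \code{social}, \code{emotional}.
#' @export
score_ibdq <- function(responses, domain_map = ibdq_domain_map()) {
  if (length(responses) != 32L)
    .mc_error("IBDQ-32 requires exactly 32 item responses", "mc_validation_error")
  if (any(is.na(responses)))
    .mc_error("missing IBDQ item response; no imputation at scoring stage",
              "mc_missing_data")
  if (any(responses < 1 | responses > 7))
    .mc_error("IBDQ responses must lie in 1-7", "mc_validation_error")
  idx <- sort(unlist(domain_map, use.names = FALSE))
  if (!identical(idx, 1:32))
    .mc_error("domain_map must partition items 1..32", "mc_validation_error")
  out <- lapply(domain_map, function(i) sum(responses[i]))
  c(list(total = sum(responses)), out)
}

#' Score the Short Health Scale
#'
#' The SHS records four single-item dimensions (bowel symptoms, social
#' function, disease-related worry, general well-being) on a 1-6 scale with
#' 1 best; dimensions are reported separately and never summed.
#'
#' @param responses numeric vector of 4 responses, each in 1-6, in the order
#'   symptoms, function, worry, wellbeing.
#' @return named list of the four dimension scores.
#' @export
score_shs <- function(responses) {
  if (length(responses) != 4L)
    .mc_error("SHS has exactly 4 dimensions", "mc_validation_error")
  if (any(is.na(responses)) || any(responses < 1 | responses > 6) ||
      any(responses != round(responses)))
    .mc_error("SHS responses must be integers in 1-6", "mc_validation_error")
  list(symptoms = responses[1], functioning = responses[2],
       worry = responses[3], wellbeing = responses[4])
}

#' Audit a wide cohort table
#'
#' Reports (without failing) range violations for known questionnaire
#' columns, duplicated patient-timepoints, and per-row / per-column
#' missingness fractions.
#'
#' @param table wide data.frame, one row per patient-timepoint.
#' @return list of class \code{cohort_validation} with \code{violations}
#'   (data.frame: column, row, value, rule), \code{duplicates},
#'   \code{row_missing}, \code{col_missing}.
#' @export
validate_cohort_table <- function(table) {
  table <- as.data.frame(table)
  ranges <- list()
  for (i in 1:32) ranges[[sprintf("ibdq_%02d", i)]] <- c(1, 7)
  for (d in c("shs_symptoms", "shs_function", "shs_worry", "shs_wellbeing"))
    ranges[[d]] <- c(1, 6)
  ranges$patient_symptom_rating <- c(0, 3)
  ranges$ibs <- c(0, 1)
  viol <- list()
  for (cl in intersect(names(ranges), names(table))) {
    v <- table[[cl]]
    bad <- which(!is.na(v) & (v < ranges[[cl]][1] | v > ranges[[cl]][2]))
    if (length(bad) > 0L)
      viol[[cl]] <- data.frame(column = cl, row = bad, value = v[bad],
                               rule = sprintf("range %g-%g", ranges[[cl]][1],
                                              ranges[[cl]][2]))
  }
  violations <- if (length(viol)) do.call(rbind, c(viol, make.row.names = FALSE))
    else data.frame(column = character(), row = integer(),
                    value = numeric(), rule = character())
  dup <- integer()
  if (all(c("patient_id", "timepoint") %in% names(table))) {
    key <- paste(table$patient_id, table$timepoint)
    dup <- which(duplicated(key))
  }
  miss <- is.na(table)
  structure(list(
    violations = violations,
    duplicates = dup,
    row_missing = rowMeans(miss),
    col_missing = colMeans(miss),
    clean = nrow(violations) == 0L && length(dup) == 0L
  ), class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort table audit\n")
  cat("  range violations:", nrow(x$violations), "\n")
  cat("  duplicate patient-timepoints:", length(x$duplicates), "\n")
  cat(sprintf("  overall missingness: %.1f%%\n", 100 * mean(x$row_missing)))
  invisible(x)
}

#' Prorated questionnaire sum score
#'
#' Sum over items with sporadically missing responses replaced by the
#' respondent's mean over observed items, provided at least
#' \code{min_frac} of the items were answered; otherwise NA. This is the
#' conventional half-rule handling for Likert sum scores and is used for
#' analysis tables only - \code{\link{score_ibdq}} itself refuses missing
#' items.
#'
#' @param items data.frame or matrix of item responses (rows =
#'   respondents).
#' @param min_frac minimum fraction of answered items (default 0.8).
#' @return numeric vector of prorated sums.
#' @export
prorated_score <- function(items, min_frac = 0.8) {
  m <- as.matrix(items)
  frac <- rowMeans(!is.na(m))
  out <- rowMeans(m, na.rm = TRUE) * ncol(m)
  out[frac < min_frac] <- NA_real_
  out
}

#' Read a long diary CSV
#'
#' One row per patient-day with columns \code{patient_id}, \code{timepoint},
#' \code{day_index}, \code{total}, \code{nocturnal}, \code{bristol6},
#' \code{bristol7}, \code{solid}, \code{urgency}, \code{leakage},
#' \code{pain}. Empty cells are read as missing; per-column missingness is
#' attached as attribute \code{"col_missing"}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_diary_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", .diary_day_cols)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L)
    .mc_error(paste0("diary CSV missing columns: ",
                     paste(missing_cols, collapse = ", ")), "mc_schema_error")
  attr(x, "col_missing") <- colMeans(is.na(x))
  x
}

#' Read a wide questionnaire CSV
#'
#' One row per patient-timepoint carrying IBDQ items \code{ibdq_01..ibdq_32},
#' SHS dimensions, patient symptom rating, health transition and
#' demographics. Empty cells are read as missing.
#'
#' @param path file path.
#' @return data.frame with attribute \code{"col_missing"}.
#' @export
read_questionnaire_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "timepoint") %in% names(x)))
    .mc_error("questionnaire CSV must carry patient_id and timepoint",
              "mc_schema_error")
  attr(x, "col_missing") <- colMeans(is.na(x))
  x
}
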