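# End-to-end orchestration: simulate -> score -> calibrate -> validate ->
# cluster -> roc, with per-stage seeds derived from one master seed, CSV
# artifacts and a JSON manifest.

#' Pipeline run configuration
#'
#' @param seed master seed; every stochastic stage receives a seed derived
#'   deterministically from it.
#' @param out_dir output directory (created if needed); NULL disables all
#'   file output.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("simulate", "score", "calibrate", "validate", "cluster",
#'   "roc")}.
#' @param generator a \code{\link{generator_config}} for the simulate
#'   stage (its seed is overridden by the derived stage seed).
#' @param score_table_path optional path to a score-table config file;
#'   default uses \code{\link{default_score_table}}.
#' @param r_threshold convergent-validity hypothesis threshold on |r|.
#' @param cluster_n_dims PCA dimensions for clustering, or
#'   \code{"jackstraw"}.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, out_dir = NULL,
                       stages = c("simulate", "score", "calibrate",
                                  "validate", "cluster", "roc"),
                       generator = generator_config(),
                       score_table_path = NULL, r_threshold = 0.4,
                       cluster_n_dims = "jackstraw") {
  known <- c("simulate", "score", "calibrate", "validate", "cluster", "roc")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L)
    .mc_error(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
              "mc_config_error")
  structure(list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
                 generator = generator, score_table_path = score_table_path,
                 r_threshold = r_threshold, cluster_n_dims = cluster_n_dims),
            class = "run_config")
}

# deterministic per-stage seeds from the master seed (kept below 2^31)
.stage_seed <- function(master, stage) {
  offsets <- c(simulate = 101L, score = 211L, calibrate = 307L,
               validate = 401L, cluster = 503L, roc = 601L)
  (as.integer(master) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

.write_stage_csv <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort (or on
#' supplied diary and questionnaire tables): weekly diary summaries and MCS
#' scoring, IBDQ-anchored score-table calibration, the psychometric
#' validation battery (internal consistency, test-retest reliability,
#' responsiveness, convergent validity, factorability), the unsupervised
#' severity clustering, and the ROC contrasts. Artifacts are written as CSV
#' plus a JSON manifest recording seeds and row counts per stage.
#'
#' @param config a \code{\link{run_config}}.
#' @param diary,questionnaires optional externally supplied long diary and
#'   wide questionnaire tables (used when the simulate stage is disabled).
#' @return list of class \code{validation_report} with one element per
#'   executed stage plus \code{manifest}.
#' @export
run_pipeline <- function(config = run_config(), diary = NULL,
                         questionnaires = NULL) {
  stages <- config$stages
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list()
  manifest <- list(seed = config$seed, stages = stages,
                   stage_seeds = sapply(stages, function(s)
                     .stage_seed(config$seed, s)),
                   counts = list())
  truth <- NULL
  if ("simulate" %in% stages) {
    gen_cfg <- config$generator
    gen_cfg$seed <- .stage_seed(config$seed, "simulate")
    sim <- generate_cohort(gen_cfg)
    diary <- sim$diary
    questionnaires <- sim$cohort
    truth <- sim$truth
    report$simulate <- sim
    manifest$counts$simulated_patients <- gen_cfg$n_patients
    .write_stage_csv(sim$diary, out_dir, "diary.csv")
    .write_stage_csv(sim$cohort, out_dir, "questionnaires.csv")
  }
  if (is.null(diary) || is.null(questionnaires))
    .mc_error("no input: supply diary/questionnaires or enable simulate",
              "mc_config_error")

  table <- if (is.null(config$score_table_path)) default_score_table()
    else read_score_table(config$score_table_path)

  summaries <- summarize_diaries(diary)
  scored <- score_cohort(summaries, table)
  ibdq_cols <- sprintf("ibdq_%02d", 1:32)
  q <- questionnaires
  q$ibdq_total <- prorated_score(q[ibdq_cols])
  dm <- ibdq_domain_map()
  for (d in names(dm))
    q[[paste0("ibdq_", d)]] <- prorated_score(q[ibdq_cols[dm[[d]]]])
  cohort <- merge(scored, q, by = c("patient_id", "timepoint"),
                  suffixes = c("", ".q"), sort = FALSE)
  cohort <- cohort[order(cohort$patient_id, cohort$timepoint), ]
  rownames(cohort) <- NULL
  if ("score" %in% stages) {
    report$score <- cohort
    manifest$counts$scored_rows <- nrow(cohort)
    .write_stage_csv(scored, out_dir, "scores.csv")
  }
  if ("calibrate" %in% stages) {
    ok <- !is.na(cohort$ibdq_total)
    cal <- calibrate_score_table(cohort[ok, ], cohort$ibdq_total[ok],
                                 strict = FALSE)
    report$calibrate <- cal
    manifest$counts$calibration_rows <- sum(ok)
    if (!is.null(out_dir)) {
      if (!is.null(cal$table))
        write_score_table(cal$table, file.path(out_dir, "mcs_table.cfg"))
      .write_stage_csv(cal$selection$models, out_dir, "model_comparison.csv")
    }
  }
  if ("validate" %in% stages) {
    # the six diary items: loose stools (of which Bristol 6/7 are the
    # components) rather than the derived b6/b7/total columns, which are
    # exact linear combinations and would make the correlation matrix
    # singular
    items <- cohort[, c(mcs_items(), "mean_solid")]
    cc <- items[stats::complete.cases(items), ]
    val <- list(
      bartlett = bartlett_sphericity(as.matrix(cc), n = nrow(cc)),
      kmo = kmo(as.matrix(cc)),
      alpha_mcs_items = cronbach_alpha(cohort[stats::complete.cases(
        cohort[mcs_items()]), mcs_items()]),
      parallel = parallel_analysis(as.matrix(cc),
                                   seed = .stage_seed(config$seed, "validate"))
    )
    val$efa <- efa(as.matrix(cc), n_factors = 3, rotation = "promax")
    # test-retest: patients in remission (by Hjortswang) at both timepoints
    bl <- cohort[cohort$timepoint == "baseline", ]
    fu <- cohort[cohort$timepoint == "followup", ]
    both <- intersect(bl$patient_id[!bl$hjortswang_active],
                      fu$patient_id[!fu$hjortswang_active])
    if (length(both) >= 5L) {
      mat <- cbind(bl$mcs[match(both, bl$patient_id)],
                   fu$mcs[match(both, fu$patient_id)])
      val$reliability <- icc2k(mat)
      manifest$counts$retest_pairs <- nrow(mat)
    }
    # responsiveness: active at baseline (treated at follow-up)
    act <- intersect(bl$patient_id[bl$hjortswang_active], fu$patient_id)
    if (length(act) >= 5L)
      val$responsiveness <- responsiveness_battery(
        bl[bl$patient_id %in% act, c("patient_id", mcs_items(), "mcs")],
        fu[fu$patient_id %in% act, c("patient_id", mcs_items(), "mcs")])
    ok <- stats::complete.cases(cohort[c("mcs", "ibdq_total", "shs_symptoms",
                                         "patient_symptom_rating")])
    val$validity <- validity_correlations(
      cohort[ok, c(mcs_items(), "mcs")],
      data.frame(ibdq_total = cohort$ibdq_total[ok],
                 ibdq_bowel = cohort$ibdq_bowel[ok],
                 shs_symptoms = cohort$shs_symptoms[ok],
                 patient_symptom_rating = cohort$patient_symptom_rating[ok],
                 active = as.integer(cohort$hjortswang_active[ok])),
      spearman_cols = c("shs_symptoms", "patient_symptom_rating"),
      expected_sign = c(ibdq_total = -1, ibdq_bowel = -1, shs_symptoms = 1,
                        patient_symptom_rating = 1, active = 1),
      r_threshold = config$r_threshold)
    report$validate <- val
    if (!is.null(out_dir)) {
      .write_stage_csv(val$validity, out_dir, "validity.csv")
      if (!is.null(val$responsiveness))
        .write_stage_csv(val$responsiveness, out_dir, "responsiveness.csv")
    }
  }
  if ("cluster" %in% stages) {
    feat_cols <- c("mean_total", "mean_nocturnal", "mean_b6", "mean_b7",
                   "mean_loose", "mean_solid", "urgency_days", "leakage_days",
                   "mean_pain", "ibdq_total", "ibdq_bowel", "ibdq_systemic",
                   "ibdq_social", "ibdq_emotional", "shs_symptoms",
                   "shs_function", "shs_worry", "shs_wellbeing",
                   "patient_symptom_rating", "age", "sex_female",
                   "disease_duration")
    feat <- cohort[, intersect(feat_cols, names(cohort))]
    cl <- cluster_severity(feat, n_dims = config$cluster_n_dims,
                           seed = .stage_seed(config$seed, "cluster"))
    report$cluster <- cl
    manifest$counts$clustered_rows <- length(cl$labels)
    if (!is.null(out_dir))
      .write_stage_csv(data.frame(
        patient_id = cohort$patient_id[cl$kept_rows],
        timepoint = cohort$timepoint[cl$kept_rows],
        cluster = cl$labels, severity = cl$annotation), out_dir, "clusters.csv")
  }
  if ("roc" %in% stages) {
    sev <- rep(NA_character_, nrow(cohort))
    if (!is.null(report$cluster))
      sev[report$cluster$kept_rows] <- report$cluster$annotation
    keep <- !is.na(cohort$mcs)
    report$roc <- evaluate_severity_contrasts(
      cohort$mcs[keep], cohort$hjortswang_active[keep],
      if (!is.null(report$cluster)) sev[keep] else NULL)
    .write_stage_csv(report$roc, out_dir, "roc.csv")
  }
  report$cohort <- cohort
  report$truth <- truth
  manifest$config_hash <- .config_hash(config)
  report$manifest <- manifest
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  class(report) <- "validation_report"
  report
}

# small deterministic hash of the serialized configuration
.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Round-trip a data.frame through CSV
#'
#' Writes with RFC-4180 quoting and '.' decimal, re-reads, and checks that
#' writing again is byte-stable.
#'
#' @param x data.frame.
#' @param path file path.
#' @return the re-read data.frame; errors if the round trip is not
#'   byte-stable.
#' @export
csv_roundtrip <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  y <- utils::read.csv(path, stringsAsFactors = FALSE)
  path2 <- tempfile(fileext = ".csv")
  on.exit(unlink(path2), add = TRUE)
  utils::write.csv(y, path2, row.names = FALSE)
  if (!identical(readLines(path), readLines(path2)))
    .mc_error("CSV round trip is not byte-stable", "mc_schema_error")
  y
}
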