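# IBDQ-anchored calibration of the score table: item cut-offs are chosen so
# that each awarded point corresponds to a 15-20 point decrease in IBDQ-32
# total, and the diarrhea item entering the score is selected by adjusted-R2
# model comparison.

#' Calibration configuration
#'
#' @param target_drop_min,target_drop_max the IBDQ-32 total decrease (in
#'   points, on the 32-224 scale) that one awarded MCS point must
#'   correspond to; default 15-20.
#' @param max_points maximum points one item may carry (default 3, so five
#'   items reach the score maximum of 15).
#' @param min_category_n minimum observations per point category (default
#'   5); partitions with thinner categories are rejected.
#' @param max_candidates candidate thresholds are mid-points between
#'   consecutive unique item values, thinned by quantile spacing to at most
#'   this many (default 40); the spacing of this grid is the resolution at
#'   which cut-offs are identified.
#' @param epsilon_r2 minimum adjusted-R2 increase considered meaningful in
#'   multivariate model comparison (default 0.01).
#' @return list of class \code{calibration_config}.
#' @export
calibration_config <- function(target_drop_min = 15, target_drop_max = 20,
                               max_points = 3L, min_category_n = 5L,
                               max_candidates = 40L, epsilon_r2 = 0.01) {
  if (!(target_drop_min > 0 && target_drop_min <= target_drop_max))
    .mc_error("need 0 < target_drop_min <= target_drop_max", "mc_config_error")
  structure(list(target_drop_min = target_drop_min,
                 target_drop_max = target_drop_max,
                 max_points = as.integer(max_points),
                 min_category_n = as.integer(min_category_n),
                 max_candidates = as.integer(max_candidates),
                 epsilon_r2 = epsilon_r2),
            class = "calibration_config")
}

#' Univariate anchor regression of IBDQ-32 total on one item
#'
#' Ordinary least squares of the anchor on the item, with the usual
#' adjusted R2 and a 95\% confidence interval for the slope.
#'
#' @param item_values numeric item measurements.
#' @param ibdq_totals paired IBDQ-32 totals.
#' @return list of class \code{anchor_fit}: \code{slope}, \code{intercept},
#'   \code{adjusted_r2}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{n}.
#' @export
fit_anchor_regression <- function(item_values, ibdq_totals) {
  ok <- stats::complete.cases(item_values, ibdq_totals)
  x <- item_values[ok]; y <- ibdq_totals[ok]
  if (length(x) < 10L)
    .mc_error("need at least 10 paired observations", "mc_validation_error")
  if (stats::var(x) == 0)
    .mc_error("degenerate predictor: item has zero variance", "mc_degenerate_predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = 0.95)
  structure(list(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 adjusted_r2 = sm$adj.r.squared,
                 ci_low = ci[1], ci_high = ci[2],
                 p_value = sm$coefficients["x", 4],
                 n = length(x)),
            class = "anchor_fit")
}

# candidate thresholds: mid-points between consecutive unique values,
# thinned to at most max_candidates by quantile-spaced selection
.candidate_thresholds <- function(x, max_candidates) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(numeric())
  mids <- (u[-1] + u[-length(u)]) / 2
  if (length(mids) > max_candidates) {
    idx <- unique(round(seq(1L, length(mids), length.out = max_candidates)))
    mids <- mids[idx]
  }
  mids
}

#' Derive point cut-offs for one item from the IBDQ anchor
#'
#' Exhaustive search over subsets of candidate thresholds (mid-points
#' between consecutive unique item values, quantile-thinned): the chosen
#' partition maximizes the number of adjacent point categories whose
#' difference in mean IBDQ-32 total falls inside the target window
#' (default [15, 20]); ties are broken toward the partition whose
#' piecewise-constant fit of the anchor has the smallest residual sum of
#' squares (the change-point criterion, which localizes category boundaries
#' sharply), then fewer categories, then lexicographically lower
#' thresholds. Categories must each hold at least \code{min_category_n}
#' observations. If the item has no usable
#' association with the anchor (slope confidence interval covering 0 and no
#' in-window gap), a single-category zero-point entry is returned with the
#' \code{flat} flag set.
#'
#' @param item_values,ibdq_totals paired observations.
#' @param item item name for the resulting entry.
#' @param config a \code{\link{calibration_config}}.
#' @return a \code{\link{score_table_entry}} with attributes
#'   \code{"category_means"}, \code{"gaps"}, \code{"in_window"}.
#' @export
derive_item_cutoffs <- function(item_values, ibdq_totals, item = "item",
                                config = calibration_config()) {
  ok <- stats::complete.cases(item_values, ibdq_totals)
  x <- item_values[ok]; y <- ibdq_totals[ok]
  if (length(x) < 10L)
    .mc_error("need at least 10 paired observations", "mc_validation_error")
  if (stats::var(x) == 0)
    .mc_error("degenerate predictor: item has zero variance", "mc_degenerate_predictor")

  cand <- .candidate_thresholds(x, config$max_candidates)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  cum_y <- c(0, cumsum(ys))
  cum_y2 <- c(0, cumsum(ys^2))
  n <- length(xs)

  # category counts/means/fit via index bounds in the sorted vector
  n_below <- function(t) findInterval(t - .Machine$double.eps^0.5, xs)
  cat_stats <- function(thr) {
    brk <- c(0L, vapply(thr, n_below, integer(1)), n)
    cnt <- diff(brk)
    sums <- cum_y[brk[-1] + 1L] - cum_y[brk[-length(brk)] + 1L]
    sq <- cum_y2[brk[-1] + 1L] - cum_y2[brk[-length(brk)] + 1L]
    mu <- sums / cnt
    list(count = cnt, mean = mu, sse = sum(sq - sums^2 / cnt))
  }

  lo <- config$target_drop_min; hi <- config$target_drop_max
  best <- NULL
  consider <- function(thr) {
    st <- cat_stats(thr)
    if (any(st$count < config$min_category_n)) return(NULL)
    gaps <- -diff(st$mean)                    # positive when IBDQ decreases
    list(thr = thr, stats = st, gaps = gaps,
         n_in = sum(gaps >= lo & gaps <= hi))
  }
  better <- function(a, b) {
    # more in-window gaps; tie -> best piecewise-constant fit of the anchor
    # (sharpest category-boundary localization); tie -> fewer categories;
    # tie -> lower thresholds
    if (is.null(b)) return(TRUE)
    if (a$n_in != b$n_in) return(a$n_in > b$n_in)
    if (abs(a$stats$sse - b$stats$sse) > 1e-9)
      return(a$stats$sse < b$stats$sse)
    if (length(a$thr) != length(b$thr)) return(length(a$thr) < length(b$thr))
    d <- a$thr - b$thr
    i <- which(d != 0)[1]
    !is.na(i) && d[i] < 0
  }
  for (k in seq_len(min(config$max_points, length(cand)))) {
    for (combo in utils::combn(length(cand), k, simplify = FALSE)) {
      res <- consider(cand[combo])
      if (!is.null(res) && better(res, best)) best <- res
    }
  }

  fit <- fit_anchor_regression(x, y)
  flat_assoc <- fit$ci_low <= 0 && fit$ci_high >= 0
  if (is.null(best) || best$n_in == 0L) {
    if (flat_assoc) {
      entry <- score_table_entry(item, numeric(), 0L, flat = TRUE)
      attr(entry, "category_means") <- mean(y)
      attr(entry, "gaps") <- numeric()
      attr(entry, "in_window") <- logical()
      return(entry)
    }
    # associated but no gap can be placed in the window: fall back to the
    # best single threshold by gap closest to the window
    if (is.null(best)) {
      singles <- lapply(cand, function(t) consider(t))
      singles <- Filter(Negate(is.null), singles)
      if (length(singles) == 0L)
        .mc_error("no admissible partition (categories too thin)", "mc_config_error")
      dist_to_win <- vapply(singles, function(s)
        max(lo - s$gaps, s$gaps - hi, 0), numeric(1))
      best <- singles[[which.min(dist_to_win)]]
    }
  }
  entry <- score_table_entry(item, best$thr, seq(0L, length(best$thr)))
  attr(entry, "category_means") <- best$stats$mean
  attr(entry, "category_counts") <- best$stats$count
  attr(entry, "gaps") <- best$gaps
  attr(entry, "in_window") <- best$gaps >= lo & best$gaps <= hi
  entry
}

#' Select the diarrhea item for the score
#'
#' Mean loose stools is the sum of the Bristol 6 and Bristol 7 items, so
#' only one of the three may enter the score. All three univariate OLS
#' models of the IBDQ anchor, the three two-variable models and no exactly
#' collinear triple are fitted; the best univariate model by adjusted R2 is
#' selected, and any multivariate adjusted-R2 improvement larger than
#' \code{epsilon_r2} over it is reported.
#'
#' @param candidates data.frame with columns \code{mean_loose},
#'   \code{mean_b6}, \code{mean_b7}.
#' @param ibdq_totals paired IBDQ-32 totals.
#' @param config a \code{\link{calibration_config}} (uses
#'   \code{epsilon_r2}).
#' @return list of class \code{item_selection}: \code{chosen},
#'   \code{models} (data.frame of model, adjusted R2), \code{meaningful_gain},
#'   \code{flat} (TRUE when no candidate shows a nonzero slope).
#' @export
select_diarrhea_item <- function(candidates, ibdq_totals,
                                 config = calibration_config()) {
  need <- c("mean_loose", "mean_b6", "mean_b7")
  if (!all(need %in% names(candidates)))
    .mc_error("candidates must carry mean_loose, mean_b6, mean_b7",
              "mc_validation_error")
  df <- data.frame(candidates[need], y = ibdq_totals)
  df <- df[stats::complete.cases(df), ]
  uni <- lapply(need, function(v)
    summary(stats::lm(stats::reformulate(v, "y"), data = df))$adj.r.squared)
  names(uni) <- need
  pairs <- utils::combn(need, 2, simplify = FALSE)
  multi <- lapply(pairs, function(p)
    summary(stats::lm(stats::reformulate(p, "y"), data = df))$adj.r.squared)
  names(multi) <- vapply(pairs, paste, character(1), collapse = "+")
  # the triple is exactly collinear (loose = b6 + b7) and is excluded
  models <- data.frame(
    model = c(need, names(multi)),
    type = rep(c("univariate", "multivariate"), c(3L, length(multi))),
    adjusted_r2 = unlist(c(uni, multi), use.names = FALSE)
  )
  chosen <- need[which.max(unlist(uni))]
  gain <- max(unlist(multi)) - max(unlist(uni))
  flats <- vapply(need, function(v) {
    f <- fit_anchor_regression(df[[v]], df$y)
    f$ci_low <= 0 && f$ci_high >= 0
  }, logical(1))
  structure(list(chosen = chosen, models = models,
                 meaningful_gain = gain > config$epsilon_r2,
                 gain = gain, flat = all(flats)),
            class = "item_selection")
}

#' Assemble a score table from calibrated entries
#'
#' Entries for mean solid or mean total stools are dropped with a warning
#' (both are excluded from the score by construction). If the maximum
#' points across the five retained items exceed 15, top categories of the
#' largest entries are merged (with a warning) until the total is 15; if
#' the total falls short of 15 the table cannot be formed and a
#' configuration error is raised.
#'
#' @param entries list of \code{\link{score_table_entry}} objects.
#' @return a validated \code{\link{score_table}}.
#' @export
assemble_score_table <- function(entries) {
  items <- vapply(entries, function(e) e$item, character(1))
  drop <- items %in% c("mean_solid", "mean_total")
  if (any(drop)) {
    warning("dropping excluded item(s): ", paste(items[drop], collapse = ", "))
    entries <- entries[!drop]
    items <- items[!drop]
  }
  if (!setequal(items, mcs_items()))
    .mc_error(paste0("need entries for exactly: ",
                     paste(mcs_items(), collapse = ", ")), "mc_config_error")
  total <- sum(vapply(entries, function(e) max(e$points), integer(1)))
  if (total < 15L)
    .mc_error(sprintf(
      "cannot reach a 15-point maximum: calibrated entries carry only %d points",
      total), "mc_config_error")
  while (total > 15L) {
    maxpts <- vapply(entries, function(e) max(e$points), integer(1))
    i <- which.max(maxpts)
    e <- entries[[i]]
    warning(sprintf("merging top categories of '%s' to reach a 15-point maximum",
                    e$item))
    entries[[i]] <- score_table_entry(e$item,
                                      e$thresholds[-length(e$thresholds)],
                                      e$points[-length(e$points)])
    total <- total - 1L
  }
  score_table(entries)
}

#' Calibrate a full score table from a cohort
#'
#' Runs the diarrhea-item selection, derives cut-offs for the selected
#' diarrhea item and the four remaining items against the IBDQ-32 total
#' anchor, and assembles the validated table.
#'
#' @param summaries data.frame of weekly summaries (as from
#'   \code{\link{summarize_diaries}}); the diarrhea entry is always stored
#'   under \code{mean_loose}.
#' @param ibdq_totals paired IBDQ-32 totals.
#' @param config a \code{\link{calibration_config}}.
#' @param strict when TRUE (default) a table whose calibrated entries
#'   cannot reach the 15-point maximum raises a configuration error; when
#'   FALSE the result carries \code{table = NULL} plus the per-item entries
#'   and a warning, so exploratory pipelines can continue.
#' @return list of class \code{calibration_result}: \code{table} (possibly
#'   NULL when \code{strict = FALSE}), \code{entries}, \code{selection},
#'   \code{fits} (per-item anchor regressions).
#' @export
calibrate_score_table <- function(summaries, ibdq_totals,
                                  config = calibration_config(),
                                  strict = TRUE) {
  sel <- select_diarrhea_item(summaries, ibdq_totals, config)
  entries <- list()
  diarrhea <- derive_item_cutoffs(summaries[[sel$chosen]], ibdq_totals,
                                  "mean_loose", config)
  entries[["mean_loose"]] <- diarrhea
  for (it in setdiff(mcs_items(), "mean_loose"))
    entries[[it]] <- derive_item_cutoffs(summaries[[it]], ibdq_totals, it, config)
  fits <- lapply(mcs_items(), function(it)
    fit_anchor_regression(summaries[[if (it == "mean_loose") sel$chosen else it]],
                          ibdq_totals))
  names(fits) <- mcs_items()
  table <- if (strict) assemble_score_table(unname(entries)) else
    tryCatch(assemble_score_table(unname(entries)), error = function(e) {
      warning("calibrated entries do not form a full 15-point table: ",
              conditionMessage(e))
      NULL
    })
  structure(list(table = table, entries = entries,
                 selection = sel, fits = fits),
            class = "calibration_result")
}
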