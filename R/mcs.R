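# The Microscopic Colitis Score: an item -> points table over five weekly
# diary aggregates, summed to a 0-15 composite and binned into severity
# groups.

#' Construct a score-table entry for one MCSQ item
#'
#' An entry maps a weekly item value to points through strictly increasing
#' thresholds: value v earns \code{points[j]} where j indexes the half-open
#' interval [t_j, t_{j+1}) containing v (the top interval is closed above by
#' +Inf). Points start at 0 and increase strictly across intervals.
#'
#' @param item item name, one of \code{\link{mcs_items}()}.
#' @param thresholds strictly increasing numeric cut-offs (may be empty for
#'   a flagged zero-point entry).
#' @param points integer points per interval; defaults to
#'   \code{0:length(thresholds)}.
#' @param flat logical, marks an entry with no usable item-anchor
#'   association (0 max points).
#' @return list of class \code{score_table_entry}.
#' @export
score_table_entry <- function(item, thresholds, points = seq(0L, length(thresholds)),
                              flat = FALSE) {
  thresholds <- as.numeric(thresholds)
  points <- as.integer(points)
  if (length(points) != length(thresholds) + 1L)
    .mc_error("need one more points level than thresholds", "mc_config_error")
  if (length(thresholds) > 0L && any(diff(thresholds) <= 0))
    .mc_error("thresholds must be strictly increasing", "mc_config_error")
  if (points[1] != 0L)
    .mc_error("points must start at 0", "mc_config_error")
  if (length(points) > 1L && any(diff(points) <= 0L))
    .mc_error("points must be strictly increasing with interval", "mc_config_error")
  structure(list(item = item, thresholds = thresholds, points = points,
                 flat = isTRUE(flat)),
            class = "score_table_entry")
}

#' Assemble a full MCS score table
#'
#' Validates the defining invariants of the score: exactly the five included
#' items (\code{\link{mcs_items}()}) are present, mean solid and mean total
#' stools are never present, and the maximum awardable points sum to 15.
#'
#' @param entries list of \code{\link{score_table_entry}} objects.
#' @return list of class \code{score_table}, keyed by item name.
#' @export
score_table <- function(entries) {
  items <- vapply(entries, function(e) e$item, character(1))
  if (any(items %in% c("mean_solid", "mean_total")))
    .mc_error("mean_solid and mean_total are excluded from the MCS",
              "mc_config_error")
  if (anyDuplicated(items))
    .mc_error("duplicated item in score table", "mc_config_error")
  missing_items <- setdiff(mcs_items(), items)
  if (length(missing_items) > 0L)
    .mc_error(paste0("score table missing item(s): ",
                     paste(missing_items, collapse = ", ")), "mc_config_error")
  extra <- setdiff(items, mcs_items())
  if (length(extra) > 0L)
    .mc_error(paste0("unknown item(s) in score table: ",
                     paste(extra, collapse = ", ")), "mc_config_error")
  names(entries) <- items
  entries <- entries[mcs_items()]
  maxpts <- sum(vapply(entries, function(e) max(e$points), integer(1)))
  if (maxpts != 15L)
    .mc_error(sprintf("maximum points must sum to 15, got %d", maxpts),
              "mc_config_error")
  structure(entries, class = "score_table")
}

#' The default MCS score table
#'
#' Each of the five items carries 0-3 points (5 x 3 = 15, the score's
#' maximum). The shipped thresholds are round-number clinical cut-points
#' spaced on the anchoring principle that each additional point should
#' track a meaningful (15-20 point) IBDQ-32 decrease; for any particular
#' cohort, \code{\link{calibrate_score_table}} derives a data-specific
#' replacement, and an externally supplied table can be loaded with
#' \code{\link{read_score_table}}. A copy of this table ships as
#' \code{system.file("extdata", "mcs_table_default.cfg", package =
#' "mcactivity")}.
#'
#' @return a \code{\link{score_table}}.
#' @export
default_score_table <- function() {
  score_table(list(
    score_table_entry("mean_loose",     c(1, 3, 5)),
    score_table_entry("mean_nocturnal", c(0.5, 1.5, 3)),
    score_table_entry("urgency_days",   c(2, 4, 6)),
    score_table_entry("leakage_days",   c(1, 3, 5)),
    score_table_entry("mean_pain",      c(0.5, 1.5, 2.5))
  ))
}

#' Award points for one item value
#'
#' @param value non-negative item measurement.
#' @param entry a \code{\link{score_table_entry}}.
#' @return integer points; monotone non-decreasing in \code{value}.
#' @export
award_item_points <- function(value, entry) {
  if (any(is.na(value)) || any(value < 0))
    .mc_error("item value must be non-negative", "mc_validation_error")
  if (length(entry$thresholds) == 0L) return(rep(0L, length(value)))
  entry$points[findInterval(value, entry$thresholds) + 1L]
}

#' Compute the Microscopic Colitis Score
#'
#' Sums item-specific points over the five included weekly aggregates. The
#' result ranges from 0 (asymptomatic) to 15 (maximal symptoms) and is
#' monotone non-decreasing in every included item.
#'
#' @param summary an \code{mcsq_summary} (or list carrying the five item
#'   fields).
#' @param table a \code{\link{score_table}}; default
#'   \code{\link{default_score_table}()}.
#' @return list of class \code{mcs_result} with \code{item_points}
#'   (named integer vector), \code{mcs} and \code{severity}.
#' @export
compute_mcs <- function(summary, table = default_score_table()) {
  if (!inherits(table, "score_table"))
    .mc_error("table must be a score_table", "mc_config_error")
  pts <- vapply(mcs_items(), function(it) {
    v <- summary[[it]]
    if (is.null(v) || is.na(v))
      .mc_error(sprintf("summary lacks item '%s'", it), "mc_validation_error")
    as.integer(award_item_points(v, table[[it]]))
  }, integer(1))
  mcs <- sum(pts)
  structure(list(item_points = pts, mcs = mcs,
                 severity = classify_severity(mcs)),
            class = "mcs_result")
}

#' Severity class of an MCS value
#'
#' Remission 0-3, mild 4-6, moderate 7-9, severe 10-15: the boundaries 4, 7
#' and 10 are the ROC-selected minima of the mild, moderate and severe
#' groups.
#'
#' @param mcs integer score(s) in 0-15.
#' @return character vector of severity classes.
#' @export
classify_severity <- function(mcs) {
  if (any(is.na(mcs)) || any(mcs < 0 | mcs > 15) || any(mcs != round(mcs)))
    .mc_error("mcs must be an integer in 0-15", "mc_validation_error")
  cut_points <- c(-Inf, 4, 7, 10, Inf)
  labs <- c("remission", "mild", "moderate", "severe")
  labs[findInterval(mcs, cut_points)]
}

#' Score a cohort of weekly summaries
#'
#' @param summaries data.frame as returned by \code{\link{summarize_diaries}}.
#' @param table a \code{\link{score_table}}.
#' @return the input with \code{mcs}, \code{severity}, \code{hjortswang_active}
#'   and \code{hjortswang_rule} columns appended.
#' @export
score_cohort <- function(summaries, table = default_score_table()) {
  res <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- as.list(summaries[i, ])
    m <- compute_mcs(s, table)
    h <- hjortswang_classify(s)
    data.frame(mcs = m$mcs, severity = m$severity,
               hjortswang_active = h$active, hjortswang_rule = h$rule_fired,
               stringsAsFactors = FALSE)
  })
  cbind(summaries, do.call(rbind, res))
}

#' @export
print.score_table <- function(x, ...) {
  cat("MCS score table (max", sum(vapply(x, function(e) max(e$points), integer(1))),
      "points)\n")
  for (e in x) {
    cat(sprintf("  %-14s thresholds: %s; points: %s%s\n", e$item,
                paste(e$thresholds, collapse = ", "),
                paste(e$points, collapse = ", "),
                if (e$flat) " [flat]" else ""))
  }
  invisible(x)
}

#' Write a score table to a human-readable config file
#'
#' One block per item: a \code{[item]} header followed by \code{thresholds:}
#' and \code{points:} lines. The loader re-validates all invariants, and a
#' write-read-write cycle is byte-stable.
#'
#' @param table a \code{\link{score_table}}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(table, path) {
  if (!inherits(table, "score_table"))
    .mc_error("table must be a score_table", "mc_config_error")
  lines <- c("# MCS score table v1")
  for (e in table) {
    lines <- c(lines,
               sprintf("[%s]", e$item),
               sprintf("thresholds: %s",
                       paste(format(e$thresholds, trim = TRUE, digits = 15),
                             collapse = ", ")),
               sprintf("points: %s", paste(e$points, collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a score table config file
#'
#' @param path file written by \code{\link{write_score_table}} (or hand
#'   edited in the same format).
#' @return a validated \code{\link{score_table}}.
#' @export
read_score_table <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  heads <- grep("^\\[.+\\]$", lines)
  if (length(heads) == 0L)
    .mc_error("no [item] blocks found in score table config", "mc_config_error")
  entries <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    block <- lines[heads[i]:(bounds[i + 1L] - 1L)]
    item <- sub("^\\[(.+)\\]$", "\\1", block[1])
    get_field <- function(key) {
      ln <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (length(ln) != 1L)
        .mc_error(sprintf("item '%s': expected exactly one '%s:' line", item, key),
                  "mc_config_error")
      as.numeric(strsplit(sub(paste0("^", key, ":\\s*"), "", ln), ",")[[1]])
    }
    entries[[i]] <- score_table_entry(item, get_field("thresholds"),
                                      as.integer(get_field("points")))
  }
  score_table(entries)
}
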