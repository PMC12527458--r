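# ROC analysis of the MCS against reference labels: curve, AUC, optimal
# cut-off selection and the severity-contrast table.

#' ROC curve for a score against binary labels
#'
#' Sweeps the rule "score >= c is positive" over all unique score values
#' (plus an all-negative sentinel). The AUC is computed by the trapezoid
#' rule over the (FPR, TPR) path, which handles ties by construction and
#' equals the normalized Mann-Whitney concordance probability
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels (0/1 or logical).
#' @return list of class \code{roc_result}: \code{thresholds}, \code{tpr},
#'   \code{fpr}, \code{auc}, \code{n_pos}, \code{n_neg}.
#' @export
roc_curve <- function(scores, labels) {
  ok <- stats::complete.cases(scores, labels)
  s <- scores[ok]; l <- as.integer(labels[ok])
  if (!all(l %in% c(0L, 1L)))
    .mc_error("labels must be binary", "mc_validation_error")
  n_pos <- sum(l == 1L); n_neg <- sum(l == 0L)
  if (n_pos == 0L || n_neg == 0L)
    .mc_error("AUC undefined: one class absent", "mc_undefined_auc")
  thr <- c(sort(unique(s)), Inf)          # Inf = nothing positive
  tpr <- vapply(thr, function(t) sum(s >= t & l == 1L) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & l == 0L) / n_neg, numeric(1))
  ord <- order(fpr, tpr)                  # ascending path from (0,0) to (1,1)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(ord)]) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' Optimal cut-off from a ROC curve
#'
#' By default maximizes Youden's J = sensitivity + specificity - 1; ties
#' are broken toward the lower cut-off, favouring sensitivity. The
#' closest-to-(0,1) criterion is also available. A useless score (J = 0 at
#' the degenerate all-positive cut-off) is flagged.
#'
#' @param roc a \code{\link{roc_curve}} result.
#' @param criterion \code{"youden"} (default) or \code{"closest_topleft"}.
#' @return list with \code{cutoff} (smallest value c such that score >= c
#'   is positive), \code{sensitivity}, \code{specificity}, \code{j},
#'   \code{criterion}, \code{degenerate}.
#' @export
optimal_cutoff <- function(roc, criterion = c("youden", "closest_topleft")) {
  criterion <- match.arg(criterion)
  sens <- roc$tpr; spec <- 1 - roc$fpr
  score <- switch(criterion,
                  youden = sens + spec - 1,
                  closest_topleft = -((1 - sens)^2 + (1 - spec)^2))
  # candidates ordered by threshold ascending; ties -> lower cutoff
  best <- which(score == max(score))[1]
  j <- sens[best] + spec[best] - 1
  list(cutoff = roc$thresholds[best], sensitivity = sens[best],
       specificity = spec[best], j = j, criterion = criterion,
       degenerate = max(sens + spec - 1) <= 0)
}

#' ROC contrasts of the MCS against activity and severity references
#'
#' One ROC per contrast: active vs remission under the Hjortswang criteria,
#' and - from the cluster-derived severity annotation - any active disease
#' (mild or worse), moderate-or-severe, and severe. Integer cut-offs are
#' reported as the smallest c with "MCS >= c positive". Contrasts with a
#' single class are skipped with a warning.
#'
#' @param mcs integer MCS values per patient-timepoint.
#' @param hjortswang_active logical/0-1 Hjortswang activity labels.
#' @param cluster_severity character severity annotation per
#'   patient-timepoint (levels within remission, partial remission, mild,
#'   moderate, severe).
#' @param criterion cut-off criterion, see \code{\link{optimal_cutoff}}.
#' @return data.frame of class \code{severity_contrasts}: contrast, n_pos,
#'   n_neg, auc, cutoff, sensitivity, specificity.
#' @export
evaluate_severity_contrasts <- function(mcs, hjortswang_active = NULL,
                                        cluster_severity = NULL,
                                        criterion = "youden") {
  contrasts <- list()
  if (!is.null(hjortswang_active))
    contrasts[["hjortswang_active"]] <- as.integer(hjortswang_active)
  if (!is.null(cluster_severity)) {
    sev_rank <- c("remission" = 0, "partial remission" = 0, "mild" = 1,
                  "moderate" = 2, "severe" = 3)
    r <- sev_rank[as.character(cluster_severity)]
    contrasts[["cluster_active"]] <- as.integer(r >= 1)
    contrasts[["cluster_moderate_or_severe"]] <- as.integer(r >= 2)
    contrasts[["cluster_severe"]] <- as.integer(r >= 3)
  }
  rows <- list()
  for (nm in names(contrasts)) {
    lab <- contrasts[[nm]]
    if (length(unique(lab[!is.na(lab)])) < 2L) {
      warning(sprintf("contrast '%s' has a single class; skipped", nm))
      next
    }
    roc <- roc_curve(mcs, lab)
    oc <- optimal_cutoff(roc, criterion)
    rows[[nm]] <- data.frame(contrast = nm, n_pos = roc$n_pos,
                             n_neg = roc$n_neg, auc = roc$auc,
                             cutoff = oc$cutoff, sensitivity = oc$sensitivity,
                             specificity = oc$specificity)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contrast = character(), n_pos = integer(), n_neg = integer(),
               auc = numeric(), cutoff = numeric(), sensitivity = numeric(),
               specificity = numeric())
  rownames(out) <- NULL
  class(out) <- c("severity_contrasts", "data.frame")
  out
}
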