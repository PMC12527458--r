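# Unsupervised severity-group discovery: missingness filtering, iterative
# random-forest imputation, scaling + PCA with JackStraw dimension
# selection, shared-nearest-neighbour Jaccard graph and Leiden
# partitioning, followed by burden-ordered cluster annotation.

#' Filter rows and columns by missingness
#'
#' Rows (patient-timepoints) with more than \code{row_max_missing} missing
#' fraction are removed first, then columns (variables) with more than
#' \code{col_max_missing} missingness among the remaining rows. The removal
#' order is logged.
#'
#' @param table data.frame or matrix.
#' @param row_max_missing,col_max_missing maximum tolerated missing
#'   fraction (default 0.20 each).
#' @return list with \code{table}, \code{removed_rows},
#'   \code{removed_cols}, \code{log} (character).
#' @export
filter_missing <- function(table, row_max_missing = 0.20,
                           col_max_missing = 0.20) {
  x <- as.data.frame(table)
  log <- character()
  rm_rows <- which(rowMeans(is.na(x)) > row_max_missing)
  if (length(rm_rows) > 0L) {
    log <- c(log, sprintf("removed %d row(s) with >%.0f%% missingness",
                          length(rm_rows), 100 * row_max_missing))
    x <- x[-rm_rows, , drop = FALSE]
  }
  rm_cols <- which(colMeans(is.na(x)) > col_max_missing)
  if (length(rm_cols) > 0L) {
    log <- c(log, sprintf("removed column(s) with >%.0f%% missingness: %s",
                          100 * col_max_missing,
                          paste(names(x)[rm_cols], collapse = ", ")))
    x <- x[, -rm_cols, drop = FALSE]
  }
  if (nrow(x) == 0L || ncol(x) == 0L)
    .mc_error("missingness filter removed everything", "mc_empty_output")
  list(table = x, removed_rows = rm_rows, removed_cols = rm_cols, log = log)
}

#' Iterative random-forest imputation
#'
#' Non-parametric imputation in the missForest style: missing cells are
#' initialized with column means, then each incomplete column (in order of
#' increasing missingness) is regressed on all other columns with a random
#' forest and its missing entries replaced by forest predictions. Sweeps
#' repeat until the normalized change in imputed values increases or
#' \code{max_iter} is reached; the values from the last improving sweep are
#' returned. Observed cells are never altered. Deterministic given
#' \code{seed}.
#'
#' @param table numeric data.frame or matrix with missing values.
#' @param n_trees trees per forest (default 100).
#' @param max_iter maximum sweeps (default 10).
#' @param seed integer seed.
#' @return list of class \code{imputation_result}: \code{ximp} (completed
#'   data.frame), \code{mask} (logical matrix of imputed cells),
#'   \code{iterations}, \code{trace} (per-sweep normalized change).
#' @export
rf_impute <- function(table, n_trees = 100L, max_iter = 10L, seed = 1L) {
  x <- as.data.frame(table)
  num <- vapply(x, is.numeric, logical(1))
  if (!all(num))
    .mc_error("rf_impute expects numeric columns (one-hot encode categoricals)",
              "mc_validation_error")
  m <- as.matrix(x)
  mask <- is.na(m)
  if (mean(mask) >= 0.5)
    .mc_error("overall missingness must stay below 50%", "mc_validation_error")
  all_missing <- colSums(!mask) == 0L
  if (any(all_missing))
    .mc_error(paste0("column(s) entirely missing: ",
                     paste(colnames(m)[all_missing], collapse = ", ")),
              "mc_validation_error")
  if (!any(mask))
    return(structure(list(ximp = x, mask = mask, iterations = 0L,
                          trace = numeric()),
                     class = "imputation_result"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # mean initialization
  for (j in which(colSums(mask) > 0L))
    m[mask[, j], j] <- mean(m[!mask[, j], j])
  cols <- order(colSums(mask))
  cols <- cols[colSums(mask)[cols] > 0L]
  trace <- numeric()
  prev <- m
  best <- m
  iterations <- 0L
  prev_change <- Inf
  for (iter in seq_len(max_iter)) {
    for (j in cols) {
      obs <- !mask[, j]
      fit <- suppressWarnings(
        randomForest::randomForest(x = m[obs, -j, drop = FALSE],
                                   y = m[obs, j], ntree = n_trees))
      m[mask[, j], j] <- stats::predict(fit, m[mask[, j], -j, drop = FALSE])
    }
    change <- sum((m[mask] - prev[mask])^2) / max(sum(m[mask]^2),
                                                  .Machine$double.eps)
    trace <- c(trace, change)
    iterations <- iter
    if (change >= prev_change) break   # diverging: keep previous sweep
    best <- m
    prev <- m
    prev_change <- change
  }
  ximp <- as.data.frame(best)
  names(ximp) <- names(x)
  rownames(ximp) <- rownames(x)
  stopifnot(identical(unname(as.matrix(ximp)[!mask]), unname(as.matrix(x)[!mask])))
  structure(list(ximp = ximp, mask = mask, iterations = iterations,
                 trace = trace),
            class = "imputation_result")
}

#' Scale and embed a complete table by PCA
#'
#' Columns are standardized to zero mean and unit variance (zero-variance
#' columns are dropped with a warning), then decomposed by PCA. The sign of
#' each component is fixed so that its largest-magnitude loading is
#' positive, making loadings reproducible across runs.
#'
#' @param table complete numeric data.frame or matrix.
#' @param n_dims number of dimensions to retain (default: all).
#' @return list of class \code{embedding_result}: \code{scores},
#'   \code{loadings}, \code{var_explained}, \code{dropped_cols}.
#' @export
embed_pca <- function(table, n_dims = NULL) {
  x <- as.matrix(table)
  if (any(is.na(x)))
    .mc_error("PCA input must be complete; impute first", "mc_validation_error")
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0L) {
    warning("dropping zero-variance column(s): ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  xs <- scale(x)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  if (is.null(n_dims)) n_dims <- ncol(pc$x)
  n_dims <- min(n_dims, ncol(pc$x))
  load <- pc$rotation[, seq_len(n_dims), drop = FALSE]
  scores <- pc$x[, seq_len(n_dims), drop = FALSE]
  for (j in seq_len(n_dims)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = load,
                 var_explained = ve[seq_len(n_dims)], dropped_cols = dropped),
            class = "embedding_result")
}

#' JackStraw significance of principal components
#'
#' Permutation test in the JackStraw style: in each replicate a small
#' fraction of columns is chosen and their values permuted across rows, PCA
#' is recomputed, and the squared correlation of each permuted column with
#' the leading component scores forms the null. Observed scores are the
#' squared correlations of every original column with the original
#' components. A dimension's p-value is a one-sided rank-sum comparison of
#' the observed association scores against that dimension's null (a real
#' component shifts the association scores of its loading variables upward
#' as a group). The number of significant dimensions is counted from the
#' first component until the first non-significant one.
#'
#' @param table complete numeric table (scaled internally via
#'   \code{\link{embed_pca}}).
#' @param n_perm permutation replicates (default 1000; at least 100).
#' @param perm_fraction fraction of columns permuted per replicate
#'   (default 0.01, at least one column).
#' @param alpha significance level for a dimension (default 0.05).
#' @param n_dims_test leading components tested (default 10).
#' @param seed integer seed; identical seeds give identical p-values.
#' @return list with \code{n_significant}, \code{p_values},
#'   \code{observed}, \code{null}.
#' @export
jackstraw <- function(table, n_perm = 1000L, perm_fraction = 0.01,
                      alpha = 0.05, n_dims_test = 10L, seed = 1L) {
  if (n_perm < 100L) .mc_error("need n_perm >= 100", "mc_validation_error")
  x <- as.matrix(table)
  sds <- apply(x, 2L, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  xs <- scale(x)
  p <- ncol(xs)
  d <- min(n_dims_test, p - 1L, nrow(xs) - 1L)
  emb <- embed_pca(xs, n_dims = d)
  obs <- matrix(NA_real_, p, d)
  for (j in seq_len(p)) obs[j, ] <- stats::cor(xs[, j], emb$scores)^2
  n_col_perm <- max(1L, ceiling(perm_fraction * p))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null <- matrix(NA_real_, n_perm * n_col_perm, d)
  row <- 0L
  for (r in seq_len(n_perm)) {
    xp <- xs
    cols <- sample.int(p, n_col_perm)
    for (cc in cols) xp[, cc] <- xp[sample.int(nrow(xp)), cc]
    pcp <- stats::prcomp(xp, center = FALSE, scale. = FALSE)
    sc <- pcp$x[, seq_len(d), drop = FALSE]
    for (cc in cols) {
      row <- row + 1L
      null[row, ] <- stats::cor(xp[, cc], sc)^2
    }
  }
  pvals <- vapply(seq_len(d), function(jdim) {
    stats::wilcox.test(obs[, jdim], null[, jdim], alternative = "greater",
                       exact = FALSE)$p.value
  }, numeric(1))
  sig <- pvals < alpha
  n_sig <- if (!sig[1]) 0L else which.min(c(sig, FALSE)) - 1L
  list(n_significant = n_sig, p_values = pvals, observed = obs, null = null)
}

#' Shared-nearest-neighbour Jaccard graph
#'
#' Each point's neighbourhood is itself plus its k nearest neighbours by
#' Euclidean distance in the embedding (ties broken by index). Edges carry
#' the Jaccard overlap |N(i) n N(j)| / |N(i) u N(j)|; weights below
#' \code{prune_threshold} are dropped.
#'
#' @param scores numeric matrix, points x embedding dimensions.
#' @param k neighbours per point (default 10).
#' @param prune_threshold minimum retained Jaccard weight (default 1/15).
#' @return an \code{igraph} weighted undirected graph with one vertex per
#'   point.
#' @export
snn_graph <- function(scores, k = 10L, prune_threshold = 1 / 15) {
  x <- as.matrix(scores)
  n <- nrow(x)
  if (n < k + 1L) .mc_error("need at least k+1 points", "mc_validation_error")
  dm <- as.matrix(stats::dist(x))
  nb <- matrix(0L, n, k + 1L)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ])            # stable: ties broken by index
    ord <- c(i, setdiff(ord, i))     # self first
    nb[i, ] <- ord[seq_len(k + 1L)]
  }
  nb_sets <- lapply(seq_len(n), function(i) sort(nb[i, ]))
  edges <- integer(); weights <- numeric()
  for (i in seq_len(n - 1L)) {
    si <- nb_sets[[i]]
    for (j in seq.int(i + 1L, n)) {
      inter <- length(intersect(si, nb_sets[[j]]))
      if (inter == 0L) next
      w <- inter / (2L * (k + 1L) - inter)
      if (w >= prune_threshold) {
        edges <- c(edges, i, j)
        weights <- c(weights, w)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, edges, attr = list(weight = weights))
  g
}

#' Leiden partition of a weighted graph
#'
#' Optimizes the resolution-parameterized modularity objective with the
#' Leiden algorithm. Labels are returned 0-based and contiguous, ordered by
#' decreasing cluster size. An edgeless graph yields one singleton cluster
#' per node with a warning.
#'
#' @param graph an \code{igraph} graph (weights used when present).
#' @param resolution resolution parameter (default 0.9).
#' @param seed integer seed; identical seeds give identical labels.
#' @param n_iterations Leiden iterations (default 10).
#' @return list of class \code{cluster_result}: \code{labels} (0-based),
#'   \code{n_clusters}, \code{quality} (modularity at the resolution).
#' @export
leiden_partition <- function(graph, resolution = 0.9, seed = 1L,
                             n_iterations = 10L) {
  n <- igraph::vcount(graph)
  if (igraph::ecount(graph) == 0L) {
    warning("graph has no edges; every node is its own cluster")
    return(structure(list(labels = seq_len(n) - 1L, n_clusters = n,
                          quality = 0), class = "cluster_result"))
  }
  w <- igraph::E(graph)$weight
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               weights = w, resolution = resolution,
                               n_iterations = n_iterations)
  mem <- igraph::membership(cl)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(mem)])
  q <- igraph::modularity(graph, mem, weights = w, resolution = resolution)
  structure(list(labels = labels, n_clusters = length(sizes), quality = q),
            class = "cluster_result")
}

#' Annotate clusters with severity labels
#'
#' Clusters are ordered by a composite burden score - each cluster's mean
#' loose stools (standardized across clusters, ascending) minus its
#' standardized mean IBDQ-32 total, so that diarrhea burden and
#' quality-of-life loss contribute equally on comparable scales - with
#' cluster size (descending, logged) breaking exact ties, and named from
#' the five-level
#' vocabulary remission, partial remission, mild, moderate, severe. When
#' fewer clusters than labels exist, labels are taken from the extremes
#' inward (2 clusters: remission + severe), keeping the annotation
#' one-to-one; with more than five clusters, burden-adjacent clusters share
#' labels and a warning is raised.
#'
#' @param labels cluster labels per patient-timepoint (0-based).
#' @param features data.frame aligned with \code{labels}, carrying
#'   \code{mean_loose} and \code{ibdq_total}.
#' @return list of class \code{severity_annotation}: \code{annotation}
#'   (character per observation), \code{mapping} (data.frame: label,
#'   severity, mean_loose, ibdq_total, size), \code{tie_log}.
#' @export
annotate_clusters <- function(labels, features) {
  if (length(labels) != nrow(features))
    .mc_error("labels and features must be aligned", "mc_validation_error")
  vocab <- c("remission", "partial remission", "mild", "moderate", "severe")
  uls <- sort(unique(labels))
  k <- length(uls)
  stat <- data.frame(
    label = uls,
    mean_loose = vapply(uls, function(l) mean(features$mean_loose[labels == l],
                                              na.rm = TRUE), numeric(1)),
    ibdq_total = vapply(uls, function(l) mean(features$ibdq_total[labels == l],
                                              na.rm = TRUE), numeric(1)),
    size = vapply(uls, function(l) sum(labels == l), integer(1))
  )
  zsafe <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  burden <- zsafe(stat$mean_loose) - zsafe(stat$ibdq_total)
  ord <- order(burden, -stat$size, stat$label)
  tie_log <- character()
  dup <- duplicated(burden) | duplicated(burden, fromLast = TRUE)
  if (any(dup))
    tie_log <- sprintf("burden tie between clusters %s broken by size",
                       paste(stat$label[dup], collapse = ", "))
  # label selection from the extremes inward: remission, severe, partial, ...
  if (k <= 5L) {
    pick_order <- c(1L, 5L, 2L, 4L, 3L)
    sev <- vocab[sort(pick_order[seq_len(k)])]
  } else {
    # more clusters than vocabulary levels: burden-adjacent clusters share
    # a label and the annotation is no longer one-to-one
    warning(sprintf("%d clusters exceed the 5-level severity vocabulary; %s",
                    k, "adjacent clusters share labels"))
    sev <- vocab[round(seq(1, 5, length.out = k))]
  }
  stat <- stat[ord, ]
  stat$severity <- sev
  ann <- stat$severity[match(labels, stat$label)]
  structure(list(annotation = ann, mapping = stat, tie_log = tie_log),
            class = "severity_annotation")
}

#' Full severity-clustering pipeline
#'
#' Chains the unsupervised stages: missingness filter, random-forest
#' imputation (when needed), scaling + PCA, JackStraw dimension selection,
#' shared-nearest-neighbour graph (k = 10, Jaccard weights) and Leiden
#' partitioning at resolution 0.9, followed by burden-ordered severity
#' annotation.
#'
#' @param features numeric data.frame of clustering variables (one row per
#'   patient-timepoint); must include \code{mean_loose} and
#'   \code{ibdq_total} for the annotation step.
#' @param k nearest neighbours (default 10).
#' @param resolution Leiden resolution (default 0.9).
#' @param n_dims number of PCA dimensions, or \code{"jackstraw"} (default)
#'   to select by permutation significance.
#' @param n_dims_min floor on the embedding dimensionality when JackStraw
#'   selection is used (default 6). Severity cohorts are often dominated by
#'   a single symptom-burden component; embedding in a single significant
#'   dimension makes every patient group a near one-dimensional chain in
#'   which shared-neighbour graphs fragment, so the neighbourhood geometry
#'   is kept isotropic by retaining at least this many components.
#' @param jackstraw_n_perm replicates for the JackStraw stage (default 1000).
#' @param seed master seed for the stochastic stages.
#' @param row_max_missing,col_max_missing missingness filter limits.
#' @param n_trees trees per imputation forest.
#' @return list of class \code{severity_clustering}: \code{labels},
#'   \code{annotation}, \code{n_clusters}, \code{kept_rows}, \code{filter},
#'   \code{imputation}, \code{embedding}, \code{n_dims}, \code{partition}.
#' @export
cluster_severity <- function(features, k = 10L, resolution = 0.9,
                             n_dims = "jackstraw", n_dims_min = 6L,
                             jackstraw_n_perm = 1000L,
                             seed = 1L, row_max_missing = 0.2,
                             col_max_missing = 0.2, n_trees = 100L) {
  flt <- filter_missing(features, row_max_missing, col_max_missing)
  x <- flt$table
  imp <- NULL
  if (anyNA(x)) {
    imp <- rf_impute(x, n_trees = n_trees, seed = seed)
    x <- imp$ximp
  }
  js <- NULL
  if (identical(n_dims, "jackstraw")) {
    js <- jackstraw(x, n_perm = jackstraw_n_perm, seed = seed + 1L)
    n_use <- min(max(n_dims_min, js$n_significant), ncol(x) - 1L)
  } else n_use <- as.integer(n_dims)
  emb <- embed_pca(x, n_dims = n_use)
  g <- snn_graph(emb$scores, k = k)
  part <- leiden_partition(g, resolution = resolution, seed = seed + 2L)
  ann <- annotate_clusters(part$labels, x)
  kept <- setdiff(seq_len(nrow(as.data.frame(features))), flt$removed_rows)
  structure(list(labels = part$labels, annotation = ann$annotation,
                 n_clusters = part$n_clusters, kept_rows = kept,
                 filter = flt, imputation = imp, embedding = emb,
                 n_dims = n_use, jackstraw = js, partition = part,
                 severity_mapping = ann$mapping),
            class = "severity_clustering")
}
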