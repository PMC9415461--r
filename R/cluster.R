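#' Condition-condition correlation of Fourier feature vectors
#'
#' Pearson correlation between every pair of condition rows of a
#' normalized feature matrix (the condition-level heat map).
#'
#' @param fm A `feature_matrix` (see [build_feature_matrix()]); it should
#'   be column-normalized for the clustering workflow.
#' @return Symmetric correlation matrix with unit diagonal, one
#'   row/column per condition.
#' @export
condition_correlation <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  m <- unclass(fm)
  if (nrow(m) < 2)
    stop("need at least 2 conditions", call. = FALSE)
  v <- apply(m, 1, stats::sd)
  if (any(v < 1e-12))
    stop("zero-variance feature vector for condition(s): ",
         paste(rownames(m)[v < 1e-12], collapse = ", "), call. = FALSE)
  r <- stats::cor(t(m))
  diag(r) <- 1
  r
}

#' Hierarchically cluster conditions by correlation distance
#'
#' Agglomerative clustering of conditions with distance `d = 1 - r`
#' (one minus Pearson correlation) and the named linkage.
#'
#' @param corr Condition correlation matrix ([condition_correlation()]).
#' @param linkage One of `"average"` (default), `"single"`, `"complete"`.
#' @param k Number of flat clusters to cut the tree into.
#' @return A `cluster_result`: `conditions`, `correlation`, `distance`,
#'   the `hclust` `tree`, `k`, and the flat integer `clusters`.
#' @examples
#' fm <- table2_features(normalize = TRUE)
#' cluster_conditions(condition_correlation(fm), k = 2)
#' @export
cluster_conditions <- function(corr, linkage = "average", k = 2) {
  supported <- c("average", "single", "complete")
  if (!is.character(linkage) || !(linkage %in% supported))
    stop("unknown linkage '", paste(linkage, collapse = ","),
         "'; supported: ", paste(supported, collapse = ", "),
         call. = FALSE)
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("'corr' must be a square correlation matrix", call. = FALSE)
  if (max(abs(corr - t(corr))) > 1e-8 || any(abs(diag(corr) - 1) > 1e-8) ||
      any(corr < -1 - 1e-8 | corr > 1 + 1e-8))
    stop("'corr' is not a valid correlation matrix", call. = FALSE)
  d <- stats::as.dist(1 - corr)
  tree <- stats::hclust(d, method = linkage)
  k <- as.integer(k)
  if (k < 1 || k > nrow(corr))
    stop("'k' must lie in 1..", nrow(corr), call. = FALSE)
  structure(list(conditions = rownames(corr), correlation = corr,
                 distance = d, tree = tree, k = k,
                 clusters = stats::cutree(tree, k = k)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d conditions, %s linkage on 1 - r, k = %d\n",
              length(x$conditions), x$tree$method, x$k))
  for (g in sort(unique(x$clusters)))
    cat(sprintf("  cluster %d: %s\n", g,
                paste(names(x$clusters)[x$clusters == g], collapse = ", ")))
  invisible(x)
}

#' End-to-end archetype recovery report
#'
#' Runs the full profiling pipeline — aggregate, center/scale, DFT,
#' dominant features, normalized feature matrix, condition correlation,
#' hierarchical clustering at `k = `number of archetypes — on a set of
#' replicated conditions with known archetype labels, and scores how well
#' the flat clusters recover the archetypes (adjusted Rand index; 1 =
#' perfect recovery).
#'
#' @param records Records data frame covering all condition replicates.
#' @param truth Named character vector mapping each condition label to its
#'   true archetype.
#' @param linkage Linkage passed to [cluster_conditions()].
#' @return List: `feature_matrix`, `correlation`, `clusters` (the
#'   `cluster_result`), `truth`, and `agreement` (adjusted Rand index
#'   between flat clusters and archetype labels).
#' @export
archetype_recovery_report <- function(records, truth, linkage = "average") {
  conds <- unique(records$condition)
  if (is.null(names(truth)) || !all(conds %in% names(truth)))
    stop("'truth' must name every condition in the records", call. = FALSE)
  truth <- truth[conds]
  archetypes <- unique(truth)
  if (length(archetypes) < 2)
    stop("need replicates of at least 2 archetypes", call. = FALSE)
  if (any(table(truth) < 2))
    stop("need at least 2 replicate conditions per archetype", call. = FALSE)
  centered <- lapply(aggregate_records(records), center_scale)
  fm <- build_feature_matrix(spectral_features(centered), normalize = TRUE)
  corr <- condition_correlation(fm)
  cl <- cluster_conditions(corr, linkage = linkage, k = length(archetypes))
  agreement <- mclust::adjustedRandIndex(cl$clusters[conds],
                                         as.character(truth))
  list(feature_matrix = fm, correlation = corr, clusters = cl,
       truth = truth, agreement = agreement)
}
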