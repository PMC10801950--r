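# Subject-level unsupervised classification: PCA on Z-scores and Ward
# hierarchical clustering on correlation distances, with diagnosis-agreement
# scoring.

#' Principal component analysis of subjects
#'
#' Singular-value decomposition of the column-centered Z-score matrix. No
#' further scaling is applied: incoming variables are already unit-variance,
#' and re-standardizing standardized data is idempotent.
#'
#' @param table a complete-case `zscore_table` (run [complete_case_filter()]
#'   then [z_score()] first).
#' @return A `pca_result` list: `scores` (subjects x components), `loadings`
#'   (variables x components, orthonormal), `explained_variance` (fractions,
#'   non-increasing), `sdev`.
#' @export
pca_subjects <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (anyNA(table$values)) {
    stop_koaev("missing values present; apply complete_case_filter() first",
               "koaev_missing_values")
  }
  pc <- prcomp(table$values, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(
    list(
      scores = pc$x,
      loadings = pc$rotation,
      explained_variance = ev / sum(ev),
      sdev = pc$sdev,
      center = pc$center
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d subjects, %d components; PC1-2 explain %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained_variance[1:min(2, length(x$explained_variance))])))
  invisible(x)
}

#' Hierarchical clustering of subjects on correlation distance
#'
#' Pairwise subject dissimilarity is `1 - r`, the Pearson correlation
#' between the subjects' variable profiles, agglomerated with the Ward
#' method on unsquared distances (`"ward.D"`; set `squared = TRUE` for
#' classical Ward on squared distances) and cut into `n_clusters` flat
#' labels. Diagnosis and sex are labels, not features, so clustering never
#' sees them; agreement with diagnosis is scored afterwards with the
#' adjusted Rand index and cluster purity.
#'
#' @param table a complete-case `zscore_table` (or [cohort_table()]).
#' @param n_clusters number of flat clusters (default 2).
#' @param squared use classical Ward on squared distances (`"ward.D2"`).
#' @return A `subject_clustering` list: `tree` (hclust), `labels`,
#'   `ari`, `purity`, `n_clusters`.
#' @export
cluster_subjects <- function(table, n_clusters = 2, squared = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  if (anyNA(table$values)) {
    stop_koaev("missing values present; apply complete_case_filter() first",
               "koaev_missing_values")
  }
  if (n_clusters < 2 || n_clusters > nrow(table$values)) {
    stop_koaev("n_clusters must lie between 2 and the number of subjects",
               "koaev_bad_input")
  }
  d <- as.dist(1 - cor(t(table$values)))
  tree <- hclust(d, method = if (squared) "ward.D2" else "ward.D")
  labels <- cutree(tree, k = n_clusters)
  structure(
    list(
      tree = tree,
      labels = setNames(labels, table$subjects),
      ari = adjusted_rand_index(labels, as.character(table$diagnosis)),
      purity = cluster_purity(labels, as.character(table$diagnosis)),
      n_clusters = n_clusters
    ),
    class = "subject_clustering"
  )
}

#' @export
print.subject_clustering <- function(x, ...) {
  cat(sprintf(
    "<subject_clustering> %d clusters over %d subjects; ARI vs diagnosis = %.3f, purity = %.3f\n",
    x$n_clusters, length(x$labels), x$ari, x$purity
  ))
  invisible(x)
}

#' Export a linkage tree in Newick format
#'
#' Writes the dendrogram of a clustering (subjects or variables) as a
#' nested-parenthesis tree with merge heights as branch lengths.
#'
#' @param tree an `hclust` object, or a result of [cluster_subjects()] /
#'   [cluster_variables()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_tree_newick <- function(tree, path) {
  if (inherits(tree, "subject_clustering")) tree <- tree$tree
  if (inherits(tree, "group_assignment")) tree <- attr(tree, "tree")
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
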