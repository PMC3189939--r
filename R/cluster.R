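#' Average-linkage hierarchical clustering of samples
#'
#' Clusters the sample columns (points in probe space) by UPGMA/average
#' linkage over pairwise Euclidean distances, via [stats::hclust()]. Feed it
#' the probe-filtered, log2-transformed table: the transform is explicit, not
#' implied.
#'
#' @param x An expression tibble of log-scale values with at least 2 samples.
#' @param top_k_variance Optional integer; when given, only the `k` probes of
#'   highest across-sample variance are used. Default `NULL` uses all probes.
#' @return An object of class [stats::hclust] whose labels are sample ids.
#' @export
cluster_samples <- function(x, top_k_variance = NULL) {
  x <- as_expression_tbl(x)
  m <- expr_matrix(x)
  if (ncol(m) < 2) abort("Clustering needs at least 2 samples.")
  if (!is.null(top_k_variance)) {
    k <- min(as.integer(top_k_variance), nrow(m))
    v <- apply(m, 1, var)
    m <- m[order(v, decreasing = TRUE)[seq_len(k)], , drop = FALSE]
  }
  hclust(dist(t(m), method = "euclidean"), method = "average")
}

#' Cut a sample dendrogram into the two primary groups
#'
#' The two subtrees below the root merge define Group 1 and Group 2. Which
#' subtree is called Group 1 is controlled by `anchor`: a sample id (its
#' subtree becomes Group 1), or — together with `labels` — a class label
#' (the subtree where that label is the majority becomes Group 1). With no
#' anchor the smaller subtree is Group 1, ties broken by the subtree holding
#' the lexicographically smallest sample id.
#'
#' @param hc An [stats::hclust] object from [cluster_samples()].
#' @param anchor Optional sample id or class label designating Group 1.
#' @param labels Optional named character vector mapping sample id to class
#'   label; required when `anchor` is a label.
#' @return A grouping tibble (`sample_id`, `group`).
#' @export
cut_into_two_groups <- function(hc, anchor = NULL, labels = NULL) {
  if (!inherits(hc, "hclust")) abort("`hc` must be an hclust object.")
  cl <- cutree(hc, k = 2)
  ids <- names(cl)
  side_a <- ids[cl == 1]
  side_b <- ids[cl == 2]
  g1 <- NULL
  if (!is.null(anchor)) {
    if (anchor %in% ids) {
      g1 <- if (anchor %in% side_a) side_a else side_b
    } else if (!is.null(labels)) {
      if (!all(ids %in% names(labels))) abort("`labels` must cover every sample.")
      if (!anchor %in% labels) abort(sprintf("Anchor label '%s' not found.", anchor))
      frac_a <- mean(labels[side_a] == anchor)
      frac_b <- mean(labels[side_b] == anchor)
      g1 <- if (frac_a >= frac_b) side_a else side_b
    } else {
      abort(sprintf("Anchor '%s' is neither a sample id nor a label with `labels` given.", anchor))
    }
  } else {
    if (length(side_a) != length(side_b)) {
      g1 <- if (length(side_a) < length(side_b)) side_a else side_b
    } else {
      g1 <- if (min(side_a) < min(side_b)) side_a else side_b
    }
  }
  as_grouping_tbl(tibble(
    sample_id = ids,
    group = ifelse(ids %in% g1, 1L, 2L)
  ))
}
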