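#' Two-group differential expression, probe by probe
#'
#' For each probe, a Welch (unequal-variance) two-sample t-test on
#' log2-transformed intensities compares Group 1 to Group 2, with
#' Benjamini-Hochberg adjustment across all tested probes. A probe is called
#' differentially expressed when `fdr < fdr_threshold` *and* the ratio of the
#' larger to the smaller linear-scale group mean exceeds `fold_threshold`. A
#' gene is differentially expressed when at least one of its probes passes;
#' its direction is the passing probe's sign.
#'
#' @param x An expression tibble of linear-scale intensities, already
#'   probe-filtered (see [filter_probes_by_max_intensity()]).
#' @param grouping A grouping tibble covering exactly the samples of `x`;
#'   both groups need at least two samples.
#' @param fold_threshold Minimum linear fold change between group means
#'   (strict; default 2.5).
#' @param fdr_threshold BH threshold (strict; default 0.05).
#' @param pseudocount Offset for the log2 transform feeding the t-test.
#' @return A tibble of class `cafet_de`, one row per probe: `probe_id`,
#'   `gene`, `mean_group1`, `mean_group2` (linear scale), `fold_change`
#'   (max/min ratio, `>= 1`), `direction` (`"group1"`/`"group2"`, the group
#'   with the larger mean), `t`, `p_value`, `fdr`, `degenerate`, `is_de`.
#' @seealso [de_genes()] for the per-direction gene lists.
#' @export
differential_expression <- function(x, grouping, fold_threshold = 2.5,
                                    fdr_threshold = 0.05, pseudocount = 1) {
  x <- as_expression_tbl(x)
  check_nonnegative_intensities(x)
  smp <- expr_sample_ids(x)
  grouping <- as_grouping_tbl(grouping, sample_ids = smp)
  g1 <- group_samples(grouping, 1L)
  g2 <- group_samples(grouping, 2L)
  if (length(g1) < 2 || length(g2) < 2) {
    abort("Each group needs at least 2 samples for differential expression.")
  }
  m <- expr_matrix(x)
  lg <- log2(m + pseudocount)
  w <- welch_rows(lg, match(g1, colnames(m)), match(g2, colnames(m)))
  mean1 <- rowMeans(m[, g1, drop = FALSE])
  mean2 <- rowMeans(m[, g2, drop = FALSE])
  hi <- pmax(mean1, mean2); lo <- pmin(mean1, mean2)
  fold <- ifelse(hi == lo, 1, ifelse(lo == 0, Inf, hi / lo))
  fdr <- benjamini_hochberg(w$p)
  out <- tibble(
    probe_id = x$probe_id,
    gene = x$gene,
    mean_group1 = unname(mean1),
    mean_group2 = unname(mean2),
    fold_change = unname(fold),
    direction = unname(ifelse(mean1 >= mean2, "group1", "group2")),
    t = unname(w$t),
    p_value = unname(w$p),
    fdr = unname(fdr),
    degenerate = unname(w$degenerate),
    is_de = unname(fdr < fdr_threshold & fold > fold_threshold)
  )
  structure(out,
            class = c("cafet_de", class(out)),
            fold_threshold = fold_threshold,
            fdr_threshold = fdr_threshold)
}

#' Differentially expressed genes by direction
#'
#' Applies the any-probe rule to a [differential_expression()] result: a gene
#' is listed for a direction when at least one of its probes passes with the
#' larger mean in that group. Probes without a gene mapping are ignored. A
#' gene with probes passing in both directions appears in both lists.
#'
#' @param de A `cafet_de` tibble.
#' @param direction `"group1"` (higher in Group 1) or `"group2"`.
#' @return Character vector of gene symbols.
#' @export
de_genes <- function(de, direction = c("group1", "group2")) {
  direction <- match.arg(direction)
  hit <- de$is_de & de$direction == direction & !is.na(de$gene)
  sort(unique(de$gene[hit]))
}
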