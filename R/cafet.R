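#' Flag dysregulated samples per gene
#'
#' The sample-axis primitive: for every gene, find the samples in which it is
#' dysregulated relative to a per-probe baseline. The baseline of each probe
#' is its median across *all* samples (or, optionally, its mean over Group 2
#' samples). A sample is flagged `up` for a gene when any of the gene's
#' probes exceeds `up_fold` times that probe's baseline (strict), and `down`
#' when any probe falls below `down_fold` times the baseline (strict). The
#' thresholds are asymmetric because baseline noise limits the observable
#' magnitude of down-regulation.
#'
#' A probe with baseline 0 can never flag `down` (nothing is `< 0`) and flags
#' `up` for any positive value; such probes are reported via a message.
#'
#' @param x An expression tibble of linear-scale intensities.
#' @param genes Character vector of gene symbols to evaluate; default all
#'   mapped genes. A requested gene absent from the table is an error.
#' @param up_fold Up-regulation multiple of the baseline (default 2.5).
#' @param down_fold Down-regulation multiple of the baseline (default 0.5).
#' @param baseline `"median"` (per-probe median over all samples, the
#'   default) or `"group2_mean"` (per-probe mean over Group 2; needs
#'   `grouping`).
#' @param grouping Grouping tibble, only for `baseline = "group2_mean"`.
#' @return A long tibble of class `cafet_flags` with columns `gene`,
#'   `direction` (`"up"`/`"down"`) and `sample_id`, one row per flagged
#'   (gene, direction, sample) event. Attributes `samples` (the full sample
#'   universe) and `genes` (every gene evaluated, flagged or not) support
#'   downstream counting.
#' @export
flag_dysregulated_samples <- function(x, genes = NULL, up_fold = 2.5,
                                      down_fold = 0.5,
                                      baseline = c("median", "group2_mean"),
                                      grouping = NULL) {
  x <- as_expression_tbl(x)
  check_nonnegative_intensities(x)
  baseline <- match.arg(baseline)
  if (is.null(genes)) genes <- unique(x$gene[!is.na(x$gene)])
  genes <- unique(genes)
  if (length(genes) == 0) abort("No genes to evaluate.")
  missing <- setdiff(genes, x$gene)
  if (length(missing) > 0) {
    abort(sprintf("Gene(s) absent from the expression table: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  keep <- !is.na(x$gene) & x$gene %in% genes
  sub <- x[keep, , drop = FALSE]
  m <- expr_matrix(sub)
  smp <- colnames(m)
  base <- switch(baseline,
    median = apply(m, 1, median),
    group2_mean = {
      if (is.null(grouping)) abort("`baseline = \"group2_mean\"` needs `grouping`.")
      grouping <- as_grouping_tbl(grouping, sample_ids = smp)
      rowMeans(m[, group_samples(grouping, 2L), drop = FALSE])
    }
  )
  n_zero <- sum(base == 0)
  if (n_zero > 0) {
    inform(sprintf(
      "%d probe(s) have baseline 0: they cannot flag 'down' and flag 'up' for any positive value.",
      n_zero))
  }
  up <- m > up_fold * base
  down <- m < down_fold * base
  gene_f <- factor(sub$gene, levels = genes)
  flag_long <- function(probe_flags, dir) {
    g <- rowsum(probe_flags + 0, group = gene_f) > 0   # any-probe union
    hit <- which(g, arr.ind = TRUE)
    if (nrow(hit) == 0) {
      return(tibble(gene = character(), direction = character(),
                    sample_id = character()))
    }
    tibble(gene = rownames(g)[hit[, 1]], direction = dir,
           sample_id = smp[hit[, 2]])
  }
  out <- dplyr::bind_rows(flag_long(up, "up"), flag_long(down, "down"))
  out <- out[order(out$gene, out$direction, out$sample_id, method = "radix"), ]
  structure(out, class = c("cafet_flags", class(out)),
            samples = smp, genes = genes)
}

#' Keep one direction of a flags object
#'
#' Subsets a `cafet_flags` tibble to a single direction while preserving its
#' sample universe and evaluated-gene attributes, as required by
#' [cafet_group_test()].
#'
#' @param flags A `cafet_flags` tibble.
#' @param direction `"up"` or `"down"`.
#' @return A `cafet_flags` tibble holding only the requested direction.
#' @export
filter_flags <- function(flags, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!inherits(flags, "cafet_flags")) {
    abort("`flags` must come from flag_dysregulated_samples().")
  }
  out <- flags[flags$direction == direction, , drop = FALSE]
  structure(out, class = class(flags),
            samples = attr(flags, "samples"), genes = attr(flags, "genes"))
}

#' Sample-axis enrichment test for single genes
#'
#' For each evaluated gene and direction, tests whether the samples in which
#' the gene is dysregulated concentrate in Group 1: with `S_T` total samples,
#' `S_G` Group 1 samples, `S_P` flagged samples and `S_C` flagged samples in
#' Group 1, `p = P(X >= S_C)` under the hypergeometric null. Genes with no
#' flagged sample get `S_P = 0`, `p = 1`.
#'
#' @param flags A `cafet_flags` tibble from [flag_dysregulated_samples()].
#' @param grouping A grouping tibble over exactly the flags' sample universe.
#' @return A tibble, one row per (gene, direction): `gene`, `direction`,
#'   `S_T`, `S_G`, `S_P`, `S_C`, `p_value`.
#' @export
cafet_gene_test <- function(flags, grouping) {
  if (!inherits(flags, "cafet_flags")) {
    abort("`flags` must come from flag_dysregulated_samples().")
  }
  samples <- attr(flags, "samples")
  genes <- attr(flags, "genes")
  grouping <- as_grouping_tbl(grouping)
  if (!setequal(grouping$sample_id, samples)) {
    abort("Grouping and flags cover different sample universes.")
  }
  g1 <- group_samples(grouping, 1L)
  s_t <- length(samples)
  s_g <- length(g1)
  grid <- tidyr::expand_grid(gene = genes, direction = c("up", "down"))
  counts <- dplyr::summarise(
    dplyr::group_by(flags, .data$gene, .data$direction),
    S_P = dplyr::n(),
    S_C = sum(.data$sample_id %in% g1),
    .groups = "drop"
  )
  out <- dplyr::left_join(grid, counts, by = c("gene", "direction"))
  out$S_P[is.na(out$S_P)] <- 0L
  out$S_C[is.na(out$S_C)] <- 0L
  out$S_T <- s_t
  out$S_G <- s_g
  out$p_value <- hypergeom_upper_tail(out$S_T, out$S_G, out$S_P, out$S_C)
  out[, c("gene", "direction", "S_T", "S_G", "S_P", "S_C", "p_value")]
}

#' Gene-by-gene CAFET with FDR over a gene list
#'
#' Flags dysregulated samples for each listed gene (deduplicated), tests each
#' gene with [cafet_gene_test()], and applies Benjamini-Hochberg separately
#' within each direction (up and down are independent batches, reported as
#' separate panels).
#'
#' @inheritParams flag_dysregulated_samples
#' @param grouping A grouping tibble over the table's samples.
#' @param genes Character vector of genes to test (e.g. a pathway's members);
#'   duplicated symbols are tested once.
#' @param direction Directions to analyse, default both.
#' @param fdr_threshold Threshold for the `significant` flag (default 0.05).
#' @return A tibble of class `cafet_gene_result` ordered by direction, then
#'   ascending p, then gene: columns of [cafet_gene_test()] plus `fdr` and
#'   `significant`.
#' @export
cafet_genes <- function(x, grouping, genes, direction = c("up", "down"),
                        up_fold = 2.5, down_fold = 0.5,
                        baseline = c("median", "group2_mean"),
                        fdr_threshold = 0.05) {
  direction <- match.arg(direction, several.ok = TRUE)
  flags <- flag_dysregulated_samples(x, genes = genes, up_fold = up_fold,
                                     down_fold = down_fold, baseline = baseline,
                                     grouping = grouping)
  res <- cafet_gene_test(flags, grouping)
  res <- res[res$direction %in% direction, , drop = FALSE]
  res <- dplyr::mutate(dplyr::group_by(res, .data$direction),
                       fdr = benjamini_hochberg(.data$p_value))
  res <- dplyr::ungroup(res)
  res$significant <- res$fdr < fdr_threshold
  res <- res[order(res$direction, res$p_value, res$gene, method = "radix"), ]
  structure(res, class = c("cafet_gene_result", class(res)),
            fdr_threshold = fdr_threshold)
}

#' Sample-axis enrichment of one functional group
#'
#' Pools the member genes' flagged-sample sets: `S_FP` is the size of the
#' union of the per-gene flagged sets (samples dysregulating *at least one*
#' member gene) and `S_FC` the part of that union in Group 1; the p-value is
#' the hypergeometric upper tail at those counts. A group is *eligible* only
#' when at least `min_contributing_genes` member genes have one or more
#' flagged samples; ineligible groups are excluded from downstream FDR
#' adjustment.
#'
#' @param flags A `cafet_flags` tibble holding the member genes' flags, all
#'   in one direction.
#' @param grouping A grouping tibble over the flags' sample universe.
#' @param min_contributing_genes Eligibility threshold (default 5).
#' @return A one-row tibble: `direction`, `n_genes_contributing`, `S_T`,
#'   `S_G`, `S_FP`, `S_FC`, `p_value`, `eligible`.
#' @export
cafet_group_test <- function(flags, grouping, min_contributing_genes = 5) {
  if (!inherits(flags, "cafet_flags")) {
    abort("`flags` must come from flag_dysregulated_samples().")
  }
  if (length(attr(flags, "genes")) == 0) abort("Empty member gene list.")
  dirs <- unique(flags$direction)
  if (length(dirs) > 1) {
    abort("Group-level CAFET takes flags of a single direction; filter first.")
  }
  samples <- attr(flags, "samples")
  grouping <- as_grouping_tbl(grouping)
  if (!setequal(grouping$sample_id, samples)) {
    abort("Grouping and flags cover different sample universes.")
  }
  g1 <- group_samples(grouping, 1L)
  union_samples <- unique(flags$sample_id)
  s_fp <- length(union_samples)
  s_fc <- sum(union_samples %in% g1)
  n_contrib <- length(unique(flags$gene))
  tibble(
    direction = if (length(dirs) == 1) dirs else NA_character_,
    n_genes_contributing = n_contrib,
    S_T = length(samples),
    S_G = length(g1),
    S_FP = s_fp,
    S_FC = s_fc,
    p_value = hypergeom_upper_tail(length(samples), length(g1), s_fp, s_fc),
    eligible = n_contrib >= min_contributing_genes
  )
}

#' Group-level CAFET across a gene-set collection
#'
#' Computes dysregulation flags once per gene (shared across overlapping
#' sets), evaluates every set with [cafet_group_test()] in the requested
#' direction, and applies Benjamini-Hochberg across the *eligible* sets only;
#' ineligible sets keep their p-value but get `fdr = NA`. Set members absent
#' from the expression table contribute nothing. Directions are separate
#' batches: run once per direction.
#'
#' @inheritParams flag_dysregulated_samples
#' @param grouping A grouping tibble over the table's samples.
#' @param sets A gene-set tibble (see [as_geneset_tbl()]).
#' @param direction `"up"` (the default, matching over-expression coverage)
#'   or `"down"`.
#' @param min_contributing_genes Eligibility threshold (default 5).
#' @param fdr_threshold Threshold for the `significant` flag (default 0.05).
#' @return A tibble of class `cafet_result`, one row per set, ordered by
#'   ascending p then `set_id`: `set_id`, `set_name`, `direction`,
#'   `n_genes_contributing`, `S_T`, `S_G`, `S_FP`, `S_FC`, `p_value`,
#'   `fdr`, `eligible`, `significant`.
#' @export
cafet_groups <- function(x, grouping, sets, direction = c("up", "down"),
                         up_fold = 2.5, down_fold = 0.5,
                         baseline = c("median", "group2_mean"),
                         min_contributing_genes = 5, fdr_threshold = 0.05) {
  direction <- match.arg(direction)
  x <- as_expression_tbl(x)
  sets <- as_geneset_tbl(sets)
  grouping <- as_grouping_tbl(grouping, sample_ids = expr_sample_ids(x))
  on_array <- intersect(unique(sets$gene), unique(x$gene[!is.na(x$gene)]))
  if (length(on_array) == 0) {
    warn("No gene-set member is present on the array; empty CAFET result.")
    return(empty_cafet_result(fdr_threshold))
  }
  flags <- flag_dysregulated_samples(x, genes = on_array, up_fold = up_fold,
                                     down_fold = down_fold, baseline = baseline,
                                     grouping = grouping)
  flags_dir <- flags[flags$direction == direction, , drop = FALSE]
  g1 <- group_samples(grouping, 1L)
  s_t <- length(attr(flags, "samples"))
  s_g <- length(g1)
  names_by_id <- dplyr::distinct(sets[, c("set_id", "set_name")])
  per_set <- dplyr::summarise(
    dplyr::group_by(
      dplyr::inner_join(sets[, c("set_id", "gene")], flags_dir,
                        by = "gene", relationship = "many-to-many"),
      .data$set_id),
    n_genes_contributing = dplyr::n_distinct(.data$gene),
    S_FP = dplyr::n_distinct(.data$sample_id),
    S_FC = dplyr::n_distinct(.data$sample_id[.data$sample_id %in% g1]),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble(set_id = unique(sets$set_id)), per_set,
                          by = "set_id")
  out$n_genes_contributing[is.na(out$n_genes_contributing)] <- 0L
  out$S_FP[is.na(out$S_FP)] <- 0L
  out$S_FC[is.na(out$S_FC)] <- 0L
  out <- dplyr::mutate(out,
    set_name = names_by_id$set_name[match(.data$set_id, names_by_id$set_id)],
    direction = direction,
    S_T = s_t,
    S_G = s_g,
    p_value = hypergeom_upper_tail(s_t, s_g, .data$S_FP, .data$S_FC),
    eligible = .data$n_genes_contributing >= min_contributing_genes
  )
  out$fdr <- NA_real_
  out$fdr[out$eligible] <- benjamini_hochberg(out$p_value[out$eligible])
  out$significant <- out$eligible & !is.na(out$fdr) & out$fdr < fdr_threshold
  out <- out[, c("set_id", "set_name", "direction", "n_genes_contributing",
                 "S_T", "S_G", "S_FP", "S_FC", "p_value", "fdr",
                 "eligible", "significant")]
  if (!any(out$eligible)) {
    warn("Every gene set is ineligible (too few contributing genes).")
  }
  out <- out[order(out$p_value, out$set_id, method = "radix"), ]
  structure(out, class = c("cafet_result", class(out)),
            fdr_threshold = fdr_threshold,
            min_contributing_genes = min_contributing_genes)
}

empty_cafet_result <- function(fdr_threshold) {
  out <- tibble(set_id = character(), set_name = character(),
                direction = character(), n_genes_contributing = integer(),
                S_T = integer(), S_G = integer(), S_FP = integer(),
                S_FC = integer(), p_value = numeric(), fdr = numeric(),
                eligible = logical(), significant = logical())
  structure(out, class = c("cafet_result", class(out)),
            fdr_threshold = fdr_threshold)
}
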