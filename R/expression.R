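#' Expression tables
#'
#' `cafet` represents a probe-by-sample expression matrix as a wide tibble:
#' a `probe_id` column (unique probe identifiers), a `gene` column (gene
#' symbol, `NA` for unmapped probes) and one numeric column per sample holding
#' non-negative linear-scale intensities. Every function that consumes
#' expression data takes such a tibble as its first argument, so pipelines
#' chain with the pipe. `as_expression_tbl()` validates and normalises a data
#' frame into this shape.
#'
#' @param x A data frame with a `probe_id` column, an optional `gene` column
#'   and numeric sample columns.
#' @return A tibble with columns `probe_id`, `gene`, then one column per
#'   sample.
#' @examples
#' as_expression_tbl(data.frame(
#'   probe_id = c("p1", "p2"), gene = c("TP53", "TP53"),
#'   s1 = c(120, 80), s2 = c(95, 110)
#' ))
#' @export
as_expression_tbl <- function(x) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)
  if (!"probe_id" %in% names(x)) abort("Expression table needs a `probe_id` column.")
  if (!"gene" %in% names(x)) {
    x$gene <- NA_character_
  }
  x$probe_id <- as.character(x$probe_id)
  x$gene <- as.character(x$gene)
  x <- dplyr::relocate(x, "probe_id", "gene")
  validate_expression_tbl(x)
  x
}

# Invariants: unique probes, unique samples, finite non-negative intensities.
validate_expression_tbl <- function(x, arg = "expression table") {
  dup <- x$probe_id[duplicated(x$probe_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicated probe id(s) in %s: %s", arg,
                  paste(unique(dup), collapse = ", ")))
  }
  smp <- expr_sample_ids(x)
  if (anyDuplicated(smp)) abort(sprintf("Duplicated sample ids in %s.", arg))
  for (s in smp) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("Column '%s' of %s is not numeric.", s, arg))
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      abort(sprintf("Non-finite value at probe '%s', sample '%s'.",
                    x$probe_id[bad[1]], s))
    }
  }
  invisible(x)
}

#' Sample identifiers of an expression table
#'
#' @param x An expression tibble (see [as_expression_tbl()]).
#' @return Character vector of sample column names.
#' @export
expr_sample_ids <- function(x) {
  setdiff(names(x), c("probe_id", "gene"))
}

#' Extract the numeric probe-by-sample matrix
#'
#' @param x An expression tibble.
#' @return A numeric matrix with probe ids as row names and sample ids as
#'   column names.
#' @export
expr_matrix <- function(x) {
  smp <- expr_sample_ids(x)
  m <- as.matrix(x[smp])
  rownames(m) <- x$probe_id
  m
}

#' Remove probes that never reach a minimum intensity
#'
#' Retains exactly the probes whose maximum linear-scale intensity across all
#' samples is at least `threshold`; probes whose maximum falls below the
#' threshold are dropped. The sample set is unchanged.
#'
#' @param x An expression tibble of linear-scale intensities.
#' @param threshold Minimum per-probe maximum intensity to keep (default 100).
#' @return The filtered expression tibble (possibly zero rows).
#' @examples
#' expr <- as_expression_tbl(data.frame(
#'   probe_id = c("a", "b"), s1 = c(50, 120), s2 = c(99, 40)
#' ))
#' filter_probes_by_max_intensity(expr, threshold = 100)
#' @export
filter_probes_by_max_intensity <- function(x, threshold = 100) {
  x <- as_expression_tbl(x)
  check_nonnegative_intensities(x)
  m <- expr_matrix(x)
  if (nrow(m) == 0) return(x)
  keep <- apply(m, 1, max) >= threshold
  x[keep, , drop = FALSE]
}

#' Log2-transform an expression table
#'
#' Replaces every intensity with `log2(value + pseudocount)`. Transformation
#' is always explicit: no other function log-transforms silently.
#'
#' @param x An expression tibble of linear-scale intensities (all `>= 0`).
#' @param pseudocount Non-negative offset added before taking logs (default 1).
#'   With `pseudocount = 0` every intensity must be strictly positive.
#' @return An expression tibble of the same shape holding log2 values.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  x <- as_expression_tbl(x)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    abort("`pseudocount` must be a single non-negative number.")
  }
  check_nonnegative_intensities(x)
  smp <- expr_sample_ids(x)
  for (s in smp) {
    v <- x[[s]] + pseudocount
    if (any(v <= 0)) {
      abort(sprintf("log2 undefined: zero intensity with pseudocount 0 in sample '%s'.", s))
    }
    x[[s]] <- log2(v)
  }
  x
}

check_nonnegative_intensities <- function(x) {
  for (s in expr_sample_ids(x)) {
    bad <- which(x[[s]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("Negative intensity at probe '%s', sample '%s'.",
                    x$probe_id[bad[1]], s))
    }
  }
  invisible(x)
}

#' Sample groupings
#'
#' A partition of the cohort into Group 1 and Group 2 (the two primary sample
#' clusters, or any caller-supplied two-group split such as histology) is a
#' tibble with columns `sample_id` and `group` (integer 1 or 2), plus an
#' optional `subgroup` column.
#'
#' @param x A data frame with columns `sample_id` and `group`.
#' @param sample_ids Optional character vector; when given, the grouping must
#'   cover exactly these samples.
#' @return A validated grouping tibble.
#' @export
as_grouping_tbl <- function(x, sample_ids = NULL) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)
  if (!all(c("sample_id", "group") %in% names(x))) {
    abort("Grouping needs `sample_id` and `group` columns.")
  }
  x$sample_id <- as.character(x$sample_id)
  x$group <- as.integer(x$group)
  if (anyDuplicated(x$sample_id)) abort("Duplicated sample id in grouping.")
  if (!all(x$group %in% c(1L, 2L))) abort("`group` must be 1 or 2.")
  if (!any(x$group == 1L) || !any(x$group == 2L)) {
    abort("Both groups must be non-empty.")
  }
  if (!is.null(sample_ids) && !setequal(x$sample_id, sample_ids)) {
    abort("Grouping samples do not match the expression table's samples.")
  }
  x
}

group_samples <- function(grouping, which = 1L) {
  grouping$sample_id[grouping$group == which]
}
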