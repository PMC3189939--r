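#' Tidy and summarise result objects
#'
#' `tidy()` strips the result class and returns a plain tibble; `glance()`
#' condenses a result into one row suitable for binding across runs.
#'
#' @param x A `cafet_result`, `cafet_gene_result`, `fga_result` or `cafet_de`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name cafet-tidiers
NULL

strip_result <- function(x) {
  class(x) <- setdiff(class(x),
                      c("cafet_result", "cafet_gene_result", "fga_result",
                        "cafet_de", "cafet_flags", "cafet_scores"))
  attr(x, "fdr_threshold") <- NULL
  attr(x, "min_contributing_genes") <- NULL
  attr(x, "fold_threshold") <- NULL
  attr(x, "samples") <- NULL
  attr(x, "genes") <- NULL
  as_tibble(x)
}

#' @rdname cafet-tidiers
#' @export
tidy.cafet_result <- function(x, ...) strip_result(x)

#' @rdname cafet-tidiers
#' @export
tidy.cafet_gene_result <- function(x, ...) strip_result(x)

#' @rdname cafet-tidiers
#' @export
tidy.fga_result <- function(x, ...) strip_result(x)

#' @rdname cafet-tidiers
#' @export
tidy.cafet_de <- function(x, ...) strip_result(x)

#' @rdname cafet-tidiers
#' @export
glance.cafet_result <- function(x, ...) {
  tibble(n_sets = nrow(x),
         n_eligible = sum(x$eligible),
         n_significant = sum(x$significant),
         min_fdr = if (any(x$eligible)) min(x$fdr[x$eligible]) else NA_real_,
         fdr_threshold = attr(x, "fdr_threshold") %||% NA_real_)
}

#' @rdname cafet-tidiers
#' @export
glance.cafet_gene_result <- function(x, ...) {
  tibble(n_tests = nrow(x),
         n_significant = sum(x$significant),
         min_fdr = if (nrow(x) > 0) min(x$fdr) else NA_real_,
         fdr_threshold = attr(x, "fdr_threshold") %||% NA_real_)
}

#' @rdname cafet-tidiers
#' @export
glance.fga_result <- function(x, ...) {
  tibble(n_sets = nrow(x),
         n_significant = sum(x$significant),
         min_fdr = if (nrow(x) > 0) min(x$fdr) else NA_real_,
         fdr_threshold = attr(x, "fdr_threshold") %||% NA_real_)
}

#' @rdname cafet-tidiers
#' @export
glance.cafet_de <- function(x, ...) {
  tibble(n_probes = nrow(x),
         n_de_probes = sum(x$is_de),
         n_de_genes_group1 = length(de_genes(x, "group1")),
         n_de_genes_group2 = length(de_genes(x, "group2")),
         fold_threshold = attr(x, "fold_threshold") %||% NA_real_,
         fdr_threshold = attr(x, "fdr_threshold") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
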