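#' Gene-axis over-representation of one functional group
#'
#' The conventional enrichment baseline (FGA): does a query gene list overlap
#' a functional group more than expected among the annotated genes of the
#' array? With `N_T` universe genes, `N_F` group genes in the universe, `N_G`
#' query genes and overlap `N_C`, the p-value is the inclusive hypergeometric
#' upper tail `P(X >= N_C)`. One-sided: over-representation only.
#'
#' @param query_genes Character vector of query gene symbols (e.g. a
#'   differentially expressed gene list); must be a subset of `universe`.
#' @param set_genes Character vector, the functional group's members; genes
#'   outside the universe are ignored.
#' @param universe Character vector of all genes on the (filtered) array,
#'   deduplicated by symbol.
#' @return A one-row tibble: `N_T`, `N_F`, `N_G`, `N_C`, `p_value`.
#' @export
fga_enrich_set <- function(query_genes, set_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("Empty gene universe.")
  query_genes <- unique(query_genes)
  stray <- setdiff(query_genes, universe)
  if (length(stray) > 0) {
    abort(sprintf("Query gene(s) outside the universe: %s",
                  paste(head(stray, 5), collapse = ", ")))
  }
  grp <- intersect(unique(set_genes), universe)
  n_t <- length(universe)
  n_f <- length(grp)
  n_g <- length(query_genes)
  n_c <- length(intersect(query_genes, grp))
  tibble(N_T = n_t, N_F = n_f, N_G = n_g, N_C = n_c,
         p_value = hypergeom_upper_tail(n_t, n_f, n_g, n_c))
}

#' Gene-axis over-representation across a collection
#'
#' Runs [fga_enrich_set()] for every set in a collection, skipping sets with
#' fewer than `min_set_size` genes in the universe (skipped sets do not count
#' toward the Benjamini-Hochberg `m`), then adjusts across the tested sets.
#'
#' @param query_genes Character vector of query genes, subset of `universe`.
#' @param sets A gene-set tibble (see [as_geneset_tbl()]).
#' @param universe Character vector of array genes.
#' @param min_set_size Minimum in-universe set size to be tested (default 5).
#' @param fdr_threshold Threshold for the `significant` flag (default 0.05).
#' @return A tibble of class `fga_result`, one row per tested set, ordered by
#'   ascending p then `set_id`: `set_id`, `set_name`, `N_T`, `N_F`, `N_G`,
#'   `N_C`, `p_value`, `fdr`, `significant`.
#' @export
fga_enrich <- function(query_genes, sets, universe, min_set_size = 5,
                       fdr_threshold = 0.05) {
  sets <- as_geneset_tbl(sets)
  universe <- unique(universe)
  in_univ <- sets[sets$gene %in% universe, , drop = FALSE]
  sizes <- table(in_univ$set_id)
  keep_ids <- names(sizes)[sizes >= min_set_size]
  if (length(keep_ids) == 0) {
    warn("No gene set reaches `min_set_size` in the universe; empty FGA result.")
    out <- tibble(set_id = character(), set_name = character(),
                  N_T = integer(), N_F = integer(), N_G = integer(),
                  N_C = integer(), p_value = numeric(), fdr = numeric(),
                  significant = logical())
    return(structure(out, class = c("fga_result", class(out)),
                     fdr_threshold = fdr_threshold))
  }
  names_by_id <- dplyr::distinct(sets[, c("set_id", "set_name")])
  rows <- purrr::map(keep_ids, function(id) {
    r <- fga_enrich_set(query_genes, in_univ$gene[in_univ$set_id == id], universe)
    dplyr::bind_cols(tibble(set_id = id,
                            set_name = names_by_id$set_name[match(id, names_by_id$set_id)]),
                     r)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- benjamini_hochberg(out$p_value)
  out$significant <- out$fdr < fdr_threshold
  out <- out[order(out$p_value, out$set_id, method = "radix"), ]
  structure(out, class = c("fga_result", class(out)),
            fdr_threshold = fdr_threshold)
}
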