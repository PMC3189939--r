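# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except through the io round-trip tests.

# Expression tibble from a numeric matrix (rownames = probes, colnames =
# samples); genes default to the probe ids (one probe per gene).
make_expr <- function(m, genes = NULL) {
  if (is.null(genes)) genes <- rownames(m)
  as_expression_tbl(dplyr::bind_cols(
    tibble::tibble(probe_id = rownames(m), gene = genes),
    tibble::as_tibble(m)
  ))
}

make_grouping <- function(g1, g2) {
  tibble::tibble(sample_id = c(g1, g2),
                 group = rep(c(1L, 2L), c(length(g1), length(g2))))
}

# Expression table in which each gene is up-flagged (2.5x-over-median rule)
# in exactly the samples listed for it: baseline 100 everywhere, 1000 at the
# flagged cells. Valid while each gene's flagged set is a minority of the
# cohort, so the per-probe median stays at 100.
make_flagged_expr <- function(samples, flagged_by_gene) {
  stopifnot(all(lengths(flagged_by_gene) < length(samples) / 2))
  m <- matrix(100, nrow = length(flagged_by_gene), ncol = length(samples),
              dimnames = list(names(flagged_by_gene), samples))
  for (g in names(flagged_by_gene)) {
    m[g, flagged_by_gene[[g]]] <- 1000
  }
  make_expr(m)
}

# A 138-sample cohort shaped like the lung study: 63 Group 1 samples.
cohort_samples <- sprintf("t%03d", 1:138)
cohort_grouping <- make_grouping(cohort_samples[1:63], cohort_samples[64:138])

# Flag layout whose per-gene sets are each a cohort minority but union to a
# chosen coverage: `covered` samples split round-robin across `n_genes`.
split_coverage <- function(covered, n_genes) {
  split(covered, rep_len(seq_len(n_genes), length(covered)))
}

# Brute-force hypergeometric upper tail by enumerating all draws with
# utils::combn; exact for small populations, independent of the package's
# log-space path.
enumerate_upper_tail <- function(population, successes, draws, observed) {
  items <- seq_len(population)
  good <- items <= successes
  combos <- utils::combn(items, draws)
  hits <- colSums(matrix(good[combos], nrow = draws))
  mean(hits >= observed)
}

# Hand-coded BH step-up, kept independent of stats::p.adjust.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}
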