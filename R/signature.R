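#' Gene-level standardized expression
#'
#' Collapses probes to genes and standardizes: each gene's probe rows are
#' log2-transformed, averaged, and the resulting gene row is scaled across
#' samples to mean 0 and standard deviation 1 (sample sd, `n - 1` divisor).
#' Genes whose averaged row has zero across-sample variance map to all-zero
#' rows. Unmapped probes are dropped.
#'
#' @param x An expression tibble of linear-scale intensities where the genes
#'   of interest each have at least one probe.
#' @param pseudocount Offset for the log2 transform (default 1).
#' @return A tibble with a `gene` column and one numeric column per sample
#'   holding z-scores.
#' @export
normalize_expression <- function(x, pseudocount = 1) {
  x <- as_expression_tbl(x)
  x <- x[!is.na(x$gene), , drop = FALSE]
  if (nrow(x) == 0) abort("No gene-mapped probes to normalize.")
  lg <- log2_transform(x, pseudocount = pseudocount)
  m <- expr_matrix(lg)
  gene_f <- factor(lg$gene, levels = unique(lg$gene))
  avg <- rowsum(m, group = gene_f) / as.vector(table(gene_f))
  mu <- rowMeans(avg)
  s <- apply(avg, 1, sd)
  z <- (avg - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  dplyr::bind_cols(tibble(gene = rownames(avg)), as_tibble(z))
}

#' Score samples against an up/down signature
#'
#' The per-sample signature score is the sum of standardized gene-level
#' expression ([normalize_expression()]) over the signature's up-genes minus
#' the sum over its down-genes. Signature genes absent from the table are
#' dropped with a warning; if none remain the call errors.
#'
#' @param x An expression tibble of linear-scale intensities.
#' @param signature A data frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`); the two lists must be disjoint.
#' @param pseudocount Offset for the log2 transform (default 1).
#' @return A tibble of class `cafet_scores`: `sample_id`, `score`,
#'   `n_up_used`, `n_down_used`.
#' @export
score_samples <- function(x, signature, pseudocount = 1) {
  x <- as_expression_tbl(x)
  if (!is.data.frame(signature) ||
      !all(c("gene", "direction") %in% names(signature))) {
    abort("`signature` needs `gene` and `direction` columns.")
  }
  if (!all(signature$direction %in% c("up", "down"))) {
    abort("Signature `direction` must be 'up' or 'down'.")
  }
  up <- unique(signature$gene[signature$direction == "up"])
  down <- unique(signature$gene[signature$direction == "down"])
  if (length(intersect(up, down)) > 0) {
    abort("Signature up and down lists must be disjoint.")
  }
  present <- unique(x$gene[!is.na(x$gene)])
  lost <- setdiff(c(up, down), present)
  if (length(lost) > 0) {
    warn(sprintf("Dropping %d signature gene(s) absent from the table: %s",
                 length(lost), paste(head(lost, 5), collapse = ", ")))
  }
  up <- intersect(up, present)
  down <- intersect(down, present)
  if (length(up) + length(down) == 0) {
    abort("No signature gene is present in the expression table.")
  }
  z <- normalize_expression(x, pseudocount = pseudocount)
  zm <- as.matrix(z[expr_sample_ids(x)])
  rownames(zm) <- z$gene
  score <- colSums(zm[up, , drop = FALSE]) - colSums(zm[down, , drop = FALSE])
  out <- tibble(sample_id = colnames(zm), score = as.numeric(score),
                n_up_used = length(up), n_down_used = length(down))
  structure(out, class = c("cafet_scores", class(out)))
}
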