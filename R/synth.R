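#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the parameters of [generate_cohort()]. The defaults
#' describe a mid-sized microarray cohort: 1000 single-probe genes, 100
#' samples split evenly into two groups, log-normal baseline intensities
#' (log2 mean 8, log2 sd 0.5), and a 20-gene pathway planted at 4-fold in
#' the distributed regime.
#'
#' @param n_genes Number of genes.
#' @param probes_per_gene Probes per gene (scalar, or vector of length
#'   `n_genes`).
#' @param n_samples Number of samples.
#' @param group1_fraction Fraction of samples in Group 1 (strictly between
#'   0 and 1).
#' @param baseline_log2_mean,baseline_log2_sd Mean and sd of the per-cell
#'   log2 intensity before any planted effect.
#' @param planted_set_size Number of genes in the planted pathway.
#' @param planted_fold Linear fold applied to planted genes (`> 1` outside
#'   the null regime).
#' @param regime `"distributed"` (each Group 1 sample dysregulates exactly
#'   one planted gene, assigned round-robin), `"concentrated"` (every
#'   planted gene dysregulated in every Group 1 sample) or `"null"` (no
#'   planted effect).
#' @param n_decoy_sets Number of decoy sets of matched size drawn from the
#'   non-planted genes (default 20).
#' @param seed Integer seed; the generated cohort is fully reproducible
#'   from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 1000, probes_per_gene = 1, n_samples = 100,
                         group1_fraction = 0.5, baseline_log2_mean = 8,
                         baseline_log2_sd = 0.5, planted_set_size = 20,
                         planted_fold = 4,
                         regime = c("distributed", "concentrated", "null"),
                         n_decoy_sets = 20, seed = 1) {
  regime <- match.arg(regime)
  cfg <- list(n_genes = as.integer(n_genes),
              probes_per_gene = as.integer(probes_per_gene),
              n_samples = as.integer(n_samples),
              group1_fraction = group1_fraction,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              planted_set_size = as.integer(planted_set_size),
              planted_fold = planted_fold,
              regime = regime,
              n_decoy_sets = as.integer(n_decoy_sets),
              seed = as.integer(seed))
  if (cfg$n_genes < 1 || cfg$n_samples < 2) {
    abort("Need at least 1 gene and 2 samples.")
  }
  if (!length(cfg$probes_per_gene) %in% c(1L, cfg$n_genes) ||
      any(cfg$probes_per_gene < 1)) {
    abort("`probes_per_gene` must be a positive scalar or one value per gene.")
  }
  if (cfg$group1_fraction <= 0 || cfg$group1_fraction >= 1) {
    abort("`group1_fraction` must be strictly between 0 and 1.")
  }
  if (cfg$planted_set_size > cfg$n_genes) {
    abort("`planted_set_size` cannot exceed `n_genes`.")
  }
  if (regime != "null" && cfg$planted_fold <= 1) {
    abort("`planted_fold` must exceed 1 outside the null regime.")
  }
  if (cfg$baseline_log2_sd <= 0) abort("`baseline_log2_sd` must be positive.")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic microarray cohort with a planted pathway
#'
#' Draws positive, right-skewed baseline intensities per probe cell as
#' `2^Normal(baseline_log2_mean, baseline_log2_sd)` (log-normal: positive,
#' right-skewed, well-defined median — the features the fold-over-median
#' flagging rule relies on), then plants pathway dysregulation according to
#' the regime:
#'
#' * `"concentrated"` — every planted-set gene is multiplied by
#'   `planted_fold` in every Group 1 sample (most pathway members altered in
#'   every case sample);
#' * `"distributed"` — Group 1 samples are assigned planted genes
#'   round-robin and each sample has exactly *one* planted gene multiplied
#'   by `planted_fold` (every case sample altered, but through a different
#'   single member);
#' * `"null"` — no modification.
#'
#' The returned collection holds the planted set (`set_planted`) plus
#' `n_decoy_sets` decoy sets of matched size drawn from non-planted genes.
#' Output is bit-reproducible from `config$seed`; the caller's RNG state is
#' untouched.
#'
#' @param config A [synth_config()] object.
#' @return A list with elements `expression` (expression tibble),
#'   `grouping` (grouping tibble), `sets` (gene-set tibble) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must come from synth_config().")
  }
  withr::with_seed(config$seed, {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    ppg <- rep_len(config$probes_per_gene, config$n_genes)
    probe_gene <- rep(genes, ppg)
    probe_id <- unlist(purrr::map2(genes, ppg, function(g, k) {
      if (k == 1) g else sprintf("%s_p%d", g, seq_len(k))
    }), use.names = FALSE)
    samples <- sprintf("s%03d", seq_len(config$n_samples))
    n1 <- max(1L, min(config$n_samples - 1L,
                      round(config$n_samples * config$group1_fraction)))
    g1 <- samples[seq_len(n1)]

    m <- matrix(2^stats::rnorm(length(probe_id) * config$n_samples,
                               mean = config$baseline_log2_mean,
                               sd = config$baseline_log2_sd),
                nrow = length(probe_id),
                dimnames = list(probe_id, samples))

    planted <- sample(genes, config$planted_set_size)
    if (config$regime == "concentrated") {
      rows <- probe_gene %in% planted
      m[rows, g1] <- m[rows, g1] * config$planted_fold
    } else if (config$regime == "distributed") {
      assigned <- rep_len(planted, n1)   # round-robin: one gene per case sample
      for (i in seq_len(n1)) {
        rows <- probe_gene == assigned[i]
        m[rows, g1[i]] <- m[rows, g1[i]] * config$planted_fold
      }
    }

    decoy_pool <- setdiff(genes, planted)
    sets <- list(tibble(set_id = "set_planted", set_name = "planted pathway",
                        gene = planted))
    if (config$n_decoy_sets > 0 &&
        length(decoy_pool) >= config$planted_set_size) {
      for (d in seq_len(config$n_decoy_sets)) {
        sets[[d + 1]] <- tibble(
          set_id = sprintf("set_decoy_%03d", d),
          set_name = sprintf("decoy set %d", d),
          gene = sample(decoy_pool, config$planted_set_size))
      }
    }

    expr <- dplyr::bind_cols(
      tibble(probe_id = probe_id, gene = probe_gene),
      as_tibble(m)
    )
    list(
      expression = as_expression_tbl(expr),
      grouping = as_grouping_tbl(tibble(
        sample_id = samples,
        group = ifelse(samples %in% g1, 1L, 2L))),
      sets = as_geneset_tbl(dplyr::bind_rows(sets)),
      config = config
    )
  })
}
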