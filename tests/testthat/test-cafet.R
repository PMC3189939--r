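test_that("per-gene flagging applies strict fold-over-median rules probe-wise", {
  smp <- sprintf("s%d", 1:5)
  m <- rbind(hit = c(100, 100, 100, 100, 251),
             edge = c(100, 100, 100, 100, 250),
             low = c(100, 100, 100, 100, 49))
  colnames(m) <- smp
  flags <- flag_dysregulated_samples(make_expr(m))
  expect_identical(flags$sample_id[flags$gene == "hit" & flags$direction == "up"], "s5")
  # 250 is not strictly greater than 2.5 x 100
  expect_identical(nrow(flags[flags$gene == "edge", ]), 0L)
  expect_identical(flags$sample_id[flags$gene == "low" & flags$direction == "down"], "s5")

  # any-probe union: probes of one gene flag different samples
  m2 <- rbind(gA_p1 = c(300, 100, 100, 100, 100, 100, 100),
              gA_p2 = c(100, 100, 290, 100, 100, 100, 100))
  colnames(m2) <- sprintf("s%d", 1:7)
  f2 <- flag_dysregulated_samples(make_expr(m2, genes = c("gA", "gA")))
  expect_setequal(f2$sample_id[f2$direction == "up"], c("s1", "s3"))

  expect_error(flag_dysregulated_samples(make_expr(m), genes = "absent"),
               "absent")
})

test_that("zero-baseline probes cannot flag down and always flag up when positive", {
  m <- rbind(z = c(0, 0, 0, 5, 0))
  colnames(m) <- sprintf("s%d", 1:5)
  expect_message(flags <- flag_dysregulated_samples(make_expr(m)), "baseline 0")
  expect_identical(flags$direction, "up")
  expect_identical(flags$sample_id, "s4")
})

test_that("gene-level CAFET counts and p-values follow the sample-axis table", {
  # SOX2-like coverage: 61 of 138 samples flagged, 54 inside the 63-sample group
  flagged <- c(cohort_samples[1:54], cohort_samples[64:70])
  expr <- make_flagged_expr(cohort_samples, list(SOX2 = flagged))
  flags <- flag_dysregulated_samples(expr)
  res <- cafet_gene_test(flags, cohort_grouping)
  up <- res[res$direction == "up", ]
  expect_identical(c(up$S_T, up$S_G, up$S_P, up$S_C), c(138L, 63L, 61L, 54L))
  expect_equal(up$p_value,
               stats::phyper(53, 63, 75, 61, lower.tail = FALSE),
               tolerance = 1e-12)
  # the untouched direction has zero coverage and p = 1
  expect_equal(res$p_value[res$direction == "down"], 1)

  # flags equal to Group 1 exactly: maximal overlap for that coverage
  expr2 <- make_flagged_expr(cohort_samples, list(gX = cohort_samples[1:63]))
  res2 <- cafet_gene_test(flag_dysregulated_samples(expr2), cohort_grouping)
  up2 <- res2[res2$direction == "up", ]
  expect_identical(c(up2$S_P, up2$S_C), c(63L, 63L))
  expect_equal(up2$p_value, 1 / choose(138, 63), tolerance = 1e-9)

  expect_error(cafet_gene_test(flags, make_grouping("a", "b")),
               "different sample universes")
})

test_that("group-level CAFET pools member genes by sample-set union", {
  # seven receptor genes whose flagged sets union to 90 samples, 60 in Group 1
  covered <- c(cohort_samples[1:60], cohort_samples[64:93])
  genes <- split_coverage(covered, 7)
  names(genes) <- c("FZD3", "FZD4", "FZD6", "FZD7", "FZD8", "FZD10", "RYK")
  expr <- make_flagged_expr(cohort_samples, genes)
  flags <- filter_flags(flag_dysregulated_samples(expr), "up")
  res <- cafet_group_test(flags, cohort_grouping)
  expect_identical(c(res$S_T, res$S_G, res$S_FP, res$S_FC), c(138L, 63L, 90L, 60L))
  expect_equal(signif(res$p_value, 3), 8.55e-13)
  expect_identical(res$n_genes_contributing, 7L)
  expect_true(res$eligible)

  # a single-gene group reduces to the gene-level test
  expr1 <- make_flagged_expr(cohort_samples, list(solo = cohort_samples[5:40]))
  flags1 <- filter_flags(flag_dysregulated_samples(expr1), "up")
  grp <- cafet_group_test(flags1, cohort_grouping, min_contributing_genes = 1)
  gene <- cafet_gene_test(flags1, cohort_grouping)
  gene_up <- gene[gene$direction == "up", ]
  expect_equal(grp$p_value, gene_up$p_value)
  expect_identical(c(grp$S_FP, grp$S_FC), c(gene_up$S_P, gene_up$S_C))

  # adding a member whose flags are a subset of the union changes nothing but
  # the contributing-gene count
  genes2 <- c(genes, list(SUBSET = genes[[1]][1:3]))
  expr3 <- make_flagged_expr(cohort_samples, genes2)
  res3 <- cafet_group_test(filter_flags(flag_dysregulated_samples(expr3), "up"),
                           cohort_grouping)
  expect_identical(c(res3$S_FP, res3$S_FC), c(res$S_FP, res$S_FC))
  expect_equal(res3$p_value, res$p_value)
  expect_identical(res3$n_genes_contributing, 8L)

  # mixed-direction flags must be filtered to one direction first
  m_mix <- rbind(u = c(1000, rep(100, 4)), d = c(10, rep(100, 4)))
  colnames(m_mix) <- sprintf("s%d", 1:5)
  mixed <- flag_dysregulated_samples(make_expr(m_mix))
  expect_error(cafet_group_test(mixed, make_grouping("s1", sprintf("s%d", 2:5))),
               "single direction")
})

test_that("union coverage is bounded by member coverages and the cohort", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      n_genes <- sample(2:6, 1)
      genes <- setNames(
        lapply(seq_len(n_genes), function(i) sample(cohort_samples, sample(5:40, 1))),
        sprintf("g%d", seq_len(n_genes)))
      expr <- make_flagged_expr(cohort_samples, genes)
      flags <- filter_flags(flag_dysregulated_samples(expr), "up")
      res <- cafet_group_test(flags, cohort_grouping, min_contributing_genes = 1)
      per_gene <- cafet_gene_test(flags, cohort_grouping)
      s_p <- per_gene$S_P[per_gene$direction == "up"]
      expect_gte(res$S_FP, max(s_p))
      expect_lte(res$S_FP, min(sum(s_p), res$S_T))
    }
  })
})

test_that("gene-level CAFET p equals gene-axis enrichment on the transposed table", {
  # both reduce to the same tail query when samples and genes swap roles
  flagged <- c(cohort_samples[1:30], cohort_samples[64:73])
  expr <- make_flagged_expr(cohort_samples, list(gT = flagged))
  res <- cafet_gene_test(flag_dysregulated_samples(expr), cohort_grouping)
  p_cafet <- res$p_value[res$direction == "up"]
  universe <- sprintf("q%03d", 1:138)
  p_fga <- fga_enrich_set(query_genes = universe[1:40],
                          set_genes = universe[c(1:30, 100:132)],
                          universe = universe)$p_value
  # counts: N_T=138, N_F=63, N_G=40, N_C=30 vs S_T=138, S_G=63, S_P=40, S_C=30
  expect_equal(p_cafet, p_fga, tolerance = 1e-12)
})

test_that("collection-level CAFET shares flags, adjusts eligible sets only", {
  covered <- c(cohort_samples[1:55], cohort_samples[64:80])
  genes <- split_coverage(covered, 6)
  names(genes) <- sprintf("m%d", 1:6)
  # a second, sparse pathway: too few contributing genes to be eligible
  genes$n1 <- cohort_samples[10:20]
  genes$n2 <- cohort_samples[70:80]
  expr <- make_flagged_expr(cohort_samples, genes)
  sets <- tibble::tibble(
    set_id = c(rep("path_big", 6), rep("path_small", 2)),
    gene = c(sprintf("m%d", 1:6), "n1", "n2"))
  res <- cafet_groups(expr, cohort_grouping, sets)
  big <- res[res$set_id == "path_big", ]
  small <- res[res$set_id == "path_small", ]
  expect_true(big$eligible)
  expect_false(small$eligible)
  expect_true(is.na(small$fdr))
  expect_false(small$significant)
  # only one eligible set: its fdr equals its p
  expect_equal(big$fdr, big$p_value)
  expect_identical(c(big$S_FP, big$S_FC), c(72L, 55L))

  # duplicating the collection under new ids doubles m
  sets2 <- dplyr::bind_rows(sets,
                            dplyr::mutate(sets, set_id = paste0(set_id, "_copy")))
  res2 <- cafet_groups(expr, cohort_grouping, sets2)
  big2 <- res2[res2$set_id %in% c("path_big", "path_big_copy"), ]
  expect_equal(big2$p_value[1], big2$p_value[2])
  expect_equal(big2$fdr, pmin(1, big2$p_value * 2 / 2))

  # all-ineligible collections warn and report nothing significant
  expect_warning(
    res3 <- cafet_groups(expr, cohort_grouping,
                         sets[sets$set_id == "path_small", ]),
    "ineligible")
  expect_false(any(res3$significant))
})

test_that("CAFET results are invariant to sample order", {
  cohort <- generate_cohort(synth_config(seed = 9, n_genes = 120, n_samples = 40,
                                         planted_set_size = 8, n_decoy_sets = 4))
  res1 <- cafet_groups(cohort$expression, cohort$grouping, cohort$sets,
                       min_contributing_genes = 3)
  perm <- withr::with_seed(2, sample(expr_sample_ids(cohort$expression)))
  expr_perm <- cohort$expression[c("probe_id", "gene", perm)]
  res2 <- cafet_groups(expr_perm, cohort$grouping[sample(40), ], cohort$sets,
                       min_contributing_genes = 3)
  expect_equal(tidy(res1), tidy(res2))
})

test_that("gene-by-gene CAFET adjusts within direction over the supplied list", {
  covered <- cohort_samples[1:40]
  expr <- make_flagged_expr(cohort_samples,
                            list(a = covered, b = cohort_samples[80:100],
                                 c = cohort_samples[c(1:10, 70:75)]))
  res <- cafet_genes(expr, cohort_grouping, genes = c("a", "b", "c", "a"))
  expect_identical(nrow(res), 6L)   # 3 unique genes x 2 directions
  for (d in c("up", "down")) {
    sub <- res[res$direction == d, ]
    expect_equal(sub$fdr, benjamini_hochberg(sub$p_value))
  }
  # a single-gene list has fdr = p
  res1 <- cafet_genes(expr, cohort_grouping, genes = "a", direction = "up")
  expect_equal(res1$fdr, res1$p_value)
})

test_that("a planted dysregulated gene attains the minimum fdr of its batch", {
  cohort <- generate_cohort(synth_config(seed = 7, n_genes = 100, n_samples = 80,
                                         planted_set_size = 1, planted_fold = 6,
                                         regime = "concentrated", n_decoy_sets = 0))
  planted_gene <- cohort$sets$gene[cohort$sets$set_id == "set_planted"]
  res <- cafet_genes(cohort$expression, cohort$grouping,
                     genes = unique(cohort$expression$gene), direction = "up")
  expect_identical(res$gene[1], planted_gene)
  expect_equal(res$fdr[1], min(res$fdr))
  expect_true(res$fdr[1] < 0.05)
})
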