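test_that("intensity filter keeps exactly probes reaching the threshold", {
  m <- rbind(low = c(50, 99), edge = c(50, 100), high = c(500, 2))
  colnames(m) <- c("s1", "s2")
  expr <- make_expr(m)
  kept <- filter_probes_by_max_intensity(expr, threshold = 100)
  # a probe peaking at 99 is below 100 and removed; peaking at exactly 100 stays
  expect_setequal(kept$probe_id, c("edge", "high"))
  expect_identical(expr_sample_ids(kept), c("s1", "s2"))
  expect_equal(filter_probes_by_max_intensity(expr, threshold = 0), expr)
  expect_identical(nrow(filter_probes_by_max_intensity(expr, threshold = 1e6)), 0L)
})

test_that("log2 transform is explicit, shape-preserving and domain-checked", {
  m <- rbind(p1 = c(0, 3), p2 = c(7, 1))
  colnames(m) <- c("s1", "s2")
  expr <- make_expr(m)
  lg <- log2_transform(expr, pseudocount = 1)
  expect_equal(unname(expr_matrix(lg)), rbind(c(0, 2), c(3, 1)))
  expect_identical(lg$probe_id, expr$probe_id)
  expect_error(log2_transform(expr, pseudocount = 0), "pseudocount 0")
  expect_error(log2_transform(expr, pseudocount = -1), "non-negative")
  neg <- expr
  neg$s1[1] <- -5
  expect_error(log2_transform(neg), "Negative")
})

test_that("Welch differential expression matches per-probe t.test and the closed form", {
  withr::with_seed(11, {
    m <- matrix(2^rnorm(40 * 10, mean = 8, sd = 1), nrow = 40,
                dimnames = list(sprintf("p%02d", 1:40), sprintf("s%02d", 1:10)))
    # plant a strong shift on five probes
    m[1:5, 1:5] <- m[1:5, 1:5] * 32
  })
  expr <- make_expr(m)
  grouping <- make_grouping(colnames(m)[1:5], colnames(m)[6:10])
  de <- differential_expression(expr, grouping)

  lg <- log2(m + 1)
  for (i in c(1, 3, 17, 40)) {
    ref <- stats::t.test(lg[i, 1:5], lg[i, 6:10], var.equal = FALSE)
    expect_equal(de$p_value[de$probe_id == rownames(m)[i]], ref$p.value,
                 tolerance = 1e-12)
    expect_equal(de$t[de$probe_id == rownames(m)[i]], unname(ref$statistic),
                 tolerance = 1e-12)
  }
  expect_equal(de$fdr, benjamini_hochberg(de$p_value))
  expect_true(all(de$fdr >= de$p_value - 1e-15))
  expect_true(all(de$fold_change >= 1))
  expect_setequal(de_genes(de, "group1"), rownames(m)[1:5])

  # hand-computed Welch statistic: log2 groups [8,9,10] vs [1,2,3]
  m2 <- rbind(h = c(2^8 - 1, 2^9 - 1, 2^10 - 1, 2^1 - 1, 2^2 - 1, 2^3 - 1),
              flat = rep(50, 6))
  colnames(m2) <- sprintf("x%d", 1:6)
  de2 <- differential_expression(make_expr(m2),
                                 make_grouping(colnames(m2)[1:3], colnames(m2)[4:6]))
  t_hand <- (9 - 2) / sqrt(1 / 3 + 1 / 3)
  expect_equal(de2$t[de2$probe_id == "h"], t_hand, tolerance = 1e-12)
  # identical-in-both-groups probe: t = 0, p = 1, never DE
  expect_equal(de2$p_value[de2$probe_id == "flat"], 1)
  expect_false(de2$is_de[de2$probe_id == "flat"])
})

test_that("the DE rule gates on both FDR and linear fold change", {
  # 20 probes whose log2 separation is decisive but with varied linear folds
  withr::with_seed(3, {
    base <- matrix(2^rnorm(20 * 12, 8, 0.05), nrow = 20,
                   dimnames = list(sprintf("p%02d", 1:20), sprintf("s%02d", 1:12)))
  })
  base[1:10, 1:6] <- base[1:10, 1:6] * 2.6   # passes the 2.5-fold gate
  base[11:20, 1:6] <- base[11:20, 1:6] * 2.0 # significant but under the gate
  expr <- make_expr(base)
  grouping <- make_grouping(colnames(base)[1:6], colnames(base)[7:12])
  de <- differential_expression(expr, grouping)
  expect_true(all(de$is_de[1:10]))
  expect_false(any(de$is_de[11:20]))
  expect_true(all(de$fdr[11:20] < 0.05))  # blocked by fold, not by FDR

  # extreme thresholds empty or flood the DE set
  expect_identical(sum(differential_expression(expr, grouping,
                                               fold_threshold = Inf)$is_de), 0L)
  loose <- differential_expression(expr, grouping, fold_threshold = 1,
                                   fdr_threshold = 1.0000001)
  expect_true(all(loose$is_de))
})

test_that("differential expression is invariant to sample column order", {
  withr::with_seed(5, {
    m <- matrix(2^rnorm(30 * 8, 8, 0.5), nrow = 30,
                dimnames = list(sprintf("p%02d", 1:30), sprintf("s%d", 1:8)))
  })
  expr <- make_expr(m)
  grouping <- make_grouping(colnames(m)[1:4], colnames(m)[5:8])
  de1 <- differential_expression(expr, grouping)
  perm <- c("probe_id", "gene", sample(colnames(m)))
  de2 <- differential_expression(expr[perm], grouping[sample(8), ])
  expect_equal(tidy(de1), tidy(de2))
})

test_that("differential expression refuses degenerate groupings", {
  m <- matrix(1:9 * 10, nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  expr <- make_expr(m)
  expect_error(
    differential_expression(expr, make_grouping("s1", c("s2", "s3"))),
    "at least 2 samples")
})
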