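test_that("FPKM follows counts * 1e9 / (length * total)", {
  expect_equal(compute_fpkm(matrix(1000), 1000, 1e6)[1, 1], 1000)
  expect_equal(compute_fpkm(matrix(0L), 1000, 1e6)[1, 1], 0)
  expect_equal(compute_fpkm(matrix(250), 2000, 5e6)[1, 1], 25)
  expect_error(compute_fpkm(matrix(1), 0, 1e6), "positive")
  expect_error(compute_fpkm(matrix(1), 1000, 0), "positive")
})

test_that("per-sample FPKM totals weighted by length equal one million", {
  set.seed(11)
  counts <- matrix(rpois(600, 40), 100, 6,
                   dimnames = list(sprintf("g%03d", 1:100), NULL))
  len <- sample(300:5000, 100)
  fpkm <- compute_fpkm(counts, len)
  expect_equal(colSums(fpkm * len / 1000), rep(1e6, 6), tolerance = 1e-9)
})

test_that("expressed-gene filter is strict at the 0.5 FPKM boundary", {
  fpkm <- rbind(
    both_at_threshold = rep(0.5, 4),
    one_group_above = c(0, 0, 0.6, 0.6),
    all_zero = rep(0, 4)
  )
  expr <- make_expr(fpkm)
  out <- expressed_gene_set(expr$fpkm, expr$design)
  expect_false("both_at_threshold" %in% out)
  expect_true("one_group_above" %in% out)
  expect_false("all_zero" %in% out)
})

test_that("signed fold change is a signed ratio of the larger to the smaller mean", {
  expect_equal(signed_fold_change(3, 3), 1)
  expect_equal(signed_fold_change(2, 6, pseudocount = 1e-12), 3,
               tolerance = 1e-9)
  # antisymmetry for unequal means
  set.seed(3)
  a <- runif(50, 0, 20); b <- runif(50, 0, 20)
  expect_equal(signed_fold_change(a, b), -signed_fold_change(b, a))
  expect_error(signed_fold_change(1, 2, pseudocount = 0), "positive")
})

test_that("Benjamini-Hochberg q-values match the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(unname(bh_fdr(c(0.01, 0.02, 0.03))), c(0.03, 0.03, 0.03))
  expect_equal(unname(bh_fdr(rep(0.2, 5))), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # q >= p always
  set.seed(4)
  p <- runif(100)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("the exact test returns p = 1 when both groups are identical replicates", {
  col <- rpois(50, 30)
  counts <- matrix(rep(col, 8), 50, 8,
                   dimnames = list(sprintf("g%03d", 1:50), NULL))
  p <- de_test(counts, rep(c("A", "B"), each = 4), mid_p = FALSE)
  expect_true(all(p == 1))
  # mid-p shaves off at most half the point mass at the mode
  pm <- de_test(counts, rep(c("A", "B"), each = 4))
  expect_true(all(pm > 0.5 & pm <= 1))
})

test_that("the exact test detects a planted 8-fold change at 6 vs 6", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    mu <- c(rep(200, 49), 200)
    counts <- cbind(
      matrix(rnbinom(50 * 6, mu = mu, size = 10), 50, 6),
      matrix(rnbinom(50 * 6, mu = c(mu[-50], mu[50] * 8), size = 10), 50, 6)
    )
    rownames(counts) <- sprintf("g%03d", 1:50)
    p <- de_test(counts, rep(c("A", "B"), each = 6))
    p["g050"] < 0.01
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("the three DE filters are strict/inclusive exactly as specified", {
  # group means dictated directly via the fpkm matrix (two samples per group
  # at the group mean); pseudocount 0.25 makes the FC values exact
  fpkm <- rbind(
    low_expr = c(0.4, 0.4, 0.3, 0.3),       # FC passes, expression does not
    fc_below = c(1.00, 1.00, 1.15, 1.15),    # |FC| = 1.4
    fc_at = c(0.75, 0.75, 1.25, 1.25),       # |FC| = 1.5 exactly
    p_above = c(2, 2, 8, 8),                 # p = 0.011
    p_at = c(2, 2, 8, 8),                    # p = 0.01 exactly
    clean = c(2, 2, 20, 20)
  )
  expr <- make_expr(fpkm)
  p <- c(low_expr = 0.001, fc_below = 0.001, fc_at = 0.001,
         p_above = 0.011, p_at = 0.01, clean = 0.001)
  de <- filter_de(expr, p)
  expect_setequal(de$gene, c("fc_at", "p_at", "clean"))
  expect_equal(attr(de, "n_de"), 3)
  expect_true(all(de$q >= de$p))
  expect_true(all(sign(de$fc) == sign(de$d)))
})

test_that("tightening any DE threshold never adds genes", {
  set.seed(21)
  sim <- generate_expression_dataset(
    sim_config(n_genes = 300, n_trf = 20, n_de_true = 40, seed = 9))
  p <- de_test(sim$expr$counts, sim$expr$design)
  base <- filter_de(sim$expr, p)$gene
  for (args in list(list(min_fpkm = 1), list(min_abs_fc = 2),
                    list(max_p = 0.001))) {
    tighter <- do.call(filter_de, c(list(sim$expr, p), args))$gene
    expect_true(all(tighter %in% base))
  }
})

test_that("null p-values are close to uniform", {
  set.seed(31)
  mu <- rlnorm(3000, log(200), 1.2)
  counts <- matrix(rnbinom(3000 * 12, mu = rep(mu, 12), size = 10), 3000, 12)
  rownames(counts) <- sprintf("g%05d", 1:3000)
  p <- de_test(counts, rep(c("A", "B"), each = 6))
  # no gross departure from uniformity in either direction
  expect_gt(stats::ks.test(p, "punif")$p.value, 1e-4)
  expect_lt(abs(mean(p <= 0.1) - 0.1), 0.02)
})
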