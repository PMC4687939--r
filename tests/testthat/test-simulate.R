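test_that("configuration invariants are enforced", {
  expect_error(sim_config(fc_range = c(1, 3)), "lower bound > 1")
  expect_error(sim_config(n_trf = 10, n_planted_regulators = 11),
               "n_planted_regulators")
  expect_error(sim_config(n_genes = 100, n_trf = 20, n_de_true = 90),
               "n_genes - n_trf")
  expect_error(sim_config(n_genes = 0), "n_genes")
})

test_that("equal seeds give identical synthetic data, different seeds differ", {
  cfg <- sim_config(n_genes = 200, n_trf = 20, n_de_true = 30, seed = 5)
  s1 <- generate_expression_dataset(cfg)
  s2 <- generate_expression_dataset(cfg)
  expect_identical(s1$expr$counts, s2$expr$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_expression_dataset(
    sim_config(n_genes = 200, n_trf = 20, n_de_true = 30, seed = 6))
  expect_false(identical(s1$expr$counts, s3$expr$counts))

  q1 <- generate_qpcr_dataset(seed = 4)
  q2 <- generate_qpcr_dataset(seed = 4)
  expect_identical(q1$data, q2$data)

  v1 <- generate_variant_dataset(n_loci = 300, seed = 8)
  v2 <- generate_variant_dataset(n_loci = 300, seed = 8)
  expect_identical(v1, v2)

  f1 <- generate_fatty_acid_profiles(4, reference_fatty_acids(), sd = 1, seed = 2)
  f2 <- generate_fatty_acid_profiles(4, reference_fatty_acids(), sd = 1, seed = 2)
  expect_identical(f1, f2)
})

test_that("ground truth bookkeeping matches the configuration", {
  sim <- generate_expression_dataset(
    sim_config(n_genes = 1000, n_trf = 50, n_planted_regulators = 3,
               n_de_true = 100, seed = 7))
  tr <- sim$truth
  expect_length(tr$de_gene_ids, 100)
  expect_length(tr$planted_regulator_ids, 3)
  expect_length(tr$true_fc, 100)
  expect_true(all(abs(tr$true_fc) >= 1.9))
  expect_true(all(unlist(tr$regulator_targets) %in% tr$de_gene_ids))
  # planted targets are never candidate regulators
  expect_false(any(tr$de_gene_ids %in% names(which(sim$expr$is_trf))))
  # planted fold changes land on the group means
  gm <- t(apply(sim$expr$counts, 1, function(x)
    tapply(x, sim$expr$design, mean)))
  lens <- sim$expr$gene_length_bp
  expect_true(all(lens >= 300 & lens <= 10000))
})

test_that("a null configuration yields a false-positive rate at the nominal level", {
  sim <- generate_expression_dataset(
    sim_config(n_genes = 2000, n_trf = 50, n_planted_regulators = 0,
               n_de_true = 0, seed = 13))
  p <- de_test(sim$expr$counts, sim$expr$design)
  alpha <- 0.05
  half <- 2.576 * sqrt(alpha * (1 - alpha) / length(p))
  expect_lt(abs(mean(p <= alpha) - alpha), half + 0.002)
})

test_that("qPCR generator inverts to the planted contrasts", {
  qd <- generate_qpcr_dataset(n_targets = 2, n_reference = 1,
                              animals_per_group = 6, replicates = 3,
                              true_diff = c(target01 = -2, target02 = 1),
                              sigma_pig = 0, sigma_sample = 0,
                              sigma_resid = 1e-9, seed = 3)
  expect_equal(nrow(qd$data), 3 * 12 * 3)  # genes x animals x replicates
  res <- estimate_diff_tg(fit_qpcr_model(qd))
  expect_equal(res$diff_tg[res$gene == "target01"], -2, tolerance = 1e-6)
  expect_equal(res$diff_tg[res$gene == "target02"], 1, tolerance = 1e-6)
  expect_equal(unname(qd$true_diff["ref01"]), 0)
})

test_that("variant generator honours sharing and fixation settings", {
  vd <- generate_variant_dataset(n_loci = 400, p_shared = 1, seed = 2)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  expect_setequal(key(vd$A), key(vd$B))

  vd2 <- generate_variant_dataset(n_loci = 500, p_fixed_groupA = 1, seed = 3)
  fa <- filter_variants(vd2$A, min_coverage = 30)
  expect_true(all(classify_frequency(fa$af) == "fixed"))

  vd3 <- generate_variant_dataset(n_loci = 10000, p_fixed_groupA = 0.4, seed = 4)
  fa3 <- filter_variants(vd3$A)
  phat <- mean(classify_frequency(fa3$af) == "fixed")
  half <- 2.576 * sqrt(0.4 * 0.6 / nrow(fa3))
  expect_lt(abs(phat - 0.4), half + 0.005)
})

test_that("fatty-acid profiles renormalize to 100 and honour sd = 0", {
  gm <- reference_fatty_acids()
  prof <- generate_fatty_acid_profiles(3, gm, sd = 0, seed = 1)
  fa_cols <- setdiff(names(prof), c("animal", "group"))
  expect_equal(unname(rowSums(prof[, fa_cols])), rep(100, 6),
               tolerance = 1e-9)
  # sd = 0: every animal equals its renormalized group mean
  ib <- prof[prof$group == "IB", fa_cols]
  expect_equal(as.numeric(ib[1, ]), as.numeric(ib[2, ]))
  expect_equal(as.numeric(ib[1, ]),
               unname(100 * gm$IB / sum(gm$IB)), tolerance = 1e-9)
  expect_error(generate_fatty_acid_profiles(3, -gm), "non-negative")
})
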