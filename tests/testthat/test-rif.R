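test_that("within-group correlations reproduce hand-computed Pearson values", {
  # log2(fpkm + 0.25) is forced to the target vectors exactly
  logmat <- rbind(
    trf = c(1, 2, 3, 4, 5, 5, 5, 5),     # constant in group B
    up = c(2, 4, 6, 8, 1, 2, 1, 2),
    down = c(4, 3, 2, 1, 2, 1, 2, 1)
  )
  expr <- make_expr(fpkm_from_log2(logmat))
  co <- coexpression_correlations(expr, "trf", c("up", "down"))
  expect_equal(co$r1["trf", "up"], 1)
  expect_equal(co$r1["trf", "down"], -1)
  expect_equal(unname(co$r2["trf", ]), c(0, 0))  # zero-variance sentinel
  expect_error(
    coexpression_correlations(make_expr(matrix(1:8, 2, 4)), "g001", "g002"),
    "3 samples")
})

test_that("RIF formulas match direct evaluation on the worked example", {
  de <- data.frame(gene = c("j1", "j2"), e1 = c(1, 1), e2 = c(1, 1),
                   a = c(2, 1), d = c(1, -1), stringsAsFactors = FALSE)
  co <- list(r1 = matrix(c(0.9, 0.5), 1, dimnames = list("i", de$gene)),
             r2 = matrix(c(0.1, 0.5), 1, dimnames = list("i", de$gene)))
  out <- compute_rif(de, co)
  expect_equal(out$rif1_raw, 0.64)

  # r1 = r2 kills RIF1; equal weighted magnitudes kill RIF2
  co_eq <- list(r1 = co$r1, r2 = co$r1)
  expect_equal(compute_rif(de, co_eq)$rif1_raw, 0)
  de2 <- de; de2$e1 <- c(2, 3); de2$e2 <- c(2, 3)
  co_sym <- list(r1 = co$r1, r2 = -co$r1)
  expect_equal(compute_rif(de2, co_sym)$rif2_raw, 0)
  expect_error(compute_rif(de[0, ], co), "empty")
})

test_that("vectorized RIF agrees with a naive double loop on random instances", {
  set.seed(77)
  for (rep in 1:50) {
    n_trf <- 10; n_de <- 20
    de <- data.frame(gene = sprintf("j%02d", 1:n_de),
                     e1 = rnorm(n_de, 3, 1), e2 = rnorm(n_de, 3, 1))
    de$a <- (de$e1 + de$e2) / 2
    de$d <- de$e2 - de$e1
    r1 <- matrix(runif(n_trf * n_de, -1, 1), n_trf,
                 dimnames = list(sprintf("i%02d", 1:n_trf), de$gene))
    r2 <- matrix(runif(n_trf * n_de, -1, 1), n_trf,
                 dimnames = dimnames(r1))
    out <- compute_rif(de, list(r1 = r1, r2 = r2))
    # independent oracle: literal double-loop over the printed sums
    for (i in seq_len(n_trf)) {
      rif1 <- 0; rif2 <- 0
      for (j in seq_len(n_de)) {
        rif1 <- rif1 + de$a[j] * de$d[j] * (r1[i, j] - r2[i, j])^2
        rif2 <- rif2 + (de$e1[j] * r1[i, j])^2 - (de$e2[j] * r2[i, j])^2
      }
      expect_equal(out$rif1_raw[i], rif1 / n_de, tolerance = 1e-12)
      expect_equal(out$rif2_raw[i], rif2 / n_de, tolerance = 1e-12)
    }
  }
})

test_that("z-standardization uses the sample SD and flags degenerate input", {
  z <- standardize(c(1, 3))
  expect_equal(unname(z), c(-1, 1) / sqrt(2))
  zc <- standardize(rep(2, 5))
  expect_equal(as.numeric(zc), rep(0, 5))
  expect_true(attr(zc, "degenerate"))
  set.seed(8)
  z2 <- standardize(rnorm(40))
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 1, tolerance = 1e-12)
  expect_error(standardize(1), "at least 2")
})

test_that("rescaling the DE weights rescales RIF1 but not the z ranking", {
  set.seed(12)
  de <- data.frame(gene = sprintf("j%02d", 1:15),
                   e1 = rnorm(15, 3), e2 = rnorm(15, 3))
  de$a <- (de$e1 + de$e2) / 2; de$d <- de$e2 - de$e1
  r1 <- matrix(runif(8 * 15, -1, 1), 8, dimnames = list(NULL, de$gene))
  r2 <- matrix(runif(8 * 15, -1, 1), 8, dimnames = list(NULL, de$gene))
  base <- compute_rif(de, list(r1 = r1, r2 = r2))
  de_scaled <- de
  de_scaled$a <- de$a * 3  # multiplies every a_j * d_j by 3
  scaled <- compute_rif(de_scaled, list(r1 = r1, r2 = r2))
  expect_equal(scaled$rif1_raw, 3 * base$rif1_raw, tolerance = 1e-12)
  expect_equal(order(standardize(scaled$rif1_raw)),
               order(standardize(base$rif1_raw)))
})

test_that("the bootstrap null interval nests levels and covers ~95%", {
  sim <- generate_expression_dataset(
    sim_config(n_genes = 400, n_trf = 30, n_planted_regulators = 0,
               n_de_true = 0, seed = 19))
  expressed <- expressed_gene_set(sim$expr$fpkm, sim$expr$design)
  trfs <- intersect(names(which(sim$expr$is_trf)), expressed)
  ci <- bootstrap_null_ci(sim$expr, expressed, trfs, n_de_drawn = 30,
                          reps = 200, seed = 5, keep_null = TRUE)
  b95 <- ci$ci[ci$ci$metric == "RIF1" & ci$ci$level == 95, ]
  b99 <- ci$ci[ci$ci$metric == "RIF1" & ci$ci$level == 99, ]
  expect_lt(b99$lower, b95$lower)
  expect_gt(b99$upper, b95$upper)
  inside <- mean(ci$null_z1 >= b95$lower & ci$null_z1 <= b95$upper)
  expect_equal(inside, 0.95, tolerance = 0.01)
  expect_error(
    bootstrap_null_ci(sim$expr, expressed, trfs, n_de_drawn = 1e6, reps = 10),
    "exceeds")
  expect_warning(
    bootstrap_null_ci(sim$expr, expressed, trfs, n_de_drawn = 10, reps = 50),
    "100")
  # the documented default number of repetitions
  expect_equal(formals(bootstrap_null_ci)$reps, 10000)
})

test_that("significance calls against published-style bootstrap bounds", {
  ci <- structure(list(ci = data.frame(
    metric = rep(c("RIF1", "RIF2"), 2),
    level = rep(c(95, 99), each = 2),
    lower = c(-1.996, -2.036, -2.883, -2.609),
    upper = c(2.074, 1.953, 2.918, 2.490)
  )), class = "rif_ci")
  rif <- data.frame(trf = c("extreme1", "null", "mild2"),
                    z1 = c(3.59, 0, 0),
                    z2 = c(0, 0, -2.41), stringsAsFactors = FALSE)
  res <- classify_trf(rif, ci)
  expect_true(res$sig95_1[1] && res$sig99_1[1])
  expect_false(any(res$sig95_1[2], res$sig99_1[2],
                   res$sig95_2[2], res$sig99_2[2]))
  expect_true(res$sig95_2[3])
  expect_false(res$sig99_2[3])
})
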