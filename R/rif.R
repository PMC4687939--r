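# Regulatory Impact Factors. For candidate regulator i and DE gene j, with
# within-group Pearson correlations r1_ij / r2_ij of log2 expression and the
# DE genes' average abundance a_j, differential expression d_j and group
# means e1_j / e2_j (all on the log2 FPKM scale):
#
#   RIF1_i = (1/n_de) * sum_j a_j * d_j * (r1_ij - r2_ij)^2
#   RIF2_i = (1/n_de) * sum_j [ (e1_j * r1_ij)^2 - (e2_j * r2_ij)^2 ]
#
# Both are reported as z-scores over the candidate set, judged against a
# bootstrap null that redraws random gene sets in place of the DE set.

#' Within-group co-expression correlations
#'
#' Pearson (or Spearman) correlation of log2(FPKM + offset) between every
#' candidate regulator and every DE gene, computed separately within each
#' group. Pairs involving a constant expression vector get the sentinel 0.
#'
#' @param expr An [expression_dataset()].
#' @param trf_ids Candidate regulator gene ids.
#' @param de_ids DE gene ids.
#' @param offset Offset inside the log2 transform; default 0.25.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List of class `coexpression_profile` with matrices `r1`, `r2`
#'   (regulators x DE genes) and `n_samples_per_group`.
#' @export
coexpression_correlations <- function(expr, trf_ids, de_ids, offset = 0.25,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  fpkm <- expr$fpkm
  if (!all(c(trf_ids, de_ids) %in% rownames(fpkm))) {
    stop("all regulator and DE gene ids must be present in the dataset")
  }
  design <- expr$design
  if (any(table(design) < 3L)) stop("at least 3 samples per group are required")
  logx <- log2(fpkm + offset)
  one_group <- function(g) {
    x <- t(logx[trf_ids, design == g, drop = FALSE])
    y <- t(logx[de_ids, design == g, drop = FALSE])
    r <- suppressWarnings(cor(x, y, method = method))
    r[!is.finite(r)] <- 0  # zero-variance sentinel
    r
  }
  structure(list(
    r1 = one_group(levels(design)[1]),
    r2 = one_group(levels(design)[2]),
    n_samples_per_group = table(design)
  ), class = "coexpression_profile")
}

#' Raw RIF1 and RIF2 scores
#'
#' Evaluates the two regulatory-impact sums over the DE set for every
#' candidate regulator. RIF1 weights squared differential co-expression by
#' the DE genes' abundance times differential expression; RIF2 contrasts the
#' squared expression-weighted correlations between the two groups.
#'
#' @param de A [filter_de()] result (or data frame with `gene, e1, e2, a, d`).
#' @param co A [coexpression_correlations()] profile whose columns match
#'   `de$gene`.
#' @return Data frame `trf, rif1_raw, rif2_raw`.
#' @export
compute_rif <- function(de, co) {
  n_de <- nrow(de)
  if (n_de == 0) stop("the DE set is empty")
  if (!identical(colnames(co$r1), de$gene) &&
      !is.null(colnames(co$r1))) {
    co$r1 <- co$r1[, de$gene, drop = FALSE]
    co$r2 <- co$r2[, de$gene, drop = FALSE]
  }
  if (ncol(co$r1) != n_de) stop("correlation columns must match the DE set")
  w1 <- de$a * de$d
  rif1 <- as.vector((co$r1 - co$r2)^2 %*% w1) / n_de
  rif2 <- as.vector(sweep(co$r1^2, 2, de$e1^2, `*`) %*% rep(1, n_de) -
                    sweep(co$r2^2, 2, de$e2^2, `*`) %*% rep(1, n_de)) / n_de
  data.frame(trf = rownames(co$r1) %||% seq_len(nrow(co$r1)),
             rif1_raw = rif1, rif2_raw = rif2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' z-standardization over the candidate set
#'
#' Subtracts the mean and divides by the sample (n-1) standard deviation.
#' When all raw values coincide the z-scores are defined as 0 and flagged
#' with attribute `degenerate = TRUE`.
#'
#' @param raw Numeric vector (>= 2 values).
#' @return z-scores with the names of `raw`.
#' @export
standardize <- function(raw) {
  if (length(raw) < 2) stop("at least 2 values are required")
  s <- sd(raw)
  if (!is.finite(s) || s == 0) {
    z <- setNames(rep(0, length(raw)), names(raw))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  (raw - mean(raw)) / s
}

#' Bootstrap null distribution and confidence intervals for RIF z-scores
#'
#' In each repetition, `n_de_drawn` genes are drawn uniformly without
#' replacement from the expressed non-regulator genes and treated as the DE
#' set (their actual per-gene `a`, `d`, `e1`, `e2` are used); RIF1/RIF2
#' z-scores of all candidate regulators are computed and pooled across
#' regulators and repetitions. The interval bounds are percentiles of the
#' pooled distribution (2.5/97.5 for the 95% level, 0.5/99.5 for 99%).
#'
#' @param expr An [expression_dataset()].
#' @param expressed_ids Expressed gene ids forming the sampling pool
#'   (regulators are excluded internally).
#' @param trf_ids Candidate regulator ids.
#' @param n_de_drawn Genes drawn per repetition.
#' @param reps Repetitions; default 10000. Fewer than 100 triggers a warning.
#' @param levels Confidence levels in percent; default `c(95, 99)`.
#' @param seed Integer seed for the draw sequence.
#' @param offset log2 offset, as in [coexpression_correlations()].
#' @param keep_null Keep the pooled null z-scores in the result; default
#'   `FALSE`.
#' @return Object of class `rif_ci`: list with `ci` (data frame
#'   `metric, level, lower, upper`), `reps`, `n_de_drawn`, `seed`, and
#'   optionally `null_z1`, `null_z2`.
#' @export
bootstrap_null_ci <- function(expr, expressed_ids, trf_ids, n_de_drawn,
                              reps = 10000, levels = c(95, 99), seed = 1,
                              offset = 0.25, keep_null = FALSE) {
  pool <- setdiff(expressed_ids, trf_ids)
  if (n_de_drawn > length(pool)) {
    stop("n_de_drawn exceeds the expressed non-regulator pool")
  }
  if (reps < 100) warning("fewer than 100 bootstrap repetitions")
  design <- expr$design
  logx <- log2(expr$fpkm + offset)
  lg <- group_means(logx, design)

  # correlations of every regulator against the whole pool, once per group;
  # each repetition then just subsets columns
  co <- coexpression_correlations(expr, trf_ids, pool, offset = offset)
  e1 <- lg[pool, 1]; e2 <- lg[pool, 2]
  a <- (e1 + e2) / 2; d <- e2 - e1

  set.seed(derive_seed(seed, 606L))
  n_trf <- length(trf_ids)
  z1 <- matrix(NA_real_, n_trf, reps)
  z2 <- matrix(NA_real_, n_trf, reps)
  dr2 <- (co$r1 - co$r2)^2
  s1 <- sweep(co$r1^2, 2, e1^2, `*`)
  s2 <- sweep(co$r2^2, 2, e2^2, `*`)
  for (b in seq_len(reps)) {
    j <- sample.int(length(pool), n_de_drawn)
    rif1 <- dr2[, j, drop = FALSE] %*% (a[j] * d[j]) / n_de_drawn
    rif2 <- (rowSums(s1[, j, drop = FALSE]) -
             rowSums(s2[, j, drop = FALSE])) / n_de_drawn
    z1[, b] <- standardize(as.vector(rif1))
    z2[, b] <- standardize(rif2)
  }
  ci <- do.call(rbind, lapply(sort(levels), function(lv) {
    al <- (100 - lv) / 200
    q1 <- quantile(z1, c(al, 1 - al), names = FALSE)
    q2 <- quantile(z2, c(al, 1 - al), names = FALSE)
    data.frame(metric = c("RIF1", "RIF2"), level = lv,
               lower = c(q1[1], q2[1]), upper = c(q1[2], q2[2]))
  }))
  out <- list(ci = ci, reps = reps, n_de_drawn = n_de_drawn, seed = seed)
  if (keep_null) {
    out$null_z1 <- as.vector(z1)
    out$null_z2 <- as.vector(z2)
  }
  structure(out, class = "rif_ci")
}

#' @export
print.rif_ci <- function(x, ...) {
  cat(sprintf("Bootstrap null for RIF z-scores (%d reps, %d genes per draw)\n",
              x$reps, x$n_de_drawn))
  print(x$ci, row.names = FALSE)
  invisible(x)
}

#' Flag regulators with extreme RIF z-scores
#'
#' A regulator is significant at a level when its z-score lies strictly
#' outside the corresponding interval.
#'
#' @param rif Data frame with `trf, rif1_raw, rif2_raw` (from
#'   [compute_rif()]); alternatively precomputed `z1`/`z2` columns are used
#'   as-is.
#' @param ci A [bootstrap_null_ci()] result (or any object whose `ci`
#'   element tabulates `metric, level, lower, upper`).
#' @return Object of class `rif_result`: data frame with raw scores,
#'   z-scores and logical columns `sig95_1, sig99_1, sig95_2, sig99_2`.
#' @export
classify_trf <- function(rif, ci) {
  bounds <- ci$ci
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper))) {
    stop("confidence bounds must be finite")
  }
  z1 <- rif$z1 %||% standardize(rif$rif1_raw)
  z2 <- rif$z2 %||% standardize(rif$rif2_raw)
  if (is.null(rif$rif1_raw)) rif$rif1_raw <- NA_real_
  if (is.null(rif$rif2_raw)) rif$rif2_raw <- NA_real_
  get <- function(metric, level) {
    b <- bounds[bounds$metric == metric & bounds$level == level, ]
    c(b$lower, b$upper)
  }
  outside <- function(z, b) z < b[1] | z > b[2]
  res <- data.frame(
    trf = rif$trf, rif1_raw = rif$rif1_raw, rif2_raw = rif$rif2_raw,
    z1 = as.vector(z1), z2 = as.vector(z2),
    sig95_1 = outside(z1, get("RIF1", 95)),
    sig99_1 = outside(z1, get("RIF1", 99)),
    sig95_2 = outside(z2, get("RIF2", 95)),
    sig99_2 = outside(z2, get("RIF2", 99)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(res, class = c("rif_result", "data.frame"), ci = ci)
}

#' Regulatory-impact analysis of a DE set
#'
#' Convenience wrapper running [coexpression_correlations()], [compute_rif()],
#' [bootstrap_null_ci()] and [classify_trf()] in sequence.
#'
#' @param expr An [expression_dataset()].
#' @param de A [filter_de()] result.
#' @param trf_ids Candidate regulator ids (defaults to the dataset's TRF
#'   flags); only regulators expressed above `expressed_threshold` are kept.
#' @param expressed_threshold FPKM threshold for the expressed set; default
#'   0.5.
#' @param reps Bootstrap repetitions; default 10000.
#' @param seed Integer seed.
#' @param offset log2 offset.
#' @return A [classify_trf()] result (class `rif_result`).
#' @export
rif_analysis <- function(expr, de, trf_ids = NULL, expressed_threshold = 0.5,
                         reps = 10000, seed = 1, offset = 0.25) {
  expressed <- expressed_gene_set(expr$fpkm, expr$design, expressed_threshold)
  if (is.null(trf_ids)) trf_ids <- names(which(expr$is_trf))
  trf_ids <- intersect(trf_ids, expressed)
  if (length(trf_ids) < 2) stop("fewer than 2 expressed candidate regulators")
  co <- coexpression_correlations(expr, trf_ids, de$gene, offset = offset)
  rif <- compute_rif(de, co)
  ci <- bootstrap_null_ci(expr, expressed, trf_ids, n_de_drawn = nrow(de),
                          reps = reps, seed = seed, offset = offset)
  classify_trf(rif, ci)
}

#' @export
print.rif_result <- function(x, ...) {
  cat(sprintf("RIF analysis of %d candidate regulators\n", nrow(x)))
  sig <- x[x$sig95_1 | x$sig95_2, ]
  cat(sprintf("  outside the 95%% bootstrap interval: %d (RIF1: %d, RIF2: %d)\n",
              nrow(sig), sum(x$sig95_1), sum(x$sig95_2)))
  if (nrow(sig)) print(utils::head(as.data.frame(sig), 15), row.names = FALSE)
  invisible(x)
}
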