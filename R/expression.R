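# Expression-level computations: FPKM, expressed-gene filter, signed fold
# change, the in-repo negative-binomial exact DE test, BH correction and the
# three-criterion DE filter.

#' Fragments per kilobase per million mapped reads
#'
#' Length- and depth-normalizes a count matrix:
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length_bp[g] * total_mapped[s])`.
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns. Row and column names are carried over.
#' @param gene_length_bp Positive gene lengths in base pairs, one per row of
#'   `counts` (named vectors are matched by name).
#' @param total_mapped Per-sample totals of mapped fragments; defaults to the
#'   column sums of `counts`.
#' @return Numeric matrix of FPKM values with the dimensions of `counts`.
#' @examples
#' compute_fpkm(matrix(1000), gene_length_bp = 1000, total_mapped = 1e6)
#' @export
compute_fpkm <- function(counts, gene_length_bp, total_mapped = colSums(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_length_bp)) && !is.null(rownames(counts))) {
    gene_length_bp <- gene_length_bp[rownames(counts)]
  }
  if (length(gene_length_bp) != nrow(counts)) {
    stop("need one gene length per row of 'counts'")
  }
  if (any(gene_length_bp <= 0)) stop("gene lengths must be positive")
  if (!is.null(names(total_mapped)) && !is.null(colnames(counts))) {
    total_mapped <- total_mapped[colnames(counts)]
  }
  if (length(total_mapped) != ncol(counts)) {
    stop("need one mapped-fragment total per sample")
  }
  if (any(total_mapped <= 0)) stop("total mapped fragments must be positive")
  counts * 1e9 / outer(as.numeric(gene_length_bp), as.numeric(total_mapped))
}

# per-group means of a gene x sample matrix; design is a sample -> group
# factor/character aligned with the columns
group_means <- function(mat, design) {
  design <- check_design(design, colnames(mat), ncol(mat))
  groups <- levels(design)
  out <- vapply(groups, function(g) rowMeans(mat[, design == g, drop = FALSE]),
                numeric(nrow(mat)))
  colnames(out) <- groups
  out
}

check_design <- function(design, sample_ids = NULL, n = NULL) {
  if (!is.factor(design)) {
    des_names <- names(design)
    design <- factor(design)
    names(design) <- des_names
  }
  if (!is.null(sample_ids) && !is.null(names(design))) {
    if (!all(sample_ids %in% names(design))) {
      stop("every sample must have a group label")
    }
    design <- design[sample_ids]
  }
  if (!is.null(n) && length(design) != n) {
    stop("design length does not match the number of samples")
  }
  if (nlevels(droplevels(design)) != 2L) {
    stop("exactly two groups are required")
  }
  droplevels(design)
}

#' Expressed-gene filter
#'
#' A gene is called expressed when its mean FPKM strictly exceeds `threshold`
#' in at least one of the two groups (a gene with both group means exactly at
#' the threshold is excluded).
#'
#' @param fpkm FPKM matrix, genes in rows.
#' @param design Sample-to-group assignment (two groups).
#' @param threshold Expression cutoff in FPKM units; default 0.5.
#' @return Character vector of expressed gene ids (row names), or row indices
#'   when `fpkm` has no row names.
#' @export
expressed_gene_set <- function(fpkm, design, threshold = 0.5) {
  gm <- group_means(as.matrix(fpkm), design)
  keep <- gm[, 1] > threshold | gm[, 2] > threshold
  ids <- rownames(fpkm) %||% seq_len(nrow(fpkm))
  ids[keep]
}

#' Signed fold change between two group means
#'
#' Ratio of the larger mean to the smaller, signed by direction: positive when
#' group B (the second group, conventionally the crossbred IBxDU) is higher,
#' negative when group A (purebred IB) is higher. A small pseudocount guards
#' zero means.
#'
#' @param mean_a,mean_b Non-negative group means (vectorized).
#' @param pseudocount Positive offset added to both means; default 0.25.
#' @return Signed fold change, `|fc| >= 1`.
#' @export
signed_fold_change <- function(mean_a, mean_b, pseudocount = 0.25) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  ma <- mean_a + pseudocount
  mb <- mean_b + pseudocount
  ifelse(mb >= ma, mb / ma, -(ma / mb))
}

#' Two-group negative-binomial exact test
#'
#' A documented substitute for an external count-based DE engine: per-gene
#' two-sided exact test on library-size-normalized counts under a
#' negative-binomial model, with common + tagwise dispersion estimated by the
#' method of moments. The test conditions on the gene's total pseudo-count and
#' evaluates the conditional probability of the observed group split; the
#' two-sided p-value sums all splits at most as probable as the observed one.
#' With `mid_p = TRUE` (default) half the probability of the outcomes exactly
#' as probable as the observed one is subtracted, which calibrates the
#' otherwise conservative discrete test close to its nominal size.
#'
#' @param counts Integer count matrix, genes in rows.
#' @param design Sample-to-group assignment (two groups, each with >= 2
#'   samples).
#' @param dispersion Optional fixed NB dispersion; when `NULL` it is estimated.
#' @param prior_df Prior degrees of freedom shrinking tagwise dispersions
#'   toward the common value; default 50 (the per-gene moment estimate has
#'   only about 10 residual df at 6 + 6 samples, so strong shrinkage is
#'   needed for a calibrated plug-in test).
#' @param mid_p Apply the mid-p correction; default `TRUE`.
#' @return Named vector of p-values in `[0, 1]`.
#' @export
de_test <- function(counts, design, dispersion = NULL, prior_df = 50,
                    mid_p = TRUE) {
  counts <- as.matrix(counts)
  design <- check_design(design, colnames(counts), ncol(counts))
  if (any(table(design) < 2L)) stop("each group needs at least 2 samples")
  g1 <- design == levels(design)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)

  # equalize library sizes: scale each column to the mean depth
  lib <- colSums(counts)
  if (any(lib == 0)) stop("a sample has zero total counts")
  pseudo <- round(sweep(counts, 2, mean(lib) / lib, `*`))

  mu_hat <- rowMeans(pseudo)
  if (is.null(dispersion)) {
    disp <- moment_dispersion(pseudo, g1, g2, prior_df)
  } else {
    disp <- rep(dispersion, nrow(counts))
  }

  s1 <- rowSums(pseudo[, g1, drop = FALSE])
  s2 <- rowSums(pseudo[, g2, drop = FALSE])
  p <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_p(s1[i], s2[i], n1, n2, mu_hat[i], disp[i], mid_p)
  }, numeric(1))
  names(p) <- rownames(counts)
  p
}

# method-of-moments dispersion: pooled within-group variance vs mean,
# tagwise estimates shrunk toward the common value
moment_dispersion <- function(pseudo, g1, g2, prior_df) {
  m1 <- rowMeans(pseudo[, g1, drop = FALSE])
  m2 <- rowMeans(pseudo[, g2, drop = FALSE])
  n1 <- sum(g1); n2 <- sum(g2)
  ss <- rowSums((pseudo[, g1, drop = FALSE] - m1)^2) +
    rowSums((pseudo[, g2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  v <- ss / df
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  raw <- (v - mu) / mu^2
  ok <- is.finite(raw) & mu > 0
  raw[!ok] <- 0
  raw <- pmax(raw, 0)
  common <- if (any(ok)) mean(raw[ok]) else 0
  (df * raw + prior_df * common) / (df + prior_df)
}

# conditional NB exact test for one gene; sums of n iid NB(mu, size = 1/phi)
# are NB(n * mu, size = n / phi)
nb_exact_p <- function(s1, s2, n1, n2, mu, phi, mid_p) {
  t <- s1 + s2
  if (t == 0) return(1)
  if (phi <= 0) {
    # Poisson limit: conditional law is binomial
    lp <- dbinom(0:t, t, n1 / (n1 + n2), log = TRUE)
  } else {
    k <- 0:t
    lp <- dnbinom(k, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      dnbinom(t - k, size = n2 / phi, mu = n2 * mu, log = TRUE)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  lobs <- lp[s1 + 1]
  tol <- 1e-10
  le <- lp <= lobs + tol
  eq <- abs(lp - lobs) <= tol
  pv <- sum(exp(lp[le]))
  if (mid_p) pv <- pv - 0.5 * sum(exp(lp[eq]))
  min(max(pv, 0), 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#'
#' @param p_values Numeric p-values in `[0, 1]` (names kept).
#' @return q-values, same order and names as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Three-criterion differential-expression filter
#'
#' Retains a gene when all of the following hold: mean FPKM strictly above
#' `min_fpkm` in at least one group; absolute signed fold change at least
#' `min_abs_fc`; p-value at most `max_p`. FPKM is strict and the fold-change /
#' p-value criteria are inclusive. The returned set carries, per gene, group
#' mean expressions on the log2 scale (`e1`, `e2`, with offset `log_offset`),
#' their average `a` and difference `d = e2 - e1`, the signed fold change on
#' the linear FPKM scale, and p / BH q values.
#'
#' @param expr An [expression_dataset()] (or a list with `fpkm`, `design`).
#' @param p_values Named per-gene p-values covering every gene of `expr`.
#' @param min_fpkm Strict expression threshold (FPKM); default 0.5.
#' @param min_abs_fc Inclusive absolute fold-change threshold; default 1.5.
#' @param max_p Inclusive p-value threshold; default 0.01.
#' @param pseudocount Pseudocount for the fold change; default 0.25.
#' @param log_offset Offset inside the log2 transform of FPKM; default 0.25.
#' @return An object of class `de_genes`: a data frame with columns
#'   `gene, e1, e2, a, d, fc, p, q` and attribute `n_de`.
#' @export
filter_de <- function(expr, p_values, min_fpkm = 0.5, min_abs_fc = 1.5,
                      max_p = 0.01, pseudocount = 0.25, log_offset = 0.25) {
  fpkm <- as.matrix(expr$fpkm)
  design <- check_design(expr$design, colnames(fpkm), ncol(fpkm))
  ids <- rownames(fpkm) %||% as.character(seq_len(nrow(fpkm)))
  if (!all(ids %in% names(p_values))) {
    stop("a p-value is required for every gene in the dataset")
  }
  p <- p_values[ids]
  q <- bh_fdr(p)

  gm <- group_means(fpkm, design)
  fc <- signed_fold_change(gm[, 1], gm[, 2], pseudocount)
  logf <- log2(fpkm + log_offset)
  lg <- group_means(logf, design)

  keep <- (gm[, 1] > min_fpkm | gm[, 2] > min_fpkm) &
    abs(fc) >= min_abs_fc & p <= max_p
  res <- data.frame(
    gene = ids[keep],
    e1 = lg[keep, 1], e2 = lg[keep, 2],
    a = (lg[keep, 1] + lg[keep, 2]) / 2,
    d = lg[keep, 2] - lg[keep, 1],
    fc = fc[keep], p = p[keep], q = q[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "n_de") <- nrow(res)
  attr(res, "thresholds") <- c(min_fpkm = min_fpkm, min_abs_fc = min_abs_fc,
                               max_p = max_p)
  class(res) <- c("de_genes", "data.frame")
  res
}

#' @export
print.de_genes <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "Differentially expressed genes: %d (FPKM > %g, |FC| >= %g, p <= %g)\n",
    nrow(x), th[["min_fpkm"]], th[["min_abs_fc"]], th[["max_p"]]))
  if (nrow(x)) {
    cat(sprintf("  higher in group B: %d, higher in group A: %d\n",
                sum(x$fc > 0), sum(x$fc < 0)))
    print(utils::head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat("  ...\n")
  }
  invisible(x)
}
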