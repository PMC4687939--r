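# Efficiency-corrected qPCR relative expression: the joint mixed model on
# y = Cp * log2(E), genotype contrasts normalized by reference genes,
# FC = 2^(-diff_TG), a geNorm-style reference stability statistic, and Lin's
# concordance correlation coefficient.

#' Efficiency-corrected Cp transform
#'
#' `y = -log2(E^(-Cp)) = Cp * log2(E)`. With a perfect doubling efficiency
#' (E = 2) the transform is the identity.
#'
#' @param Cp Quantification cycles (vectorized).
#' @param E Amplification efficiency in (1, 2], per value or scalar.
#' @return Transformed expression values on the y (log2) scale.
#' @export
transform_cp <- function(Cp, E) {
  if (any(E <= 1 | E > 2)) stop("efficiency must lie in (1, 2]")
  Cp * log2(E)
}

#' Fit the joint qPCR mixed model
#'
#' Fits `y_gikr = TG_gi + B_gk + D_ik + e_gikr`: fixed gene-by-genotype cell
#' means, random pig-within-gene effects, random sample (animal) effects
#' common to all genes, and a residual, by REML (`lme4`). When the mixed fit
#' is degenerate (zero variance components or a singular design) the function
#' falls back to ordinary least squares on the fixed effects, which leaves
#' the cell-mean estimates intact.
#'
#' @param data A `qpcr_dataset` (see [generate_qpcr_dataset()] and
#'   [read_qpcr_csv()]): Cp records plus per-gene efficiencies.
#' @param mean_cp Average the replicate Cp values per gene and animal before
#'   fitting (the "mean Cp" variant); default `FALSE` (replicates enter as
#'   repeated measures).
#' @return Object of class `qpcr_fit`: list with the fixed-effect estimates
#'   (`beta`), their covariance (`vcov`), factor levels, the number of
#'   animals, and the underlying fit.
#' @export
fit_qpcr_model <- function(data, mean_cp = FALSE) {
  df <- data$data
  need <- c("gene", "animal", "group", "replicate", "Cp")
  if (!all(need %in% names(df))) stop("missing qPCR columns")
  if (length(unique(df$group)) != 2L) stop("exactly two groups are required")
  seen <- unique(df[, c("gene", "group")])
  if (any(table(seen$gene) < 2L)) {
    stop("singular design: a gene is observed in only one group")
  }
  if (mean_cp) {
    df <- aggregate(Cp ~ gene + animal + group, df, mean)
    df$replicate <- 1L
  }
  df$y <- transform_cp(df$Cp, data$efficiency[df$gene])
  df$gene <- factor(df$gene)
  df$group <- factor(df$group)
  df$animal <- factor(df$animal)
  df$gene_animal <- interaction(df$gene, df$animal, drop = TRUE)

  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(y ~ 0 + gene:group + (1 | gene_animal) + (1 | animal),
                 data = df,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- lm(y ~ 0 + gene:group, data = df)
    beta <- coef(fit)
    V <- vcov(fit)
    V[!is.finite(V)] <- 0
    method <- "ols"
  } else {
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    method <- "reml"
  }
  structure(list(
    beta = beta, vcov = V, fit = fit, method = method,
    genes = levels(df$gene), groups = levels(df$group),
    roles = data$role, efficiency = data$efficiency,
    n_animals = nlevels(df$animal), data = df
  ), class = "qpcr_fit")
}

#' @export
print.qpcr_fit <- function(x, ...) {
  cat(sprintf("qPCR mixed model (%s): %d genes, %d animals, %d records\n",
              toupper(x$method), length(x$genes), x$n_animals, nrow(x$data)))
  invisible(x)
}

# name of the fixed-effect coefficient for a gene x group cell
qpcr_coef_name <- function(gene, group) sprintf("gene%s:group%s", gene, group)

#' Reference-normalized genotype contrast and fold change
#'
#' For each target gene, `diff_TG` is the genotype contrast of its cell means
#' (group A minus group B on the y scale) minus the mean contrast of the
#' reference genes. Its standard error comes from the fixed-effect
#' covariance, the t statistic uses containment degrees of freedom
#' (`n_animals - 2`), and the fold change is `FC = 2^(-diff_TG)`.
#'
#' @param fit A [fit_qpcr_model()] result.
#' @param targets Target gene names; defaults to all genes with role
#'   "target".
#' @param references Reference gene names; defaults to all genes with role
#'   "reference".
#' @return Object of class `qpcr_de`: data frame
#'   `gene, diff_tg, se, t, p, fc`.
#' @export
estimate_diff_tg <- function(fit, targets = NULL, references = NULL) {
  if (is.null(targets)) targets <- names(which(fit$roles == "target"))
  if (is.null(references)) references <- names(which(fit$roles == "reference"))
  if (length(references) == 0) stop("at least one reference gene is required")
  if (any(targets %in% references)) {
    stop("a target gene cannot be its own reference")
  }
  ga <- fit$groups[1]; gb <- fit$groups[2]
  cn <- names(fit$beta)
  contrast_for <- function(target) {
    cv <- setNames(rep(0, length(cn)), cn)
    cv[qpcr_coef_name(target, ga)] <- 1
    cv[qpcr_coef_name(target, gb)] <- -1
    for (r in references) {
      cv[qpcr_coef_name(r, ga)] <- cv[qpcr_coef_name(r, ga)] - 1 / length(references)
      cv[qpcr_coef_name(r, gb)] <- cv[qpcr_coef_name(r, gb)] + 1 / length(references)
    }
    cv
  }
  df <- max(fit$n_animals - 2, 1)
  rows <- lapply(targets, function(tg) {
    cv <- contrast_for(tg)
    est <- sum(cv * fit$beta)
    se <- sqrt(max(as.numeric(cv %*% fit$vcov %*% cv), 0))
    tval <- if (se > 0) est / se else NA_real_
    data.frame(gene = tg, diff_tg = est, se = se, t = tval,
               p = if (is.na(tval)) NA_real_ else 2 * pt(-abs(tval), df),
               fc = 2^(-est), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("qpcr_de", "data.frame"),
            references = references, df = df)
}

#' geNorm-style reference stability and normalization factors
#'
#' For candidate reference genes with efficiency-corrected relative
#' quantities `q` (genes x samples), the stability of gene g is the mean over
#' the other candidates h of the standard deviation across samples of
#' `log2(q_g / q_h)`. The two most stable genes define per-sample
#' normalization factors as the geometric mean of their quantities.
#'
#' @param quantities Positive matrix of relative quantities, candidate genes
#'   in rows, samples in columns.
#' @return List with `M` (named stability values, lower = more stable),
#'   `selected` (the two most stable genes) and `normalization_factors`
#'   (per sample).
#' @export
reference_stability <- function(quantities) {
  q <- as.matrix(quantities)
  if (nrow(q) < 2) stop("at least 2 candidate reference genes are required")
  if (any(q <= 0)) stop("relative quantities must be positive")
  lq <- log2(q)
  M <- vapply(seq_len(nrow(q)), function(g) {
    others <- setdiff(seq_len(nrow(q)), g)
    mean(vapply(others, function(h) sd(lq[g, ] - lq[h, ]), numeric(1)))
  }, numeric(1))
  names(M) <- rownames(q) %||% paste0("gene", seq_len(nrow(q)))
  selected <- names(sort(M))[1:2]
  nf <- exp(colMeans(log(q[selected, , drop = FALSE])))
  list(M = M, selected = selected, normalization_factors = nf)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 * cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. A reproducibility index: 1 only when the paired
#' values lie on the identity line.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return CCC in `[-1, 1]`.
#' @export
concordance_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("at least 2 pairs are required")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop("CCC undefined: zero variance and equal means")
  2 * sxy / denom
}
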