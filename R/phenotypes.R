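# Fatty-acid composition indices and the two-group phenotype comparison.

#' Parse and classify a fatty-acid name
#'
#' Names follow the shorthand `C<carbons>:<double bonds>[ n-<x>]`, e.g.
#' `"C18:0"`, `"C18:2 n-6"`. The saturation class follows the double-bond
#' count (0 = SFA, 1 = MUFA, >= 2 = PUFA) and the omega family comes from the
#' `n-` suffix when present.
#'
#' @param name Fatty-acid names (vectorized).
#' @return Data frame `name, carbons, double_bonds, class, family`.
#' @export
classify_fatty_acid <- function(name) {
  m <- regmatches(name, regexec("^C(\\d+):(\\d+)(?:\\s*n-(\\d+))?$", name))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop("unparseable fatty-acid name: ", paste(name[bad], collapse = ", "))
  }
  carbons <- vapply(m, function(x) as.integer(x[2]), integer(1))
  bonds <- vapply(m, function(x) as.integer(x[3]), integer(1))
  fam <- vapply(m, function(x) if (nzchar(x[4])) paste0("n-", x[4]) else "none",
                character(1))
  data.frame(
    name = name, carbons = carbons, double_bonds = bonds,
    class = ifelse(bonds == 0, "SFA", ifelse(bonds == 1, "MUFA", "PUFA")),
    family = fam, stringsAsFactors = FALSE
  )
}

#' Fatty-acid summary indices of one profile
#'
#' Sums by saturation class and omega family, the unsaturation index
#' `UI = sum_k k * (% fatty acids with k double bonds)` for k = 1..6, and
#' the n-6/n-3 and MUFA/SFA ratios. Only supplied components enter the sums.
#'
#' @param percentages Named numeric vector: fatty-acid name -> g/100 g total
#'   fatty acids.
#' @return Named list: `sum_sfa, sum_mufa, sum_pufa, sum_n3, sum_n6, ui,
#'   n6_n3_ratio, mufa_sfa_ratio` (ratios are `NA` when the denominator
#'   is 0).
#' @export
summary_indices <- function(percentages) {
  if (any(percentages < 0)) stop("percentages must be non-negative")
  info <- classify_fatty_acid(names(percentages))
  tot <- function(sel) sum(percentages[sel])
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  sum_sfa <- tot(info$class == "SFA")
  sum_mufa <- tot(info$class == "MUFA")
  sum_n3 <- tot(info$family == "n-3")
  sum_n6 <- tot(info$family == "n-6")
  ui <- sum(pmin(info$double_bonds, 6) * percentages * (info$double_bonds >= 1))
  list(
    sum_sfa = sum_sfa, sum_mufa = sum_mufa,
    sum_pufa = tot(info$class == "PUFA"),
    sum_n3 = sum_n3, sum_n6 = sum_n6, ui = ui,
    n6_n3_ratio = ratio(sum_n6, sum_n3),
    mufa_sfa_ratio = ratio(sum_mufa, sum_sfa)
  )
}

#' Per-animal fatty-acid indices of a profile table
#'
#' @param profiles Data frame from [generate_fatty_acid_profiles()] /
#'   [read_fatty_acid_csv()]: columns `animal`, `group`, plus one column per
#'   fatty acid.
#' @return Data frame with `animal`, `group` and one column per index.
#' @export
fatty_acid_indices <- function(profiles) {
  fa_cols <- setdiff(names(profiles), c("animal", "group"))
  idx <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(i) {
    as.data.frame(summary_indices(
      setNames(as.numeric(profiles[i, fa_cols]), fa_cols)))
  }))
  cbind(profiles[, c("animal", "group")], idx)
}

#' Two-group phenotype comparison with an optional covariate
#'
#' Ordinary least squares with a group effect and an optional covariate;
#' the covariate is dropped when its own p-value exceeds `covariate_alpha`
#' (default 0.05). Returns covariate-adjusted group means, a pooled standard
#' error of the mean, and the two-sided p-value of the group effect.
#'
#' @param values Per-animal trait values.
#' @param groups Group labels (two groups, >= 2 animals each).
#' @param covariate Optional per-animal covariate (e.g. carcass weight).
#' @param covariate_alpha Retention threshold for the covariate; default 0.05.
#' @return List: `means` (named, adjusted), `sem`, `p`, `covariate_used`,
#'   `zero_variance` flag. With zero residual variance and no group
#'   difference, `p` is `NA` and the flag is set.
#' @export
group_compare <- function(values, groups, covariate = NULL,
                          covariate_alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 animals")
  use_cov <- !is.null(covariate)
  if (use_cov) {
    if (abs(suppressWarnings(cor(as.numeric(groups), covariate))) > 1 - 1e-10) {
      stop("singular fit: covariate is collinear with the group")
    }
    fit <- lm(values ~ groups + covariate)
    cov_p <- summary(fit)$coefficients["covariate", 4]
    if (is.na(cov_p) || cov_p > covariate_alpha) use_cov <- FALSE
  }
  if (!use_cov) fit <- lm(values ~ groups)
  # degenerate zero-variance fits are legitimate here and flagged below
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  sigma <- sm$sigma
  n_per <- table(groups)
  if (use_cov) {
    cbar <- mean(covariate)
    means <- c(co[1, 1] + co["covariate", 1] * cbar,
               co[1, 1] + co[2, 1] + co["covariate", 1] * cbar)
  } else {
    means <- c(co[1, 1], co[1, 1] + co[2, 1])
  }
  names(means) <- levels(groups)
  zero_var <- sigma < 1e-12
  p <- if (zero_var) {
    if (abs(co[2, 1]) < 1e-12) NA_real_ else 0
  } else {
    co[2, 4]
  }
  list(
    means = means,
    sem = sigma * sqrt(mean(1 / n_per)),
    p = p,
    covariate_used = use_cov,
    zero_variance = zero_var
  )
}

#' Reference fatty-acid composition of neonatal pig muscle
#'
#' Mean biceps femoris intramuscular fatty-acid percentages (g/100 g total
#' fatty acids) for Iberian x Duroc crossbred (`IBxDU`) and purebred Iberian
#' (`IB`) neonates, shipped as a plain-text table. Used as the default
#' group-mean input of [generate_fatty_acid_profiles()] and as the worked
#' example for the summary indices.
#'
#' @return Data frame with row names = fatty-acid names and columns `IBxDU`,
#'   `IB`.
#' @export
reference_fatty_acids <- function() {
  path <- system.file("extdata", "fatty_acid_reference.csv",
                      package = "rifpipe", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out <- df[, c("IBxDU", "IB")]
  rownames(out) <- df$fatty_acid
  out
}
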