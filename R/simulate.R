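# Synthetic-data generators. Every input of the pipeline can be produced
# here with planted ground truth: negative-binomial counts with planted DE
# genes and planted regulators, qPCR Cp replicates from the inverse of the
# mixed model, per-group variant tables, and fatty-acid profiles.

#' Simulation configuration
#'
#' Collects and validates the parameters of the expression generator. The
#' defaults state the emulated study design: two genotypes with 6 animals
#' each, a desk-scale transcriptome of 2,000 genes of which 149 are truly
#' differentially expressed with fold changes between 1.9 and 12, a candidate
#' regulator catalogue of 100 genes with 3 planted regulators, and typical
#' bulk RNA-seq negative-binomial noise.
#'
#' @param n_genes Total number of genes.
#' @param n_trf Number of candidate transcription regulators (TRF) among them.
#' @param n_planted_regulators Number of TRFs planted as true regulators
#'   (differentially co-expressed with their targets between groups).
#' @param n_de_true Number of genes with a true fold change (never TRFs).
#' @param samples_per_group Animals per genotype; default 6.
#' @param fc_range Range of true fold-change magnitudes, lower bound > 1;
#'   default `c(1.9, 12)`.
#' @param dispersion Negative-binomial overdispersion; default 0.1.
#' @param library_size_mean Expected per-sample total count; default 1e6.
#' @param seed Integer seed driving the root generator.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000, n_trf = 100, n_planted_regulators = 3,
                       n_de_true = 149, samples_per_group = 6,
                       fc_range = c(1.9, 12), dispersion = 0.1,
                       library_size_mean = 1e6, seed = 1) {
  stopifnot(n_genes >= 1, n_trf >= 1, samples_per_group >= 1,
            dispersion > 0, library_size_mean >= 1)
  if (n_planted_regulators < 0 || n_planted_regulators > n_trf) {
    stop("need 0 <= n_planted_regulators <= n_trf")
  }
  if (n_trf > n_genes) stop("n_trf cannot exceed n_genes")
  if (n_de_true < 0 || n_de_true > n_genes - n_trf) {
    stop("need 0 <= n_de_true <= n_genes - n_trf (planted targets are not TRFs)")
  }
  if (length(fc_range) != 2L || fc_range[1] <= 1 || fc_range[2] < fc_range[1]) {
    stop("fc_range must be an increasing pair with lower bound > 1")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_trf = as.integer(n_trf),
    n_planted_regulators = as.integer(n_planted_regulators),
    n_de_true = as.integer(n_de_true),
    samples_per_group = as.integer(samples_per_group),
    fc_range = as.numeric(fc_range), dispersion = dispersion,
    library_size_mean = library_size_mean, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a two-group expression dataset with planted truth
#'
#' Counts are negative-binomial with gene-specific baseline means drawn
#' log-normally. For each true DE gene the group-B mean is the group-A mean
#' times the planted fold change (direction per its sign; negative = higher
#' in group A). The planted regulators form one co-active program driving the
#' module of DE genes upregulated in group A: a shared latent per-sample
#' factor couples regulators and module in group A, while in group B the
#' module responds to the factor with the opposite sign, so the
#' regulator-target correlation inverts between groups (`r1 != r2`). Gene
#' lengths are uniform on 300-10,000 bp. Equal seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expr` (an [expression_dataset()]) and
#'   `truth` (class `ground_truth`: `de_gene_ids`, `planted_regulator_ids`,
#'   `true_fc`, `regulator_targets`).
#' @export
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 101L))
  ng <- config$n_genes
  ns <- 2L * config$samples_per_group

  gene_ids <- sprintf("gene%05d", seq_len(ng))
  trf_ids <- gene_ids[seq_len(config$n_trf)]
  is_trf <- gene_ids %in% trf_ids
  non_trf <- gene_ids[!is_trf]

  de_ids <- sort(sample(non_trf, config$n_de_true))
  planted <- sort(sample(trf_ids, config$n_planted_regulators))

  # signed fold changes, log-uniform magnitude; the purebred line carries
  # more upregulated genes (95:54 split in the emulated study)
  fc_mag <- exp(runif(config$n_de_true, log(config$fc_range[1]),
                      log(config$fc_range[2])))
  up_in_a <- runif(config$n_de_true) < 95 / 149
  true_fc <- setNames(ifelse(up_in_a, -fc_mag, fc_mag), de_ids)

  # regulator -> target coupling: the planted regulators form one co-active
  # program driving the module of DE genes upregulated in group A (the
  # dominant direction), via a single latent factor shared by regulators and
  # targets in group-A samples only. Direction-coherent targets keep the
  # differential co-expression aligned with the a_j * d_j weights instead of
  # cancelling across directions.
  regulator_targets <- list()
  if (config$n_planted_regulators > 0) {
    module <- de_ids[true_fc[de_ids] < 0]
    if (length(module) == 0) module <- de_ids
    regulator_targets <- lapply(setNames(planted, planted), function(p) module)
  }

  # baseline means, scaled to the target library size
  base <- rlnorm(ng, meanlog = log(50), sdlog = 1.5)
  base <- base * config$library_size_mean / sum(base)
  mu_a <- setNames(base, gene_ids)
  mu_b <- mu_a
  mu_b[de_ids] <- ifelse(true_fc < 0, mu_a[de_ids] / fc_mag,
                         mu_a[de_ids] * fc_mag)

  depth <- rlnorm(ns, 0, 0.1)  # per-sample depth wobble
  mu <- cbind(
    matrix(mu_a, ng, config$samples_per_group),
    matrix(mu_b, ng, config$samples_per_group)
  ) * rep(depth, each = ng)

  # latent co-expression factors (natural-log scale, sd 1: the strong
  # within-module correlation typical of a driven regulon). In group A the
  # regulators and the module move together; in group B the module responds
  # with the opposite sign, so the regulator-target correlation flips
  # (r2 = -r1) -- the planted regulators lose, and in fact invert, their
  # ability to act on the module in the crossbred background.
  # loading 1 on the regulators (TRFs are exempt from the DE test, so their
  # extra variance is harmless) and 0.4 on the module genes (keeps their
  # within-group dispersion low enough for the DE filter to find them)
  tau <- 1
  beta_mod <- 0.4
  if (length(planted) > 0) {
    spg <- config$samples_per_group
    module <- unique(unlist(regulator_targets))
    reg_rows <- match(planted, gene_ids)
    mod_rows <- match(module, gene_ids)
    f <- rnorm(spg, 0, tau)  # group A
    g <- rnorm(spg, 0, tau)  # group B
    bump <- function(rows, cols, fac, load) {
      adj <- exp(load * outer(rep(1, length(rows)), fac) - (load * tau)^2 / 2)
      mu[rows, cols] <<- mu[rows, cols] * adj
    }
    bump(reg_rows, seq_len(spg), f, 1)
    bump(mod_rows, seq_len(spg), f, beta_mod)
    bump(reg_rows, spg + seq_len(spg), g, 1)
    bump(mod_rows, spg + seq_len(spg), g, -beta_mod)
  }

  counts <- matrix(
    rnbinom(ng * ns, mu = as.vector(mu), size = 1 / config$dispersion),
    ng, ns
  )
  rownames(counts) <- gene_ids
  colnames(counts) <- c(sprintf("IB_%02d", seq_len(config$samples_per_group)),
                        sprintf("IBxDU_%02d", seq_len(config$samples_per_group)))
  design <- factor(rep(c("IB", "IBxDU"), each = config$samples_per_group),
                   levels = c("IB", "IBxDU"))
  names(design) <- colnames(counts)
  lengths <- setNames(sample(300:10000, ng, replace = TRUE), gene_ids)

  expr <- expression_dataset(counts, lengths, design, is_trf = is_trf)
  truth <- structure(list(
    de_gene_ids = de_ids,
    planted_regulator_ids = planted,
    true_fc = true_fc,
    regulator_targets = regulator_targets
  ), class = "ground_truth")
  list(expr = expr, truth = truth)
}

#' Generate a qPCR Cp table from the inverse of the mixed model
#'
#' Simulates quantification cycles according to the generative model
#' `y = TG + B + D + e` (genotype-by-gene fixed effect, pig-within-gene and
#' sample random effects, residual), then back-transforms to
#' `Cp = y / log2(E)`. Reference genes have a true genotype contrast of zero.
#'
#' @param n_targets,n_reference Numbers of target and reference genes.
#' @param animals_per_group Animals per genotype; default 6.
#' @param replicates Technical replicates per animal and gene; default 3.
#' @param true_diff Named genotype contrasts (group A minus group B on the
#'   y scale) for the target genes; unspecified targets default to draws from
#'   +/- Uniform(1, 3).
#' @param efficiencies Named per-gene amplification efficiencies in (1, 2];
#'   default 2 for every gene.
#' @param sigma_pig,sigma_sample,sigma_resid Standard deviations of the pig,
#'   sample and residual effects; defaults 0.2, 0.15, 0.2 cycles-equivalent.
#' @param seed Integer seed.
#' @return An object of class `qpcr_dataset`: list with `data` (data frame
#'   `gene, animal, group, replicate, Cp`), `efficiency` and `role` (named
#'   per-gene), and `true_diff`.
#' @export
generate_qpcr_dataset <- function(n_targets = 9, n_reference = 2,
                                  animals_per_group = 6, replicates = 3,
                                  true_diff = NULL, efficiencies = NULL,
                                  sigma_pig = 0.2, sigma_sample = 0.15,
                                  sigma_resid = 0.2, seed = 1) {
  stopifnot(n_targets >= 1, n_reference >= 1, animals_per_group >= 1,
            replicates >= 1, sigma_pig >= 0, sigma_sample >= 0,
            sigma_resid >= 0)
  set.seed(derive_seed(seed, 202L))
  genes <- c(sprintf("target%02d", seq_len(n_targets)),
             sprintf("ref%02d", seq_len(n_reference)))
  role <- setNames(rep(c("target", "reference"), c(n_targets, n_reference)),
                   genes)
  if (is.null(efficiencies)) efficiencies <- setNames(rep(2, length(genes)), genes)
  if (any(efficiencies <= 1 | efficiencies > 2)) {
    stop("efficiencies must lie in (1, 2]")
  }
  diff <- setNames(rep(0, length(genes)), genes)
  drawn <- sample(c(-1, 1), n_targets, replace = TRUE) * runif(n_targets, 1, 3)
  diff[seq_len(n_targets)] <- drawn
  if (!is.null(true_diff)) diff[names(true_diff)] <- true_diff
  diff[role == "reference"] <- 0

  groups <- c("IB", "IBxDU")
  animals <- paste0(rep(groups, each = animals_per_group), "_pig",
                    sprintf("%02d", seq_len(2 * animals_per_group)))
  animal_group <- setNames(rep(groups, each = animals_per_group), animals)

  base <- setNames(runif(length(genes), 18, 26), genes)  # TG in group A
  b_pig <- matrix(rnorm(length(genes) * length(animals), 0, sigma_pig),
                  length(genes), dimnames = list(genes, animals))
  d_sample <- setNames(rnorm(length(animals), 0, sigma_sample), animals)

  rec <- expand.grid(gene = genes, animal = animals,
                     replicate = seq_len(replicates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec$group <- animal_group[rec$animal]
  tg <- base[rec$gene] - ifelse(rec$group == groups[2], diff[rec$gene], 0)
  y <- tg + b_pig[cbind(rec$gene, rec$animal)] + d_sample[rec$animal] +
    rnorm(nrow(rec), 0, sigma_resid)
  rec$Cp <- y / log2(efficiencies[rec$gene])
  rec <- rec[, c("gene", "animal", "group", "replicate", "Cp")]

  structure(list(data = rec, efficiency = efficiencies, role = role,
                 true_diff = diff), class = "qpcr_dataset")
}

#' Generate per-group variant tables
#'
#' Draws a shared locus space, assigns each locus to one or both groups, and
#' samples coverages and allele frequencies so that the expected fraction of
#' potentially fixed calls (frequency >= 90%) among filter-passing variants
#' matches `p_fixed_groupA` / `p_fixed_groupB`. A configurable fraction of
#' loci falls inside the CDS of the supplied toy gene models so consequence
#' annotation is exercised.
#'
#' @param n_loci Number of distinct loci.
#' @param p_fixed_groupA,p_fixed_groupB Expected fixed fractions per group.
#' @param p_shared Probability that a locus is present in both groups.
#' @param toy_gene_models Optional [toy_gene_models()] object; required when
#'   `frac_cds > 0`.
#' @param frac_cds Fraction of loci placed inside CDS regions; default 0
#'   without gene models, 0.2 with.
#' @param coverage_mean Mean read coverage; default 60.
#' @param seed Integer seed.
#' @return List with components `A` and `B`, each a `variant_table` data
#'   frame (`chrom, pos, ref, alt, coverage, af, group`).
#' @export
generate_variant_dataset <- function(n_loci = 5000, p_fixed_groupA = 0.4,
                                     p_fixed_groupB = 0.3, p_shared = 0.8,
                                     toy_gene_models = NULL,
                                     frac_cds = if (is.null(toy_gene_models)) 0 else 0.2,
                                     coverage_mean = 60, seed = 1) {
  stopifnot(n_loci >= 1,
            p_fixed_groupA >= 0, p_fixed_groupA <= 1,
            p_fixed_groupB >= 0, p_fixed_groupB <= 1,
            p_shared >= 0, p_shared <= 1)
  if (frac_cds > 0 && is.null(toy_gene_models)) {
    stop("gene models are required to place loci inside CDS")
  }
  set.seed(derive_seed(seed, 303L))
  bases <- c("A", "C", "G", "T")

  n_cds <- round(frac_cds * n_loci)
  chrom <- rep("chrSim", n_loci)
  pos <- sample(1:5e6, n_loci)
  ref <- sample(bases, n_loci, replace = TRUE)
  if (n_cds > 0) {
    cds <- gene_model_cds_ranges(toy_gene_models)
    # distinct genomic positions so locus keys stay unique
    all_pos <- do.call(rbind, lapply(seq_len(nrow(cds)), function(i) {
      data.frame(chrom = cds$chrom[i], at = cds$start[i]:cds$end[i],
                 stringsAsFactors = FALSE)
    }))
    n_cds <- min(n_cds, nrow(all_pos))
    pick <- sample(nrow(all_pos), n_cds)
    chrom[seq_len(n_cds)] <- all_pos$chrom[pick]
    pos[seq_len(n_cds)] <- all_pos$at[pick]
    genome <- toy_gene_models$genome
    ref[seq_len(n_cds)] <- mapply(function(ch, p) {
      as.character(Biostrings::subseq(genome[[ch]], p, p))
    }, chrom[seq_len(n_cds)], pos[seq_len(n_cds)])
  }
  # variant type mixture: mostly SNVs, some MNV / indel / replacement
  type <- sample(c("SNV", "MNV", "insertion", "deletion", "replacement"),
                 n_loci, replace = TRUE,
                 prob = c(0.80, 0.08, 0.05, 0.05, 0.02))
  alt <- vapply(seq_len(n_loci), function(i) {
    r <- ref[i]
    switch(type[i],
      SNV = sample(setdiff(bases, r), 1),
      MNV = paste0(sample(setdiff(bases, r), 1), sample(bases, 1)),
      insertion = paste0(r, paste(sample(bases, 3, TRUE), collapse = "")),
      deletion = r,  # ref extended below
      replacement = paste0(sample(setdiff(bases, r), 1),
                           paste(sample(bases, 2, TRUE), collapse = "")))
  }, character(1))
  ref <- ifelse(type == "deletion",
                paste0(ref, vapply(seq_len(n_loci), function(i)
                  paste(sample(bases, 3, TRUE), collapse = ""), character(1))),
                ifelse(type == "MNV", paste0(ref, vapply(seq_len(n_loci),
                  function(i) sample(bases, 1), character(1))), ref))
  # keep MNV alt/ref distinct and equal length (resample clashes)
  clash <- ref == alt
  while (any(clash)) {
    alt[clash] <- vapply(which(clash), function(i) {
      paste(sample(bases, nchar(ref[i]), TRUE), collapse = "")
    }, character(1))
    clash <- ref == alt
  }

  membership <- sample(c("both", "A", "B"), n_loci, replace = TRUE,
                       prob = c(p_shared, (1 - p_shared) / 2,
                                (1 - p_shared) / 2))

  draw_group <- function(present, p_fixed) {
    idx <- which(present)
    n <- length(idx)
    fixed <- runif(n) < p_fixed
    af <- ifelse(fixed, runif(n, 0.90, 1.0), runif(n, 0.05, 0.8999))
    # a small tail of sub-threshold calls exercises the filters
    low <- runif(n) < 0.05
    af[low] <- runif(sum(low), 0.005, 0.0499)
    cov <- rnbinom(n, size = 8, mu = coverage_mean)
    data.frame(chrom = chrom[idx], pos = pos[idx], ref = ref[idx],
               alt = alt[idx], coverage = cov, af = af,
               stringsAsFactors = FALSE)
  }
  a <- draw_group(membership %in% c("both", "A"), p_fixed_groupA)
  b <- draw_group(membership %in% c("both", "B"), p_fixed_groupB)
  a$group <- "IB"; b$group <- "IBxDU"
  a <- a[order(a$chrom, a$pos), ]; rownames(a) <- NULL
  b <- b[order(b$chrom, b$pos), ]; rownames(b) <- NULL
  class(a) <- class(b) <- c("variant_table", "data.frame")
  list(A = a, B = b)
}

#' Generate per-animal fatty-acid profiles
#'
#' Adds Gaussian noise to the supplied group-mean percentages, truncates at
#' zero and renormalizes each animal's profile to sum to 100 g/100 g.
#'
#' @param animals_per_group Animals per group.
#' @param group_means Data frame or matrix of mean percentages: one row per
#'   fatty acid (row names = fatty-acid names such as `"C18:2 n-6"`), one
#'   column per group.
#' @param sd Common standard deviation of the per-animal noise; default 0.
#' @param seed Integer seed.
#' @return Data frame with columns `animal`, `group` and one column per
#'   fatty acid; every row sums to 100.
#' @export
generate_fatty_acid_profiles <- function(animals_per_group, group_means,
                                         sd = 0, seed = 1) {
  gm <- as.matrix(group_means)
  if (any(gm < 0)) stop("group means must be non-negative")
  if (sd < 0) stop("sd must be non-negative")
  set.seed(derive_seed(seed, 404L))
  groups <- colnames(gm) %||% paste0("group", seq_len(ncol(gm)))
  rows <- lapply(seq_along(groups), function(gi) {
    t(vapply(seq_len(animals_per_group), function(k) {
      x <- pmax(gm[, gi] + rnorm(nrow(gm), 0, sd), 0)
      100 * x / sum(x)
    }, numeric(nrow(gm))))
  })
  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- rownames(gm)
  data.frame(
    animal = paste0(rep(groups, each = animals_per_group), "_",
                    seq_len(animals_per_group)),
    group = rep(groups, each = animals_per_group),
    out, check.names = FALSE, stringsAsFactors = FALSE
  )
}
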