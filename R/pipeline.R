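# End-to-end orchestration: simulate -> de -> rif -> qpcr -> variants ->
# phenotypes, from a single validated configuration.

#' Pipeline configuration
#'
#' A single list of stage toggles, thresholds and paths with the study's
#' defaults (expression cutoff 0.5 FPKM, |FC| >= 1.5, p <= 0.01, 10,000
#' bootstrap repetitions, fixation threshold 90%, coverage floors 30 / 10,
#' allele-frequency floor 5%). Can be read from a JSON file.
#'
#' @param ... Named overrides of the defaults (see the function body for the
#'   full set).
#' @param file Optional JSON file of overrides, applied before `...`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(
    output_dir = tempfile("rifpipe_run_"),
    seed = 1L,
    stages = c("simulate", "de", "rif", "qpcr", "variants", "phenotypes"),
    sim = list(),                 # overrides for sim_config()
    min_fpkm = 0.5, min_abs_fc = 1.5, max_p = 0.01,
    boot_reps = 10000, boot_levels = c(95, 99),
    fixed_threshold = 0.90, min_coverage = 30, min_coverage_candidate = 10,
    min_freq = 0.05,
    n_variant_loci = 2000,
    qpcr = list(),                # overrides for generate_qpcr_dataset()
    fa_sd = 0.5, animals_per_group = 6
  )
  if (!is.null(file)) {
    over <- jsonlite::read_json(file, simplifyVector = TRUE)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$min_fpkm >= 0, cfg$min_abs_fc >= 1,
            cfg$max_p > 0, cfg$max_p <= 1,
            cfg$boot_reps >= 1, cfg$fixed_threshold > 0,
            cfg$fixed_threshold <= 1, cfg$min_coverage >= 0,
            cfg$min_freq >= 0, cfg$min_freq <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on synthetic inputs, writes every
#' artifact under `config$output_dir`, logs thresholds and seeds, and
#' returns a structured report. A stage failure aborts only its dependents
#' (`rif` depends on `de`; the remaining stages are independent).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages; default `TRUE`.
#' @return Object of class `pipeline_report`: per-stage results and counts.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (!quiet) message(msg)
  }
  report <- list(seed = config$seed, output_dir = config$output_dir,
                 stages = list())
  on <- function(s) s %in% config$stages
  note("seed: %d", config$seed)

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      note("stage %s failed: %s", name, conditionMessage(e))
      structure(list(error = conditionMessage(e)), class = "stage_error")
    })
  }

  sim <- de <- NULL
  if (on("simulate")) {
    report$stages$simulate <- run_stage("simulate", function() {
      cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      sim <<- generate_expression_dataset(cfg)
      write_expression_tsv(sim$expr,
                           file.path(config$output_dir, "counts.tsv"),
                           file.path(config$output_dir, "genes.tsv"),
                           file.path(config$output_dir, "design.tsv"))
      note("simulate: %d genes x %d samples, %d true DE, %d planted regulators",
           nrow(sim$expr$counts), ncol(sim$expr$counts),
           length(sim$truth$de_gene_ids),
           length(sim$truth$planted_regulator_ids))
      list(n_genes = nrow(sim$expr$counts),
           truth = sim$truth)
    })
  }

  if (on("de")) {
    report$stages$de <- run_stage("de", function() {
      if (is.null(sim)) stop("the de stage needs the simulate stage")
      p <- de_test(sim$expr$counts, sim$expr$design)
      de <<- filter_de(sim$expr, p, min_fpkm = config$min_fpkm,
                       min_abs_fc = config$min_abs_fc, max_p = config$max_p)
      write_de_tsv(de, file.path(config$output_dir, "de_genes.tsv"))
      expressed <- expressed_gene_set(sim$expr$fpkm, sim$expr$design,
                                      config$min_fpkm)
      note("de: %d expressed genes, %d DE (FPKM > %g, |FC| >= %g, p <= %g)",
           length(expressed), nrow(de), config$min_fpkm, config$min_abs_fc,
           config$max_p)
      list(n_expressed = length(expressed), n_de = nrow(de))
    })
  }

  if (on("rif")) {
    report$stages$rif <- run_stage("rif", function() {
      if (is.null(de) || nrow(de) == 0) stop("the rif stage needs a DE set")
      res <- rif_analysis(sim$expr, de, reps = config$boot_reps,
                          seed = config$seed)
      write_rif_tsv(res, file.path(config$output_dir, "rif.tsv"),
                    file.path(config$output_dir, "rif_ci.json"))
      note("rif: %d candidate regulators, %d outside the 95%% interval (reps = %d)",
           nrow(res), sum(res$sig95_1 | res$sig95_2), config$boot_reps)
      res
    })
  }

  if (on("qpcr")) {
    report$stages$qpcr <- run_stage("qpcr", function() {
      qd <- do.call(generate_qpcr_dataset,
                    c(config$qpcr, list(seed = derive_seed(config$seed, 7L),
                                        animals_per_group = config$animals_per_group)))
      write_qpcr_csv(qd, file.path(config$output_dir, "qpcr_cp.csv"),
                     file.path(config$output_dir, "qpcr_eff.csv"))
      fit <- fit_qpcr_model(qd)
      res <- estimate_diff_tg(fit)
      utils::write.table(as.data.frame(res),
                         file.path(config$output_dir, "qpcr_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      # concordance of planted truth vs estimate on the log2-FC scale
      truth_fc <- -qd$true_diff[res$gene]
      ccc <- concordance_ccc(truth_fc, log2(res$fc))
      note("qpcr: %d targets, CCC(truth, estimate) = %.3f", nrow(res), ccc)
      list(results = res, ccc = ccc)
    })
  }

  if (on("variants")) {
    report$stages$variants <- run_stage("variants", function() {
      models <- toy_gene_models(seed = derive_seed(config$seed, 11L))
      write_gene_models(models,
                        file.path(config$output_dir, "models.gff3"),
                        file.path(config$output_dir, "models.fa"))
      vd <- generate_variant_dataset(n_loci = config$n_variant_loci,
                                     toy_gene_models = models,
                                     seed = derive_seed(config$seed, 13L))
      write_vcf(vd$A, file.path(config$output_dir, "variants_IB.vcf"))
      write_vcf(vd$B, file.path(config$output_dir, "variants_IBxDU.vcf"))
      fa <- filter_variants(vd$A, config$min_coverage, config$min_freq)
      fb <- filter_variants(vd$B, config$min_coverage, config$min_freq)
      fa <- annotate_variants(fa, models)
      fb <- annotate_variants(fb, models)
      cmp <- compare_groups(fa, fb, config$fixed_threshold)
      jsonlite::write_json(
        rapply(cmp$summary, function(x)
          if (is.table(x)) as.list(setNames(as.integer(x), names(x))) else x,
          how = "replace"),
        file.path(config$output_dir, "variant_summary.json"),
        auto_unbox = TRUE, digits = NA)
      note("variants: %d/%d pass filters (A/B), %d fixed-in-A-segregating-in-B",
           nrow(fa), nrow(fb), cmp$summary$n_fixedA_segB)
      cmp
    })
  }

  if (on("phenotypes")) {
    report$stages$phenotypes <- run_stage("phenotypes", function() {
      prof <- generate_fatty_acid_profiles(
        config$animals_per_group, reference_fatty_acids(),
        sd = config$fa_sd, seed = derive_seed(config$seed, 17L))
      write_fatty_acid_csv(prof, file.path(config$output_dir, "fatty_acids.csv"))
      idx <- fatty_acid_indices(prof)
      cmp <- lapply(setdiff(names(idx), c("animal", "group")), function(v) {
        gc <- group_compare(idx[[v]], idx$group)
        data.frame(index = v, mean_IB = gc$means[["IB"]],
                   mean_IBxDU = gc$means[["IBxDU"]], sem = gc$sem, p = gc$p)
      })
      tab <- do.call(rbind, cmp)
      utils::write.table(tab,
                         file.path(config$output_dir, "fatty_acid_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("phenotypes: %d animals per group, %d indices", config$animals_per_group,
           nrow(tab))
      tab
    })
  }

  report$log <- log
  writeLines(log, file.path(config$output_dir, "pipeline.log"))
  failed <- vapply(report$stages, inherits, logical(1), "stage_error")
  report$ok <- !any(failed)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d): %s\n", x$seed,
              if (x$ok) "all stages completed" else "with stage failures"))
  for (line in x$log) cat(" ", line, "\n")
  cat("  artifacts in:", x$output_dir, "\n")
  invisible(x)
}
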