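# Plain-text readers and writers for every pipeline artifact. Writers are
# simple emitters; the standard parsers (VariantAnnotation, rtracklayer,
# Biostrings) do the reading of the genomic formats.

#' Write / read an expression dataset as TSV files
#'
#' Three tab-separated files: a counts matrix (genes x samples, header =
#' sample ids), gene metadata (`gene, length_bp, is_trf`) and a design table
#' (`sample, group`).
#'
#' @param expr An [expression_dataset()].
#' @param counts_path,genes_path,design_path File paths.
#' @return Invisibly (write) the paths; (read) the dataset.
#' @export
write_expression_tsv <- function(expr, counts_path, genes_path, design_path) {
  df <- data.frame(gene = rownames(expr$counts), expr$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene = expr$gene_ids,
               length_bp = expr$gene_length_bp[expr$gene_ids],
               is_trf = expr$is_trf[expr$gene_ids]),
    genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = expr$sample_ids,
               group = as.character(expr$design[expr$sample_ids])),
    design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = counts_path, genes = genes_path, design = design_path))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(counts_path, genes_path, design_path) {
  cdf <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf[[1]]
  gdf <- read.delim(genes_path, stringsAsFactors = FALSE)
  ddf <- read.delim(design_path, stringsAsFactors = FALSE)
  expression_dataset(
    counts,
    gene_length_bp = setNames(gdf$length_bp, gdf$gene),
    design = setNames(ddf$group, ddf$sample),
    is_trf = setNames(gdf$is_trf, gdf$gene)[rownames(counts)]
  )
}

#' Read a candidate-regulator list
#'
#' One gene id per line (the export format of transcription-factor
#' catalogues); blank lines and `#` comments are skipped.
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_trf_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a DE gene table as TSV
#'
#' Columns `gene, e1, e2, a, d, fc, p, q`.
#'
#' @param de A [filter_de()] result.
#' @param path File path.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a RIF result table as TSV (plus the bootstrap CI as JSON)
#'
#' @param rif A [classify_trf()] result.
#' @param path TSV path.
#' @param ci_path Optional JSON path for the bootstrap interval.
#' @export
write_rif_tsv <- function(rif, path, ci_path = NULL) {
  utils::write.table(as.data.frame(rif), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(ci_path)) {
    ci <- attr(rif, "ci")
    jsonlite::write_json(
      list(reps = ci$reps, n_de_drawn = ci$n_de_drawn, seed = ci$seed,
           ci = ci$ci),
      ci_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write / read qPCR tables
#'
#' The Cp table is a CSV with columns `gene, animal, group, replicate, Cp`;
#' efficiencies and roles live in a second CSV (`gene, E, role`).
#'
#' @param qpcr A `qpcr_dataset`.
#' @param cp_path,eff_path File paths.
#' @return Invisibly (write) the paths; (read) a `qpcr_dataset`.
#' @export
write_qpcr_csv <- function(qpcr, cp_path, eff_path) {
  write.csv(qpcr$data, cp_path, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(gene = names(qpcr$efficiency),
                       E = as.numeric(qpcr$efficiency),
                       role = qpcr$role[names(qpcr$efficiency)]),
            eff_path, row.names = FALSE, quote = FALSE)
  invisible(c(cp = cp_path, eff = eff_path))
}

#' @rdname write_qpcr_csv
#' @export
read_qpcr_csv <- function(cp_path, eff_path) {
  data <- read.csv(cp_path, stringsAsFactors = FALSE)
  eff <- read.csv(eff_path, stringsAsFactors = FALSE)
  structure(list(
    data = data,
    efficiency = setNames(eff$E, eff$gene),
    role = setNames(eff$role, eff$gene),
    true_diff = NULL
  ), class = "qpcr_dataset")
}

#' Write / read fatty-acid profiles as CSV
#'
#' @param profiles Data frame from [generate_fatty_acid_profiles()].
#' @param path File path.
#' @export
write_fatty_acid_csv <- function(profiles, path) {
  write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fatty_acid_csv
#' @export
read_fatty_acid_csv <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a variant table as VCF 4.2
#'
#' Minimal single-sample-free VCF with `DP` (coverage) and `AF` (allele
#' frequency) INFO fields, readable by any VCF parser.
#'
#' @param records `variant_table` data frame.
#' @param path Output path (`.vcf`).
#' @export
write_vcf <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read coverage\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    paste0("##source=rifpipe"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  records <- records[order(records$chrom, records$pos), ]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.6g",
                  records$chrom, records$pos, records$ref, records$alt,
                  as.integer(records$coverage), records$af)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a variant table from VCF or TSV
#'
#' VCF input (extension `.vcf`) is parsed with `VariantAnnotation`
#' (`DP` -> coverage, `AF` -> allele frequency); anything else is read as a
#' TSV with columns `chrom, pos, ref, alt, coverage, af`.
#'
#' @param path Input path.
#' @param group Optional group label attached to the records.
#' @return `variant_table` data frame.
#' @export
read_variants <- function(path, group = NA_character_) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
    af <- info$AF
    if (is.list(af) || methods::is(af, "List")) {
      af <- vapply(af, function(v) as.numeric(v)[1], numeric(1))
    }
    out <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(VariantAnnotation::ref(vcf)),
      alt = alt,
      coverage = as.integer(info$DP),
      af = as.numeric(af),
      group = group, stringsAsFactors = FALSE
    )
  } else {
    out <- read.delim(path, stringsAsFactors = FALSE)
    out$group <- group
  }
  class(out) <- c("variant_table", "data.frame")
  out
}
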