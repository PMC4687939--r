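# Variant filtering, fixed/segregating classification, cross-group
# comparison and toy coding-consequence annotation.

#' Filter variant calls on coverage and allele frequency
#'
#' Removes calls with coverage strictly under `min_coverage` or allele
#' frequency strictly under `min_freq`; boundary values survive. For
#' candidate-gene analyses the conventional coverage floor is 10 instead
#' of 30.
#'
#' @param records `variant_table` data frame with columns
#'   `chrom, pos, ref, alt, coverage, af`.
#' @param min_coverage Coverage threshold; calls with `coverage <
#'   min_coverage` are removed. Default 30.
#' @param min_freq Allele-frequency threshold; calls with `af < min_freq`
#'   are removed. Default 0.05.
#' @return The surviving records.
#' @export
filter_variants <- function(records, min_coverage = 30, min_freq = 0.05) {
  if (min_coverage < 0 || min_freq < 0) stop("thresholds must be non-negative")
  records[records$coverage >= min_coverage & records$af >= min_freq, ,
          drop = FALSE]
}

#' Classify allele frequency as potentially fixed or segregating
#'
#' Potentially fixed when the within-group allele frequency is greater than
#' or equal to `fixed_threshold` (default 90%), segregating otherwise.
#'
#' @param af Allele frequencies in `[0, 1]` (vectorized).
#' @param fixed_threshold Fixation threshold; default 0.90.
#' @return Character vector `"fixed"` / `"segregating"`.
#' @export
classify_frequency <- function(af, fixed_threshold = 0.90) {
  ifelse(af >= fixed_threshold, "fixed", "segregating")
}

#' Classify a variant by allele shape
#'
#' SNV: both alleles length 1. MNV: equal lengths > 1. Insertion/deletion:
#' one allele extends the other from a shared anchor (VCF-style anchored
#' alleles). Replacement: any other composite of neighboring changes.
#'
#' @param ref,alt Non-empty uppercase allele strings (vectorized).
#' @return Character vector with values `SNV, MNV, insertion, deletion,
#'   replacement`.
#' @export
classify_variant_type <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele")
  if (any(ref == alt)) stop("ref and alt must differ")
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1 & na == 1, "SNV",
  ifelse(nr == na, "MNV",
  ifelse(nr < na & substr(alt, 1, nr) == ref, "insertion",
  ifelse(nr > na & substr(ref, 1, na) == alt, "deletion",
         "replacement"))))
}

#' Compare the variants of two groups
#'
#' Matches loci between two filtered per-group tables on the exact key
#' `(chrom, pos, ref, alt)`, classifies each present call as fixed or
#' segregating, assigns the category `shared` / `unique_to_A` /
#' `unique_to_B`, and flags loci potentially fixed in group A while
#' segregating in group B (the differential-segregation signal). Per-group
#' summary counts (totals, fixed/segregating additivity, variant types, and
#' region / amino-acid-change counts when annotation columns are present)
#' are attached.
#'
#' @param table_a,table_b Filtered `variant_table` data frames.
#' @param fixed_threshold Fixation threshold; default 0.90.
#' @return Object of class `variant_comparison`: list with `loci` (one row
#'   per locus in the union: classes, category, flag) and `summary`.
#' @export
compare_groups <- function(table_a, table_b, fixed_threshold = 0.90) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  ka <- key(table_a); kb <- key(table_b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("duplicate locus keys within a group")
  }
  all_keys <- union(ka, kb)
  ia <- match(all_keys, ka); ib <- match(all_keys, kb)
  class_a <- ifelse(is.na(ia), "absent",
                    classify_frequency(table_a$af[ia], fixed_threshold))
  class_b <- ifelse(is.na(ib), "absent",
                    classify_frequency(table_b$af[ib], fixed_threshold))
  category <- ifelse(!is.na(ia) & !is.na(ib), "shared",
                     ifelse(!is.na(ia), "unique_to_A", "unique_to_B"))
  src <- ifelse(is.na(ia), ib, ia)
  from_a <- !is.na(ia)
  loci <- data.frame(
    chrom = ifelse(from_a, table_a$chrom[ia], table_b$chrom[ib]),
    pos = ifelse(from_a, table_a$pos[ia], table_b$pos[ib]),
    ref = ifelse(from_a, table_a$ref[ia], table_b$ref[ib]),
    alt = ifelse(from_a, table_a$alt[ia], table_b$alt[ib]),
    class_a = class_a, class_b = class_b, category = category,
    flag_fixedA_segB = class_a == "fixed" & class_b == "segregating",
    stringsAsFactors = FALSE
  )

  group_summary <- function(d) {
    cls <- classify_frequency(d$af, fixed_threshold)
    type <- classify_variant_type(d$ref, d$alt)
    s <- list(total = nrow(d),
              fixed = sum(cls == "fixed"),
              segregating = sum(cls == "segregating"),
              types = table(factor(type, levels = c("SNV", "MNV", "insertion",
                                                    "deletion", "replacement"))))
    if ("region" %in% names(d)) s$regions <- table(d$region)
    if ("consequence" %in% names(d)) {
      s$aa_change <- sum(d$consequence %in%
                           c("missense", "in-frame indel", "frameshift"))
    }
    s
  }
  summary <- list(
    A = group_summary(table_a), B = group_summary(table_b),
    categories = table(factor(loci$category,
                              levels = c("shared", "unique_to_A", "unique_to_B"))),
    n_fixedA_segB = sum(loci$flag_fixedA_segB)
  )
  structure(list(loci = loci, summary = summary,
                 fixed_threshold = fixed_threshold),
            class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  s <- x$summary
  cat("Variant comparison (locus key: chrom:pos:ref:alt)\n")
  cat(sprintf("  group A: %d variants (%d fixed, %d segregating)\n",
              s$A$total, s$A$fixed, s$A$segregating))
  cat(sprintf("  group B: %d variants (%d fixed, %d segregating)\n",
              s$B$total, s$B$fixed, s$B$segregating))
  cat(sprintf("  shared: %d, unique to A: %d, unique to B: %d\n",
              s$categories[["shared"]], s$categories[["unique_to_A"]],
              s$categories[["unique_to_B"]]))
  cat(sprintf("  potentially fixed in A while segregating in B: %d\n",
              s$n_fixedA_segB))
  invisible(x)
}

# CDS-coordinate projection of a genomic position for a single-transcript
# gene model; returns NA when outside every CDS block of the transcript
project_to_cds <- function(pos, cds_blocks, strand) {
  cds_blocks <- cds_blocks[order(cds_blocks$start), , drop = FALSE]
  widths <- cds_blocks$end - cds_blocks$start + 1L
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  hit <- which(pos >= cds_blocks$start & pos <= cds_blocks$end)
  if (!length(hit)) return(NA_integer_)
  fwd <- offsets[hit] + (pos - cds_blocks$start[hit]) + 1L
  if (strand == "+") fwd else sum(widths) - fwd + 1L
}

#' Annotate the coding consequence of a variant
#'
#' Projects a variant onto the spliced coding sequence of the overlapping
#' transcript (strand-aware: alleles are reverse-complemented for minus-
#' strand models), applies the alternate allele, translates with the
#' standard genetic code and classifies the outcome: `synonymous`,
#' `missense`, `in-frame indel` (net length change divisible by 3, with the
#' residue difference reported), `frameshift`, `UTR` for untranslated-region
#' variants, or `none` outside any transcript.
#'
#' @param record One-row data frame (or list) with `chrom, pos, ref, alt`.
#' @param gene_models A `gene_models` object ([toy_gene_models()] /
#'   [read_gene_models()]).
#' @return List with `consequence`, `transcript`, and for coding variants
#'   `protein_ref` / `protein_alt` (the translated reference and alternate
#'   coding sequences).
#' @export
annotate_consequence <- function(record, gene_models) {
  f <- gene_models$features
  pos <- as.integer(record$pos)
  ref <- as.character(record$ref); alt <- as.character(record$alt)
  end <- pos + nchar(ref) - 1L

  tx <- f[f$type == "mRNA" & f$seqid == record$chrom &
            f$start <= pos & f$end >= end, , drop = FALSE]
  if (nrow(tx) == 0) {
    return(list(consequence = "none", transcript = NA_character_))
  }
  tx <- tx[1, ]
  cds <- f[f$type == "CDS" & f$transcript_id == tx$transcript_id, , drop = FALSE]
  in_cds <- any(pos >= cds$start & end <= cds$end)
  if (!in_cds) {
    # inside the transcript but not fully inside a CDS block
    utr <- f[f$type %in% c("five_prime_UTR", "three_prime_UTR") &
               f$transcript_id == tx$transcript_id &
               f$start <= pos & f$end >= end, , drop = FALSE]
    if (nrow(utr)) {
      return(list(consequence = "UTR", transcript = tx$transcript_id))
    }
    stop("variant overlaps a CDS boundary; partial overlaps are unsupported")
  }

  strand <- tx$strand
  chrom_seq <- gene_models$genome[[record$chrom]]
  # genomic sanity check of the reference allele
  obs <- as.character(Biostrings::subseq(chrom_seq, pos, end))
  if (obs != ref) stop("reference allele does not match the genome")

  cds_seq <- extract_cds(gene_models, tx$transcript_id)
  if (nchar(cds_seq) %% 3 != 0) stop("malformed CDS: length not divisible by 3")
  cpos <- project_to_cds(pos, cds, strand)
  cend <- project_to_cds(end, cds, strand)
  if (strand == "-") {
    tmp <- cpos; cpos <- cend; cend <- tmp
    ref_t <- revcomp_chr(ref); alt_t <- revcomp_chr(alt)
  } else {
    ref_t <- ref; alt_t <- alt
  }
  stopifnot(substr(cds_seq, cpos, cend) == ref_t)
  alt_cds <- paste0(substr(cds_seq, 1, cpos - 1), alt_t,
                    substr(cds_seq, cend + 1, nchar(cds_seq)))

  shift <- nchar(alt_t) - nchar(ref_t)
  prot_ref <- translate_cds(cds_seq)
  if (shift %% 3 != 0) {
    return(list(consequence = "frameshift", transcript = tx$transcript_id,
                protein_ref = prot_ref, protein_alt = NA_character_))
  }
  prot_alt <- translate_cds(alt_cds)
  cons <- if (shift != 0) "in-frame indel"
          else if (prot_ref == prot_alt) "synonymous"
          else "missense"
  out <- list(consequence = cons, transcript = tx$transcript_id,
              protein_ref = prot_ref, protein_alt = prot_alt)
  if (cons == "in-frame indel") {
    out$residue_change <- sprintf("%+d residues", shift %/% 3)
  }
  out
}

# spliced CDS on the coding strand
extract_cds <- function(gene_models, transcript_id) {
  f <- gene_models$features
  cds <- f[f$type == "CDS" & f$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(cds)) stop("transcript has no CDS")
  cds <- cds[order(cds$start), ]
  pieces <- mapply(function(s, e) {
    as.character(Biostrings::subseq(gene_models$genome[[cds$seqid[1]]], s, e))
  }, cds$start, cds$end)
  seq <- paste(pieces, collapse = "")
  if (cds$strand[1] == "-") seq <- revcomp_chr(seq)
  seq
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_cds <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1, n)),
                                     if.fuzzy.codon = "X"))
}

#' Annotate a variant table against gene models
#'
#' Vectorized wrapper around [annotate_consequence()], adding `region`
#' (`CDS`, `UTR` or `intergenic`) and `consequence` columns.
#'
#' @param records `variant_table` data frame.
#' @param gene_models A `gene_models` object.
#' @return The records with `region` and `consequence` columns appended.
#' @export
annotate_variants <- function(records, gene_models) {
  res <- lapply(seq_len(nrow(records)), function(i) {
    tryCatch(annotate_consequence(records[i, ], gene_models),
             error = function(e) list(consequence = "none",
                                      transcript = NA_character_))
  })
  cons <- vapply(res, `[[`, character(1), "consequence")
  records$consequence <- cons
  records$region <- ifelse(cons == "none", "intergenic",
                           ifelse(cons == "UTR", "UTR", "CDS"))
  records
}
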