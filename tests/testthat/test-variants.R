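make_vt <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

test_that("coverage/frequency filtering removes strictly sub-threshold calls", {
  vt <- make_vt(chrom = "c1", pos = 1:4, ref = "A", alt = "G",
                coverage = c(29, 30, 100, 100),
                af = c(0.5, 0.05, 0.049, 0.5))
  out <- filter_variants(vt)
  expect_equal(out$pos, c(2, 4))  # 29x removed, 30x & 5% kept, 4.9% removed
  expect_error(filter_variants(vt, min_coverage = -1), "non-negative")
})

test_that("fixation classification is inclusive at 90%", {
  expect_equal(classify_frequency(c(0.90, 0.899, 1.0, 0.1)),
               c("fixed", "segregating", "fixed", "segregating"))
})

test_that("variant types follow the anchored-allele taxonomy", {
  expect_equal(classify_variant_type("A", "G"), "SNV")
  expect_equal(classify_variant_type("AT", "GC"), "MNV")
  expect_equal(classify_variant_type("ACGA", "A"), "deletion")
  expect_equal(classify_variant_type("A", "ACG"), "insertion")
  expect_equal(classify_variant_type("AC", "G"), "replacement")
  expect_error(classify_variant_type("A", "A"), "differ")
  expect_error(classify_variant_type("", "A"), "empty")
})

test_that("cross-group comparison matches the enumerated 3-locus oracle", {
  a <- make_vt(chrom = "c1", pos = c(10, 20), ref = "A", alt = "G",
               coverage = 50, af = c(0.95, 0.95))
  b <- make_vt(chrom = "c1", pos = c(10, 20, 30), ref = "A", alt = "G",
               coverage = 50, af = c(0.95, 0.60, 0.60))
  cmp <- compare_groups(a, b)
  loci <- cmp$loci[order(cmp$loci$pos), ]
  expect_equal(loci$flag_fixedA_segB, c(FALSE, TRUE, FALSE))
  expect_equal(unname(as.vector(cmp$summary$categories)), c(2, 0, 1))
  expect_equal(cmp$summary$n_fixedA_segB, 1)
  # spec case: gamma_A = 0.95 / gamma_B = 0.60 flags differential segregation
  expect_true(loci$flag_fixedA_segB[loci$pos == 20])
  dup <- rbind(a, a[1, ])
  expect_error(compare_groups(dup, b), "duplicate")
})

test_that("fixed + segregating = total after filtering, per group", {
  vd <- generate_variant_dataset(n_loci = 2000, seed = 3)
  fa <- filter_variants(vd$A); fb <- filter_variants(vd$B)
  cmp <- compare_groups(fa, fb)
  expect_equal(cmp$summary$A$fixed + cmp$summary$A$segregating,
               cmp$summary$A$total)
  expect_equal(cmp$summary$B$fixed + cmp$summary$B$segregating,
               cmp$summary$B$total)
  # categories partition the union of loci
  expect_equal(sum(cmp$summary$categories), nrow(cmp$loci))
  # raising either threshold never increases the surviving count
  expect_lte(nrow(filter_variants(vd$A, min_coverage = 50)), nrow(fa))
  expect_lte(nrow(filter_variants(vd$A, min_freq = 0.2)), nrow(fa))
})

test_that("coding consequences on the hand-built plus-strand model", {
  m <- toy_model_plus()  # CDS ATG AAA GCA TAA at 11..22
  # AAA -> AAG, third codon base: Lys -> Lys
  syn <- annotate_consequence(
    list(chrom = "ctg", pos = 16, ref = "A", alt = "G"), m)
  expect_equal(syn$consequence, "synonymous")
  # AAA -> AGA: Lys -> Arg
  mis <- annotate_consequence(
    list(chrom = "ctg", pos = 15, ref = "A", alt = "G"), m)
  expect_equal(mis$consequence, "missense")
  expect_equal(mis$protein_ref, "MKA*")
  expect_equal(mis$protein_alt, "MRA*")
  # anchored GCA deletion removes exactly one alanine
  del <- annotate_consequence(
    list(chrom = "ctg", pos = 16, ref = "AGCA", alt = "A"), m)
  expect_equal(del$consequence, "in-frame indel")
  expect_equal(del$residue_change, "-1 residues")
  expect_equal(del$protein_ref, "MKA*")
  expect_equal(del$protein_alt, "MK*")
  # 1-bp insertion shifts the frame
  fs <- annotate_consequence(
    list(chrom = "ctg", pos = 13, ref = "G", alt = "GT"), m)
  expect_equal(fs$consequence, "frameshift")
  # UTR and intergenic
  expect_equal(annotate_consequence(
    list(chrom = "ctg", pos = 7, ref = "C", alt = "T"), m)$consequence, "UTR")
  expect_equal(annotate_consequence(
    list(chrom = "ctg", pos = 2, ref = "G", alt = "T"), m)$consequence, "none")
})

test_that("substitution consequences agree with a whole-genome re-translation oracle", {
  models <- toy_gene_models(n_genes = 4, seed = 21)
  cds <- models$features[models$features$type == "CDS", ]
  set.seed(33)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    row <- cds[sample(nrow(cds), 1), ]
    pos <- sample(row$start:row$end, 1)
    chrom <- row$seqid
    ref <- as.character(Biostrings::subseq(models$genome[[chrom]], pos, pos))
    alt <- sample(setdiff(bases, ref), 1)
    got <- annotate_consequence(
      list(chrom = chrom, pos = pos, ref = ref, alt = alt), models)

    # oracle: mutate the contig, re-extract the CDS by coordinates,
    # translate the full protein on the annotated strand, and compare
    mut <- models
    s <- as.character(mut$genome[[chrom]])
    substr(s, pos, pos) <- alt
    mut$genome <- Biostrings::DNAStringSet(setNames(
      ifelse(names(models$genome) == chrom, s,
             as.character(models$genome)), names(models$genome)))
    blocks <- cds[cds$transcript_id == row$transcript_id, ]
    piece <- paste(mapply(function(st, en) substr(s, st, en),
                          blocks$start, blocks$end), collapse = "")
    if (row$strand == "-") {
      piece <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(piece)))
    }
    prot_alt <- as.character(Biostrings::translate(Biostrings::DNAString(piece)))
    expected <- if (prot_alt == got$protein_ref) "synonymous" else "missense"
    expect_equal(got$consequence, expected)
    expect_equal(got$protein_alt, prot_alt)
  }
})

test_that("VCF and gene-model files round-trip through the standard parsers", {
  vd <- generate_variant_dataset(n_loci = 120, seed = 5)
  vcf <- file.path(tempdir(), "grpA.vcf")
  write_vcf(vd$A, vcf)
  back <- read_variants(vcf, group = "IB")
  ord <- order(vd$A$chrom, vd$A$pos, vd$A$ref, vd$A$alt)
  bord <- order(back$chrom, back$pos, back$ref, back$alt)
  expect_equal(back$pos[bord], vd$A$pos[ord])
  expect_equal(back$ref[bord], vd$A$ref[ord])
  expect_equal(back$alt[bord], vd$A$alt[ord])
  expect_equal(back$coverage[bord], vd$A$coverage[ord])
  expect_equal(back$af[bord], vd$A$af[ord], tolerance = 1e-5)

  models <- toy_gene_models(n_genes = 3, seed = 4)
  gff <- file.path(tempdir(), "models.gff3")
  fa <- file.path(tempdir(), "models.fa")
  write_gene_models(models, gff, fa)
  back_m <- read_gene_models(gff, fa)
  expect_equal(as.character(back_m$genome), as.character(models$genome))
  f1 <- models$features[order(models$features$seqid, models$features$start,
                              models$features$type),
                        c("seqid", "type", "start", "end", "strand")]
  f2 <- back_m$features[order(back_m$features$seqid, back_m$features$start,
                              back_m$features$type),
                        c("seqid", "type", "start", "end", "strand")]
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f2, f1)
  # annotation gives the same calls through the round-tripped models
  cdsr <- models$features[models$features$type == "CDS", ][1, ]
  v <- list(chrom = cdsr$seqid, pos = cdsr$start + 3,
            ref = as.character(Biostrings::subseq(models$genome[[cdsr$seqid]],
                                                  cdsr$start + 3, cdsr$start + 3)),
            alt = "N")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  expect_equal(annotate_consequence(v, back_m)$consequence,
               annotate_consequence(v, models)$consequence)
})
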