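# Shared fixture builders. Everything is constructed in code; no files.

# expression dataset with fully controlled FPKM values (counts are a dummy
# copy; tests that need counts build their own)
make_expr <- function(fpkm, groups = NULL) {
  fpkm <- as.matrix(fpkm)
  if (is.null(colnames(fpkm))) {
    colnames(fpkm) <- sprintf("s%02d", seq_len(ncol(fpkm)))
  }
  if (is.null(rownames(fpkm))) {
    rownames(fpkm) <- sprintf("g%03d", seq_len(nrow(fpkm)))
  }
  if (is.null(groups)) {
    groups <- rep(c("IB", "IBxDU"), each = ncol(fpkm) / 2)
  }
  expression_dataset(
    counts = round(fpkm * 10) + 1L,
    gene_length_bp = setNames(rep(1000, nrow(fpkm)), rownames(fpkm)),
    design = setNames(groups, colnames(fpkm)),
    fpkm = fpkm
  )
}

# FPKM values whose log2(x + 0.25) equal the given matrix, so correlation
# structure on the log scale can be dictated exactly
fpkm_from_log2 <- function(logmat) 2^logmat - 0.25

# hand-built single-gene toy model on the plus strand:
# 5 bp flank | 5 bp 5'UTR | 12 bp CDS (ATG AAA GCA TAA) | 5 bp 3'UTR | 5 bp flank
toy_model_plus <- function() {
  seq <- paste0("GGGGG", "CCCCC", "ATGAAAGCATAA", "TTTTT", "GGGGG")
  structure(list(
    genome = Biostrings::DNAStringSet(c(ctg = seq)),
    features = data.frame(
      seqid = "ctg",
      type = c("gene", "mRNA", "five_prime_UTR", "CDS", "three_prime_UTR"),
      start = c(6, 6, 6, 11, 23),
      end = c(27, 27, 10, 22, 27),
      strand = "+", gene_id = "g1", transcript_id = "t1",
      stringsAsFactors = FALSE
    )
  ), class = "gene_models")
}

# small noiseless qPCR dataset: target Cp 20 (IB) / 22 (IBxDU),
# reference Cp 18 in both groups, E = 2 everywhere
noiseless_qpcr <- function(animals_per_group = 3, replicates = 2) {
  animals <- c(paste0("IB_p", seq_len(animals_per_group)),
               paste0("DU_p", seq_len(animals_per_group)))
  groups <- rep(c("IB", "IBxDU"), each = animals_per_group)
  rec <- expand.grid(gene = c("tgt", "ref"), animal = animals,
                     replicate = seq_len(replicates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec$group <- setNames(groups, animals)[rec$animal]
  rec$Cp <- ifelse(rec$gene == "ref", 18, ifelse(rec$group == "IB", 20, 22))
  structure(list(
    data = rec[, c("gene", "animal", "group", "replicate", "Cp")],
    efficiency = c(tgt = 2, ref = 2),
    role = c(tgt = "target", ref = "reference"),
    true_diff = c(tgt = -2, ref = 0)
  ), class = "qpcr_dataset")
}
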