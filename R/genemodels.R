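# Toy gene models: small single-transcript genes with UTRs and an intact CDS,
# written as GFF3 + FASTA and read back with the standard parsers. They exist
# to exercise coding-consequence annotation, not to model real gene structure.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct toy gene models
#'
#' Builds `n_genes` single-exon, single-transcript genes, each on its own
#' contig: 5' UTR, an intact CDS (ATG start, single terminal stop, no internal
#' stops on the coding strand), 3' UTR, and 50 bp flanks. Roughly half the
#' genes are placed on the minus strand.
#'
#' @param n_genes Number of genes; default 3.
#' @param cds_codons Codons per CDS including start and stop; default 60.
#' @param utr_len Length of each UTR in bp; default 30.
#' @param seed Integer seed.
#' @return An object of class `gene_models`: list with `genome`
#'   (a [Biostrings::DNAStringSet]) and `features` (a GFF3-style data frame
#'   with columns `seqid, type, start, end, strand, gene_id, transcript_id`).
#' @export
toy_gene_models <- function(n_genes = 3, cds_codons = 60, utr_len = 30,
                            seed = 1) {
  stopifnot(n_genes >= 1, cds_codons >= 3, utr_len >= 0)
  set.seed(derive_seed(seed, 505L))
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  sense_codons <- setdiff(all_codons, STOP_CODONS)
  flank <- 50L

  seqs <- character(n_genes)
  feats <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    contig <- sprintf("contig%d", i)
    gene_id <- sprintf("toygene%d", i)
    tx_id <- sprintf("toytx%d", i)
    strand <- if (i %% 2 == 0) "-" else "+"
    cds <- paste0("ATG",
                  paste(sample(sense_codons, cds_codons - 2, TRUE), collapse = ""),
                  sample(STOP_CODONS, 1))
    rnd <- function(n) paste(sample(bases, n, TRUE), collapse = "")
    transcript <- paste0(rnd(utr_len), cds, rnd(utr_len))  # transcript strand
    genomic <- if (strand == "+") transcript else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(transcript)))
    seqs[i] <- paste0(rnd(flank), genomic, rnd(flank))

    tx_start <- flank + 1L
    tx_end <- flank + nchar(transcript)
    # genomic coordinates of the CDS and UTRs (strand-aware)
    if (strand == "+") {
      cds_start <- tx_start + utr_len
      cds_end <- cds_start + nchar(cds) - 1L
      utr5 <- c(tx_start, tx_start + utr_len - 1L)
      utr3 <- c(cds_end + 1L, tx_end)
    } else {
      cds_end <- tx_end - utr_len
      cds_start <- cds_end - nchar(cds) + 1L
      utr5 <- c(cds_end + 1L, tx_end)
      utr3 <- c(tx_start, cds_start - 1L)
    }
    feats[[i]] <- data.frame(
      seqid = contig,
      type = c("gene", "mRNA", "five_prime_UTR", "CDS", "three_prime_UTR"),
      start = c(tx_start, tx_start, utr5[1], cds_start, utr3[1]),
      end = c(tx_end, tx_end, utr5[2], cds_end, utr3[2]),
      strand = strand, gene_id = gene_id, transcript_id = tx_id,
      stringsAsFactors = FALSE
    )
  }
  genome <- Biostrings::DNAStringSet(setNames(seqs, sprintf("contig%d", seq_len(n_genes))))
  structure(list(genome = genome, features = do.call(rbind, feats)),
            class = "gene_models")
}

# CDS ranges of a gene_models object as a plain data frame
gene_model_cds_ranges <- function(models) {
  f <- models$features
  f <- f[f$type == "CDS", c("seqid", "start", "end", "strand", "transcript_id")]
  names(f)[1] <- "chrom"
  f
}

#' Write gene models to GFF3 and FASTA
#'
#' @param models A [toy_gene_models()] object.
#' @param gff_path,fasta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gene_models <- function(models, gff_path, fasta_path) {
  f <- models$features
  attrs <- ifelse(
    f$type == "gene", sprintf("ID=%s", f$gene_id),
    ifelse(f$type == "mRNA",
           sprintf("ID=%s;Parent=%s", f$transcript_id, f$gene_id),
           sprintf("ID=%s:%s;Parent=%s", f$transcript_id, tolower(f$type),
                   f$transcript_id)))
  lines <- c("##gff-version 3",
             sprintf("%s\trifpipe\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                     f$seqid, f$type, f$start, f$end, f$strand,
                     ifelse(f$type == "CDS", "0", "."), attrs))
  writeLines(lines, gff_path)
  Biostrings::writeXStringSet(models$genome, fasta_path)
  invisible(c(gff = gff_path, fasta = fasta_path))
}

#' Read gene models from GFF3 and FASTA
#'
#' Uses `rtracklayer` for the GFF3 and `Biostrings` for the genome; returns
#' the same structure as [toy_gene_models()].
#'
#' @param gff_path,fasta_path Input paths.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  id <- as.character(gr$ID)
  parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  df$gene_id <- ifelse(df$type == "gene", id, NA)
  df$transcript_id <- ifelse(df$type == "mRNA", id,
                             ifelse(df$type == "gene", NA, parent))
  # propagate gene ids down from the mRNA rows
  mrna_gene <- setNames(parent[df$type == "mRNA"], id[df$type == "mRNA"])
  df$gene_id[is.na(df$gene_id)] <- mrna_gene[df$transcript_id[is.na(df$gene_id)]]
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  structure(list(genome = genome, features = df), class = "gene_models")
}
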