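# The gene x sample container shared by the DE and RIF stages.

#' Two-group expression dataset
#'
#' Bundles a count matrix, the matching FPKM matrix, gene lengths and a
#' two-group sample design. FPKM is computed from the column sums of the
#' counts when not supplied.
#'
#' @param counts Non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param gene_length_bp Positive gene lengths (bp), named by gene.
#' @param design Sample-to-group factor or character vector, named by sample;
#'   exactly two groups. The first factor level is group A (conventionally the
#'   purebred "IB"), the second group B ("IBxDU").
#' @param fpkm Optional precomputed FPKM matrix of the same dimensions.
#' @param is_trf Optional logical per gene flagging candidate transcription
#'   regulators.
#' @return An object of class `expression_dataset`: a list with elements
#'   `counts`, `fpkm`, `gene_length_bp`, `design`, `gene_ids`, `sample_ids`,
#'   `is_trf`.
#' @export
expression_dataset <- function(counts, gene_length_bp, design, fpkm = NULL,
                               is_trf = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample%02d", seq_len(ncol(counts)))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(gene_length_bp))) {
    gene_length_bp <- gene_length_bp[rownames(counts)]
  }
  design <- check_design(design, colnames(counts), ncol(counts))
  names(design) <- colnames(counts)
  if (is.null(fpkm)) {
    fpkm <- compute_fpkm(counts, gene_length_bp)
  } else {
    fpkm <- as.matrix(fpkm)
    if (!identical(dim(fpkm), dim(counts))) {
      stop("counts and fpkm must share dimensions")
    }
  }
  if (is.null(is_trf)) is_trf <- rep(FALSE, nrow(counts))
  structure(list(
    counts = counts,
    fpkm = fpkm,
    gene_length_bp = setNames(as.numeric(gene_length_bp), rownames(counts)),
    design = design,
    gene_ids = rownames(counts),
    sample_ids = colnames(counts),
    is_trf = setNames(as.logical(is_trf), rownames(counts))
  ), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$design)
  cat(sprintf(
    "Expression dataset: %d genes x %d samples (%s)\n",
    length(x$gene_ids), length(x$sample_ids),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  candidate regulators (TRF): %d\n", sum(x$is_trf)))
  invisible(x)
}
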