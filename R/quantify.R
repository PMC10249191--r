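#' Construct a raw count matrix
#'
#' Gene-level read counts, samples in rows, genes in columns.
#'
#' @param counts non-negative integer-valued matrix with sample rownames
#'   and gene colnames.
#' @return a `count_matrix`.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_matrix: sample rownames and gene colnames are required")
  if (anyDuplicated(colnames(counts)))
    stop("count_matrix: duplicate gene IDs")
  if (any(counts < 0)) stop("count_matrix: counts must be non-negative")
  structure(counts, class = c("count_matrix", class(counts)))
}

#' Construct a gene annotation table
#'
#' Per-gene metadata used by the abundance calculations: the exon-union
#' length in base pairs, the biotype (protein-coding genes are the only
#' biotype the pipeline's first filter retains, and the only genes that
#' enter the normalization denominators), and an autosome flag (the
#' upper-quartile unit's gene count G covers protein-coding genes on
#' autosomes only).
#'
#' @param gene_id character vector of gene IDs.
#' @param exon_union_length positive lengths in bp.
#' @param biotype character; `"protein_coding"` or other.
#' @param autosome logical flag per gene.
#' @return a `gene_annotation` data.frame.
#' @export
gene_annotation <- function(gene_id, exon_union_length,
                            biotype = "protein_coding", autosome = TRUE) {
  ann <- data.frame(gene_id = as.character(gene_id),
                    exon_union_length = as.numeric(exon_union_length),
                    biotype = rep_len(as.character(biotype), length(gene_id)),
                    autosome = rep_len(as.logical(autosome), length(gene_id)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$gene_id)) stop("gene_annotation: duplicate gene IDs")
  if (any(ann$exon_union_length <= 0))
    stop("gene_annotation: exon_union_length must be > 0 for every gene")
  class(ann) <- c("gene_annotation", class(ann))
  ann
}

match_annotation <- function(counts, ann) {
  idx <- match(colnames(counts), ann$gene_id)
  if (anyNA(idx)) {
    missing <- colnames(counts)[is.na(idx)]
    stop("annotation missing for genes: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  }
  ann[idx, , drop = FALSE]
}

#' Transcripts per million
#'
#' Length-normalized read rates rescaled per sample so that they sum to
#' exactly one million.
#'
#' @param counts a [count_matrix()].
#' @param ann a [gene_annotation()] covering every gene in `counts`.
#' @return an expression `OmicsMatrix` of TPM values.
#' @export
compute_tpm <- function(counts, ann) {
  ann <- match_annotation(counts, ann)
  rate <- sweep(unclass(counts), 2, ann$exon_union_length, `/`)
  tot <- rowSums(rate)
  if (any(tot == 0))
    stop("compute_tpm: zero total length-normalized count in sample(s): ",
         paste(rownames(counts)[tot == 0], collapse = ", "))
  omics_matrix(rate / tot * 1e6, "expression")
}

#' Fragments per kilobase per million mapped reads
#'
#' FPKM_g = C_g * 1e9 / (sum_i C_i * L_g), where the per-sample total
#' runs over the protein-coding genes and L_g is the exon-union length
#' of gene g in base pairs.
#'
#' @inheritParams compute_tpm
#' @return an expression `OmicsMatrix` of FPKM values.
#' @export
compute_fpkm <- function(counts, ann) {
  ann <- match_annotation(counts, ann)
  pc <- ann$biotype == "protein_coding"
  if (!any(pc)) stop("compute_fpkm: no protein-coding genes in annotation")
  tot <- rowSums(unclass(counts)[, pc, drop = FALSE])
  if (any(tot == 0))
    stop("compute_fpkm: zero protein-coding total count in sample(s): ",
         paste(rownames(counts)[tot == 0], collapse = ", "))
  x <- sweep(unclass(counts) * 1e9, 1, tot, `/`)
  x <- sweep(x, 2, ann$exon_union_length, `/`)
  omics_matrix(x, "expression")
}

#' Upper-quartile FPKM
#'
#' FPKM-UQ_g = C_g * 1e9 / (C_qtl(0.75) * G * L_g), where C_qtl(0.75) is
#' the per-sample 75th-percentile count over protein-coding genes
#' (linear-interpolation quantile, all protein-coding counts included)
#' and G counts protein-coding autosomal genes in the annotation. The
#' upper quartile replaces the noisier per-sample total, giving a more
#' stable sample-level scale factor.
#'
#' @inheritParams compute_tpm
#' @param quantile_type quantile estimator passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @param nonzero_only if `TRUE`, compute the quartile over nonzero
#'   protein-coding counts only (default `FALSE`).
#' @return an expression `OmicsMatrix` of FPKM-UQ values.
#' @export
compute_fpkm_uq <- function(counts, ann, quantile_type = 7,
                            nonzero_only = FALSE) {
  ann <- match_annotation(counts, ann)
  pc <- ann$biotype == "protein_coding"
  if (!any(pc)) stop("compute_fpkm_uq: no protein-coding genes in annotation")
  G <- sum(pc & ann$autosome)
  if (G == 0) stop("compute_fpkm_uq: no protein-coding autosomal genes (G = 0)")
  pc_counts <- unclass(counts)[, pc, drop = FALSE]
  uq <- apply(pc_counts, 1, function(v) {
    if (nonzero_only) v <- v[v > 0]
    if (length(v) == 0) return(0)
    stats::quantile(v, 0.75, type = quantile_type, names = FALSE)
  })
  if (any(uq == 0))
    stop("compute_fpkm_uq: zero upper-quartile count in sample(s): ",
         paste(rownames(counts)[uq == 0], collapse = ", "))
  x <- sweep(unclass(counts) * 1e9, 1, uq * G, `/`)
  x <- sweep(x, 2, ann$exon_union_length, `/`)
  omics_matrix(x, "expression")
}

#' Filter an expression matrix to protein-coding genes
#'
#' The first feature-reduction stage: only genes annotated as
#' protein-coding are retained.
#'
#' @param x an expression `OmicsMatrix` or [count_matrix()].
#' @param ann a [gene_annotation()].
#' @return the input restricted to protein-coding genes, original order.
#' @export
filter_protein_coding <- function(x, ann) {
  keep <- colnames(x) %in% ann$gene_id[ann$biotype == "protein_coding"]
  x[, keep, drop = FALSE]
}
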