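#' @title Tab-separated table I/O
#' @description All matrices travel as TSV with a `submitter_id` first
#'   column and a header row of feature IDs. Version-suffixed Ensembl
#'   gene IDs (`ENSG...\.N`) are normalized to their unversioned form on
#'   read.
#' @name pipeline_io
NULL

#' Write an OmicsMatrix as TSV
#'
#' @param x an `OmicsMatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(x, path) {
  df <- data.frame(submitter_id = rownames(x),
                   as_plain(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

strip_ensembl_version <- function(ids) sub("^(ENSG\\d+)\\.\\d+$", "\\1", ids)

read_tsv_matrix <- function(path, what) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("read_", what, "_table: expected a submitter-ID column plus features")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("read_", what, "_table: duplicate submitter IDs in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  feat <- strip_ensembl_version(colnames(m))
  dup <- feat[duplicated(feat)]
  if (length(dup))
    stop("read_", what, "_table: duplicate feature IDs after version ",
         "normalization: ", paste(utils::head(unique(dup), 5), collapse = ", "))
  colnames(m) <- feat
  rownames(m) <- ids
  m
}

#' Read an expression (or count) table
#'
#' Delimited text, first column submitter ID, header row of gene IDs;
#' version-suffixed Ensembl IDs are normalized, and a collision after
#' normalization is an error. Non-numeric cells are an error naming the
#' offending coordinates.
#'
#' @param path TSV path.
#' @return an expression `OmicsMatrix`.
#' @export
read_expression_table <- function(path) {
  m <- read_tsv_matrix(path, "expression")
  if (!is.numeric(m)) {
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                   dimnames = dimnames(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop("read_expression_table: non-numeric cell at row '",
           rownames(m)[bad[1, 1]], "', column '",
           colnames(m)[bad[1, 2]], "'")
    m <- num
  }
  omics_matrix(m, "expression")
}

#' Read a copy-number category table
#'
#' Cells must be integer categories.
#'
#' @param path TSV path.
#' @return a cnv `OmicsMatrix`.
#' @export
read_cnv_table <- function(path) {
  m <- read_tsv_matrix(path, "cnv")
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  bad <- which((is.na(num) & !is.na(m)) | (num != round(num)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("read_cnv_table: unparseable category at row '",
         rownames(m)[bad[1, 1]], "', column '", colnames(m)[bad[1, 2]], "'")
  omics_matrix(num, "cnv")
}

#' Read a clinical attribute table
#'
#' Empty cells and `NA` are recorded as missing. Non-numeric categorical
#' strings are factor-encoded to integer codes (level order is sorted);
#' numeric columns are kept as numbers.
#'
#' @param path TSV path.
#' @return a clinical `OmicsMatrix` (numeric with `NA` for missing).
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("read_clinical_table: duplicate submitter IDs in ", path)
  df <- df[, -1, drop = FALSE]
  cols <- lapply(df, function(v) {
    if (is.numeric(v)) return(v)
    num <- suppressWarnings(as.numeric(v))
    if (all(is.na(num) == is.na(v))) return(num)
    as.numeric(factor(v, levels = sort(unique(v[!is.na(v)])))) - 1
  })
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  omics_matrix(m, "clinical")
}

#' Read a labels table
#'
#' Two columns: `submitter_id`, `vital_status` (0/1).
#'
#' @param path TSV path.
#' @return named integer vector.
#' @export
read_labels_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("submitter_id", "vital_status") %in% colnames(df)))
    stop("read_labels_table: need submitter_id and vital_status columns")
  stats::setNames(as.integer(df$vital_status),
                  as.character(df$submitter_id))
}

#' Read a gene annotation table
#'
#' Columns: `gene_id`, `exon_union_length`, optional `biotype`,
#' optional `autosome` (TRUE/FALSE).
#'
#' @param path TSV path.
#' @return a [gene_annotation()].
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "exon_union_length") %in% colnames(df)))
    stop("read_annotation_table: need gene_id and exon_union_length columns")
  gene_annotation(strip_ensembl_version(df$gene_id),
                  df$exon_union_length,
                  biotype = if ("biotype" %in% colnames(df)) df$biotype
                            else "protein_coding",
                  autosome = if ("autosome" %in% colnames(df)) df$autosome
                             else TRUE)
}
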