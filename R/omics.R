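#' Construct an OmicsMatrix
#'
#' The package's basic data container: a samples x features matrix whose
#' rownames are patient submitter IDs, whose colnames are feature IDs
#' (e.g. unversioned Ensembl gene IDs), tagged with the modality the
#' values belong to.
#'
#' @param x numeric (or integer) matrix, samples in rows, features in columns.
#'   Rownames (submitter IDs) and colnames (feature IDs) are mandatory.
#' @param modality one of `"expression"`, `"cnv"`, `"clinical"`, `"fused"`.
#' @return an `OmicsMatrix` (a matrix with a `modality` attribute).
#' @export
omics_matrix <- function(x, modality = c("expression", "cnv", "clinical", "fused")) {
  modality <- match.arg(modality)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x))) stop("omics_matrix: rownames (submitter IDs) are required")
  if (is.null(colnames(x))) stop("omics_matrix: colnames (feature IDs) are required")
  if (anyDuplicated(rownames(x))) stop("omics_matrix: duplicate submitter IDs")
  if (anyDuplicated(colnames(x))) stop("omics_matrix: duplicate feature IDs")
  structure(x, modality = modality, class = c("OmicsMatrix", class(x)))
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix [%s]: %d samples x %d features\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  cat("  samples:", paste(utils::head(rownames(x), 3), collapse = ", "),
      if (nrow(x) > 3) "..." else "", "\n")
  cat("  features:", paste(utils::head(colnames(x), 3), collapse = ", "),
      if (ncol(x) > 3) "..." else "", "\n")
  invisible(x)
}

#' @export
`[.OmicsMatrix` <- function(x, i, j, ..., drop = TRUE) {
  m <- attr(x, "modality")
  out <- NextMethod()
  if (is.matrix(out)) out <- structure(out, modality = m,
                                       class = c("OmicsMatrix", class(out)))
  out
}

#' Modality tag of an OmicsMatrix
#' @param x an `OmicsMatrix`.
#' @return character scalar.
#' @export
modality <- function(x) attr(x, "modality")

# internal: strip class for plain-matrix math
as_plain <- function(x) {
  attr(x, "modality") <- NULL
  class(x) <- setdiff(class(x), "OmicsMatrix")
  x
}
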