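#' Preprocess a clinical matrix: drop sparse columns, encode missingness
#'
#' Columns whose missingness is at or above `max_missing` are dropped.
#' Remaining categorical columns (whole-numbered with few distinct
#' values, or named in `categorical_cols`) are integer-encoded
#' `0..L-1` with a dedicated extra category `L` for missing entries.
#' Numeric columns keep their values, with missing entries filled by the
#' column median and flagged in a companion `<name>::missing` indicator
#' column. No other imputation is performed.
#'
#' @param X clinical `OmicsMatrix` (numeric with `NA` for missing).
#' @param max_missing drop threshold on the per-column missing fraction,
#'   in `[0,1]`; default 0.5.
#' @param categorical_cols optional character vector forcing columns to
#'   be treated as categorical.
#' @param max_levels sniffing rule: whole-numbered columns with at most
#'   this many distinct values are treated as categorical (default 10).
#' @return an encoded clinical `OmicsMatrix` with an `encoding` attribute
#'   describing each retained column.
#' @export
preprocess_clinical <- function(X, max_missing = 0.5,
                                categorical_cols = NULL, max_levels = 10) {
  if (max_missing < 0 || max_missing > 1)
    stop("preprocess_clinical: max_missing must be in [0, 1]")
  x <- as_plain(X)
  miss_frac <- colMeans(is.na(x))
  keep <- miss_frac < max_missing
  if (!any(keep))
    stop("preprocess_clinical: every column exceeds the missingness ",
         "threshold (", max_missing, "); raise max_missing")
  x <- x[, keep, drop = FALSE]
  enc <- list()
  out_cols <- list()
  for (j in seq_len(ncol(x))) {
    nm <- colnames(x)[j]
    v <- x[, j]
    obs <- v[!is.na(v)]
    is_cat <- nm %in% categorical_cols ||
      (length(obs) > 0 && all(obs == round(obs)) &&
         length(unique(obs)) <= max_levels)
    if (is_cat) {
      lev <- sort(unique(obs))
      code <- match(v, lev) - 1L        # NA stays NA
      code[is.na(code)] <- length(lev)  # dedicated missing category
      out_cols[[nm]] <- code
      enc[[nm]] <- list(type = "categorical", levels = lev,
                        missing_code = length(lev))
    } else {
      med <- stats::median(obs)
      filled <- ifelse(is.na(v), med, v)
      out_cols[[nm]] <- filled
      enc[[nm]] <- list(type = "numeric", fill = med,
                        had_missing = anyNA(v))
      if (anyNA(v))
        out_cols[[paste0(nm, "::missing")]] <- as.integer(is.na(v))
    }
  }
  out <- do.call(cbind, out_cols)
  rownames(out) <- rownames(x)
  res <- omics_matrix(out, "clinical")
  attr(res, "encoding") <- enc
  res
}

#' Two-stage copy-number feature reduction
#'
#' Composition of a variance filter and a chi-squared filter: keep the
#' `top_var` highest-variance genes, then within those the `top_chi2`
#' genes most associated with the label. Defaults follow the customary
#' pipeline (2000, then 256). The returned selection is expressed
#' against the full input feature list, so it transfers directly to an
#' unlabelled CNV matrix.
#'
#' @param X categorical cnv `OmicsMatrix`.
#' @param y binary labels, one per row.
#' @param top_var variance-stage size (default 2000).
#' @param top_chi2 chi-squared-stage size (default 256).
#' @return a `selection_result` (method `"cnv_var_chi2"`).
#' @export
preprocess_cnv <- function(X, y, top_var = 2000, top_chi2 = 256) {
  if (top_chi2 > top_var)
    stop("preprocess_cnv: top_chi2 must not exceed top_var")
  if (top_var > ncol(X))
    stop("preprocess_cnv: top_var exceeds the number of features")
  sel_var <- variance_top_k(X, top_var)
  x_var <- apply_selection(sel_var, X)
  sel_chi <- chi2_select(x_var, y, top_chi2)
  new_selection_result("cnv_var_chi2",
                       list(top_var = top_var, top_chi2 = top_chi2),
                       sel_chi$selected_ids, colnames(X),
                       scores = sel_chi$scores)
}

#' Submitter-ID-matched early fusion of three modalities
#'
#' Keeps only patients present in all three modalities (a patient absent
#' from even one modality is discarded from the rest), orders rows by
#' sorted submitter ID, and concatenates the expression, CNV and
#' clinical blocks column-wise. Column names are prefixed by modality
#' (`expr|`, `cnv|`, `clin|`) so feature IDs shared between modalities
#' (e.g. Ensembl IDs in both expression and CNV) never collide. Values
#' are copied, never altered.
#'
#' @param expr expression `OmicsMatrix` (already feature-reduced).
#' @param cnv cnv `OmicsMatrix` (already feature-reduced).
#' @param clin encoded clinical `OmicsMatrix`.
#' @param labels optional named binary vector (by submitter ID); subset
#'   and aligned to the fused rows.
#' @param prefix prefix columns by modality (default `TRUE`; turning it
#'   off errors when feature IDs collide across blocks).
#' @return a `fused_dataset`: `matrix` (fused `OmicsMatrix`),
#'   `block_index` (data.frame: column, modality, feature_id), `labels`
#'   (or `NULL`), and `manifest` (per-modality counts and widths).
#' @export
match_and_fuse <- function(expr, cnv, clin, labels = NULL, prefix = TRUE) {
  mats <- list(expression = expr, cnv = cnv, clinical = clin)
  for (nm in names(mats))
    if (anyDuplicated(rownames(mats[[nm]])))
      stop("match_and_fuse: duplicate submitter IDs in ", nm)
  ids <- Reduce(intersect, lapply(mats, rownames))
  if (length(ids) == 0)
    stop("match_and_fuse: empty submitter-ID intersection (expression: ",
         nrow(expr), ", cnv: ", nrow(cnv), ", clinical: ", nrow(clin),
         " patients)")
  ids <- sort(ids)
  pfx <- c(expression = "expr|", cnv = "cnv|", clinical = "clin|")
  blocks <- lapply(names(mats), function(nm) {
    b <- as_plain(mats[[nm]])[ids, , drop = FALSE]
    if (prefix) colnames(b) <- paste0(pfx[[nm]], colnames(b))
    b
  })
  all_cols <- unlist(lapply(blocks, colnames))
  if (anyDuplicated(all_cols))
    stop("match_and_fuse: duplicate feature IDs across blocks: ",
         paste(utils::head(unique(all_cols[duplicated(all_cols)]), 5),
               collapse = ", "),
         "; enable prefix to namespace them")
  fused <- do.call(cbind, blocks)
  block_index <- data.frame(
    column = all_cols,
    modality = rep(names(mats), vapply(blocks, ncol, 0L)),
    feature_id = unlist(lapply(names(mats), function(nm) colnames(mats[[nm]]))),
    stringsAsFactors = FALSE)
  lab <- NULL
  if (!is.null(labels)) {
    if (is.null(names(labels)))
      stop("match_and_fuse: labels must be named by submitter ID")
    lab <- labels[ids]
    if (anyNA(lab)) stop("match_and_fuse: labels missing for fused patients")
  }
  manifest <- list(
    input_patients = as.list(vapply(mats, nrow, 0L)),
    intersection = length(ids),
    block_widths = as.list(stats::setNames(vapply(blocks, ncol, 0L),
                                           names(mats))),
    fused_shape = dim(fused))
  structure(list(matrix = omics_matrix(fused, "fused"),
                 block_index = block_index, labels = lab,
                 manifest = manifest),
            class = "fused_dataset")
}

#' @export
print.fused_dataset <- function(x, ...) {
  m <- x$manifest
  bw <- unlist(m$block_widths)
  cat(sprintf("fused_dataset: %d patients x %d features (%s)\n",
              m$fused_shape[1], m$fused_shape[2],
              paste(sprintf("%s %d", names(bw), bw), collapse = " + ")))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d deceased / %d total\n", sum(x$labels),
                length(x$labels)))
  invisible(x)
}
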