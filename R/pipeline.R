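#' Build a run configuration
#'
#' Describes one end-to-end run: where the modality tables live, which
#' workflow to execute, the feature-reduction and model settings, the
#' cross-validation scheme and the output directory. Round-trips
#' through JSON unchanged.
#'
#' @param cohort_dir directory holding `expression.tsv`, `labels.tsv`
#'   and (as the workflow needs them) `cnv.tsv`, `clinical.tsv`,
#'   `unlabelled.tsv` — the layout written by [write_cohort()].
#' @param workflow `"supervised"`, `"ssl"`, or `"multimodal"`.
#' @param selection list: `method` (`"ttest"`, `"lasso"`, `"pca"`) and
#'   its parameter (`alpha`, `inv_reg`, or `variance_target`).
#' @param model for `"supervised"`: a `family` plus hyperparameters as
#'   in [baseline_spec()]; ignored otherwise.
#' @param ssl list of [ssl_config()] overrides for the ssl/multimodal
#'   workflows.
#' @param cnv list: `top_var`, `top_chi2` (multimodal only).
#' @param clinical list: `max_missing` (multimodal only).
#' @param cv list: `k`, `stratified`.
#' @param seed integer master seed.
#' @param out_dir run output directory.
#' @return a `run_config`.
#' @export
run_config <- function(cohort_dir, workflow = c("ssl", "supervised",
                                                "multimodal"),
                       selection = list(method = "ttest", alpha = 0.01),
                       model = list(family = "logistic"),
                       ssl = list(), cnv = list(top_var = 2000,
                                                top_chi2 = 256),
                       clinical = list(max_missing = 0.5),
                       cv = list(k = 5, stratified = TRUE),
                       seed = 1L, out_dir = tempfile("tabvital_run_")) {
  workflow <- match.arg(workflow)
  structure(list(cohort_dir = cohort_dir, workflow = workflow,
                 selection = selection, model = model, ssl = ssl,
                 cnv = cnv, clinical = clinical, cv = cv,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

fit_selection <- function(X, y, selection) {
  switch(selection$method,
    ttest = ttest_select(X, y,
                         alpha = selection$alpha %||% 0.01,
                         var_equal = isTRUE(selection$var_equal)),
    lasso = lasso_select(X, y, inv_reg = selection$inv_reg %||% 0.001),
    pca = pca_fit(X, variance_target = selection$variance_target %||% 0.999),
    stop("unknown selection method: ", selection$method))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_ssl_config <- function(overrides, seed) {
  args <- overrides
  if (is.null(args$seed)) args$seed <- seed
  do.call(ssl_config, args)
}

# fill unavailable modalities of the unlabelled corpus so it can be
# fused with the same schema as the labelled data: CNV gets the most
# common labelled category per gene, clinical the dedicated missing code
fill_block <- function(template, ids, fill_values) {
  m <- matrix(rep(fill_values, each = length(ids)), length(ids),
              length(fill_values),
              dimnames = list(ids, names(fill_values)))
  m
}

#' Execute a configured workflow end-to-end
#'
#' Reads the cohort tables, fits the configured feature reduction on the
#' labelled data, runs the requested workflow (supervised baseline /
#' self-supervised pretraining plus fine-tuning / multimodal fusion with
#' self-supervision), and writes into the output directory: the echoed
#' config, the selection, the cross-validation report, the ranked
#' importance table (SSL workflows), the fusion manifest (multimodal),
#' training curves, and a log of the method decisions in force.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; the `cv_report` is also
#'   attached as attribute `"report"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  logline <- function(...) cat(..., "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("workflow: ", config$workflow, "; seed: ", config$seed)
  logline("decisions: t-test=",
          if (isTRUE(config$selection$var_equal)) "student" else "welch",
          "; uq-quantile=linear-interpolation(all protein-coding)",
          "; clinical max_missing=", config$clinical$max_missing %||% 0.5,
          "; importance-normalizer=unsquared")

  expr <- read_expression_table(file.path(config$cohort_dir,
                                          "expression.tsv"))
  labels <- read_labels_table(file.path(config$cohort_dir, "labels.tsv"))
  ids <- intersect(rownames(expr), names(labels))
  X <- expr[ids, , drop = FALSE]
  y <- labels[ids]

  stage <- "feature selection"
  out <- tryCatch({
    sel <- fit_selection(X, y, config$selection)
    jsonlite::write_json(
      list(method = sel$method, params = sel$params,
           n_selected = if (sel$method == "pca")
             ncol(sel$projection$rotation) else length(sel$selected_ids),
           selected_ids = sel$selected_ids),
      file.path(config$out_dir, "selection.json"), auto_unbox = TRUE,
      digits = NA)
    Xs <- apply_selection(sel, X)

    k <- config$cv$k %||% 5
    strat <- config$cv$stratified %||% TRUE

    if (config$workflow == "supervised") {
      stage <- "supervised training"
      spec <- do.call(baseline_spec,
                      c(config$model, list(seed = config$seed)))
      rep <- cross_validate(baseline_learner(spec), Xs, y, k = k,
                            seed = config$seed, stratified = strat)
    } else if (config$workflow == "ssl") {
      stage <- "self-supervised pretraining"
      unl <- read_expression_table(file.path(config$cohort_dir,
                                             "unlabelled.tsv"))
      Us <- apply_selection(sel, unl)
      cfg <- make_ssl_config(config$ssl, config$seed)
      pre <- pretrain(Us, cfg)
      utils::write.table(
        data.frame(epoch = seq_along(pre$history$pretrain),
                   loss = pre$history$pretrain),
        file.path(config$out_dir, "pretrain_curve.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      stage <- "fine-tuning"
      rep <- cross_validate(tabnet_learner(cfg, pre), Xs, y, k = k,
                            seed = config$seed, stratified = strat)
      stage <- "interpretability"
      final <- finetune(pre, Xs, y, cfg)
      iv <- tabnet_explain(final, Xs)
      export_importances(iv, path = file.path(config$out_dir,
                                              "importances.tsv"))
    } else {
      stage <- "multimodal preprocessing"
      cnv <- read_cnv_table(file.path(config$cohort_dir, "cnv.tsv"))
      clin <- read_clinical_table(file.path(config$cohort_dir,
                                            "clinical.tsv"))
      cnv_sel <- preprocess_cnv(
        cnv[intersect(rownames(cnv), names(labels)), , drop = FALSE],
        labels[intersect(rownames(cnv), names(labels))],
        top_var = min(config$cnv$top_var %||% 2000, ncol(cnv)),
        top_chi2 = min(config$cnv$top_chi2 %||% 256, ncol(cnv)))
      clin_enc <- preprocess_clinical(
        clin, max_missing = config$clinical$max_missing %||% 0.5)
      stage <- "fusion"
      fused <- match_and_fuse(apply_selection(sel, expr),
                              apply_selection(cnv_sel, cnv),
                              clin_enc, labels = labels)
      jsonlite::write_json(fused$manifest,
                           file.path(config$out_dir,
                                     "fusion_manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stage <- "self-supervised pretraining"
      unl <- read_expression_table(file.path(config$cohort_dir,
                                             "unlabelled.tsv"))
      Us <- apply_selection(sel, unl)
      # unlabelled CNV/clinical blocks are unavailable in the corpus:
      # fill with the labelled modal category / the missing code
      cnv_block <- as_plain(apply_selection(cnv_sel, cnv))
      cnv_fill <- apply(cnv_block, 2,
                        function(v) as.numeric(names(which.max(table(v)))))
      clin_fill <- vapply(seq_len(ncol(clin_enc)), function(j) {
        e <- attr(clin_enc, "encoding")[[colnames(clin_enc)[j]]]
        if (!is.null(e) && e$type == "categorical") e$missing_code
        else if (!is.null(e)) e$fill else 0
      }, 0)
      names(clin_fill) <- colnames(clin_enc)
      ufused <- cbind(as_plain(Us),
                      fill_block(NULL, rownames(Us), cnv_fill),
                      fill_block(NULL, rownames(Us), clin_fill))
      colnames(ufused) <- colnames(fused$matrix)
      cfg <- make_ssl_config(config$ssl, config$seed)
      pre <- pretrain(omics_matrix(ufused, "fused"), cfg)
      stage <- "fine-tuning"
      rep <- cross_validate(tabnet_learner(cfg, pre), fused$matrix,
                            fused$labels, k = k, seed = config$seed,
                            stratified = strat)
      stage <- "interpretability"
      final <- finetune(pre, fused$matrix, fused$labels, cfg)
      iv <- tabnet_explain(final, fused$matrix)
      export_importances(iv, path = file.path(config$out_dir,
                                              "importances.tsv"))
    }
    rep
  }, error = function(e) {
    logline("ERROR at stage [", stage, "]: ", conditionMessage(e))
    stop("run_pipeline failed at stage [", stage, "]: ",
         conditionMessage(e), call. = FALSE)
  })

  jsonlite::write_json(
    list(fold_scores = out$fold_scores, mean = out$mean, sd = out$sd,
         label = out$label, seed = out$seed,
         config_hash = out$config_hash),
    file.path(config$out_dir, "cv_report.json"), auto_unbox = TRUE,
    digits = NA)
  cfg_echo <- unclass(config)
  jsonlite::write_json(cfg_echo, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  logline(sprintf("ROC-AUC: %.4f +/- %.4f (%s)", out$mean, out$sd,
                  out$label))
  attr(config$out_dir, "report") <- out
  invisible(config$out_dir)
}
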