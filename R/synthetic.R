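#' Configuration for the synthetic multi-omic cohort generator
#'
#' Parameterizes a simulated cohort that mirrors the structure of a
#' TCGA-style vital-status study: a labelled cohort with a ~23% deceased
#' class, an unlabelled corpus roughly ten times larger drawn from a
#' related (jittered) distribution, a minority of genes carrying class
#' signal, per-gene categorical copy-number states, and clinical columns
#' with heavy missingness. Submitter IDs link the modalities, and each
#' modality independently loses a fraction of patients so that the
#' intersection-only fusion rule is exercised.
#'
#' @param n_labelled labelled cohort size (default 445).
#' @param n_unlabelled unlabelled corpus size (default 4450, ~10x labelled).
#' @param n_genes number of expression features simulated (default 2000).
#' @param n_informative number of genes carrying class signal (default 50).
#' @param effect_size standardized mean shift, on the log-expression scale,
#'   of informative genes in the deceased class (default 1).
#' @param positive_rate fraction of deceased patients (default 101/445).
#' @param n_cnv_genes number of copy-number features (default 3000).
#' @param n_cnv_states number of integer copy-number categories (default 5,
#'   i.e. codes 0..4 standing for deep loss .. high gain).
#' @param n_cnv_informative copy-number genes whose category distribution
#'   depends on the label (default 20).
#' @param n_clinical_cols number of clinical columns (default 10).
#' @param missing_rate_range range of per-column clinical missingness;
#'   column rates are spread evenly across it so both retained and dropped
#'   columns always exist at moderate thresholds (default c(0.05, 0.95)).
#' @param modality_dropout fraction of patients independently absent from
#'   each modality (default 0.05).
#' @param corpus_jitter_sd sd of the per-gene location jitter applied to
#'   the unlabelled corpus, emulating related-but-different tumour types
#'   (default 0.2).
#' @param seed integer seed; identical configuration implies a
#'   bit-identical cohort.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_labelled = 445L,
                             n_unlabelled = 4450L,
                             n_genes = 2000L,
                             n_informative = 50L,
                             effect_size = 1,
                             positive_rate = 101 / 445,
                             n_cnv_genes = 3000L,
                             n_cnv_states = 5L,
                             n_cnv_informative = 20L,
                             n_clinical_cols = 10L,
                             missing_rate_range = c(0.05, 0.95),
                             modality_dropout = 0.05,
                             corpus_jitter_sd = 0.2,
                             seed = 1L) {
  cfg <- list(n_labelled = as.integer(n_labelled),
              n_unlabelled = as.integer(n_unlabelled),
              n_genes = as.integer(n_genes),
              n_informative = as.integer(n_informative),
              effect_size = effect_size,
              positive_rate = positive_rate,
              n_cnv_genes = as.integer(n_cnv_genes),
              n_cnv_states = as.integer(n_cnv_states),
              n_cnv_informative = as.integer(n_cnv_informative),
              n_clinical_cols = as.integer(n_clinical_cols),
              missing_rate_range = as.numeric(missing_rate_range),
              modality_dropout = modality_dropout,
              corpus_jitter_sd = corpus_jitter_sd,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  counts <- c("n_labelled", "n_unlabelled", "n_genes", "n_informative",
              "n_cnv_genes", "n_cnv_states", "n_clinical_cols")
  for (f in counts)
    if (cfg[[f]] <= 0) stop("synthetic_config: ", f, " must be > 0")
  if (cfg$n_informative > cfg$n_genes)
    stop("synthetic_config: n_informative must not exceed n_genes")
  if (cfg$effect_size < 0)
    stop("synthetic_config: effect_size must be non-negative")
  if (cfg$positive_rate <= 0 || cfg$positive_rate >= 1)
    stop("synthetic_config: positive_rate must lie in (0, 1)")
  if (cfg$n_cnv_states < 2)
    stop("synthetic_config: n_cnv_states must be at least 2")
  if (any(cfg$missing_rate_range < 0) || any(cfg$missing_rate_range > 1))
    stop("synthetic_config: missing_rate_range must lie within [0, 1]")
  if (cfg$modality_dropout >= 1 || cfg$modality_dropout < 0)
    stop("synthetic_config: modality_dropout must lie in [0, 1)")
  invisible(cfg)
}

# Per-gene log-normal parameters and informative-gene identities are derived
# once from the seed so labelled and unlabelled data share them.
derive_gene_params <- function(config) {
  set.seed(config$seed)
  g <- config$n_genes
  ids <- sprintf("ENSG%011d", seq_len(g))
  meanlog <- stats::rnorm(g, mean = 3, sd = 2)
  sdlog <- stats::runif(g, 0.3, 0.8)
  informative <- sort(sample.int(g, config$n_informative))
  list(ids = ids, meanlog = meanlog, sdlog = sdlog, informative = informative)
}

#' Simulate an expression matrix with planted class signal
#'
#' Per-gene log-normal marginals mimic the positive skew of FPKM-UQ
#' values. Informative genes have their log-values shifted upward by
#' `effect_size` standard deviations in the deceased class; all other
#' genes are identically distributed across classes.
#'
#' @param config a [synthetic_config()].
#' @param labels binary vector (0 survived / 1 deceased) of length
#'   `n_labelled`.
#' @return an expression `OmicsMatrix` with a `truth` attribute listing
#'   the informative gene IDs and the planted log-scale shift.
#' @export
generate_expression <- function(config, labels) {
  validate_synthetic_config(config)
  if (length(labels) != config$n_labelled)
    stop("generate_expression: labels must have length n_labelled")
  gp <- derive_gene_params(config)
  set.seed(config$seed + 1L)
  n <- config$n_labelled
  g <- config$n_genes
  z <- matrix(stats::rnorm(n * g), n, g)
  logx <- sweep(sweep(z, 2, gp$sdlog, `*`), 2, gp$meanlog, `+`)
  if (config$n_informative > 0 && config$effect_size > 0) {
    shift <- outer(labels == 1, config$effect_size * gp$sdlog[gp$informative])
    logx[, gp$informative] <- logx[, gp$informative] + shift
  }
  x <- exp(logx)
  dimnames(x) <- list(sprintf("PT-%06d", seq_len(n)), gp$ids)
  out <- omics_matrix(x, "expression")
  attr(out, "truth") <- list(informative = gp$ids[gp$informative],
                             effect_size = config$effect_size)
  out
}

#' Simulate a categorical copy-number matrix
#'
#' Integer categories `0 .. n_cnv_states-1` per gene. A subset of
#' `n_cnv_informative` genes has a label-conditional category
#' distribution; the rest are independent of the label. Per-gene baseline
#' distributions vary so a variance filter is meaningful.
#'
#' @inheritParams generate_expression
#' @return a cnv `OmicsMatrix` (integer categories) with a `truth`
#'   attribute naming the label-dependent genes.
#' @export
generate_cnv <- function(config, labels) {
  validate_synthetic_config(config)
  if (length(labels) != config$n_labelled)
    stop("generate_cnv: labels must have length n_labelled")
  set.seed(config$seed + 2L)
  n <- config$n_labelled
  g <- config$n_cnv_genes
  k <- config$n_cnv_states
  ids <- sprintf("CNVG%07d", seq_len(g))
  # per-gene baseline: concentration around the neutral middle category,
  # with gene-specific spread so per-gene variance differs
  spread <- stats::runif(g, 0.1, 2)
  mid <- (k - 1) / 2
  base_probs <- vapply(seq_len(g), function(j) {
    w <- exp(-abs(seq_len(k) - 1 - mid) / spread[j])
    w / sum(w)
  }, numeric(k))                      # k x g
  x <- matrix(0L, n, g, dimnames = list(sprintf("PT-%06d", seq_len(n)), ids))
  for (j in seq_len(g))
    x[, j] <- sample.int(k, n, replace = TRUE, prob = base_probs[, j]) - 1L
  n_inf <- min(config$n_cnv_informative, g)
  inf_idx <- sort(sample.int(g, n_inf))
  if (n_inf > 0) {
    pos <- labels == 1
    for (j in inf_idx) {
      # deceased class skewed towards the top category
      w <- exp(0.9 * (seq_len(k) - 1))
      x[pos, j] <- sample.int(k, sum(pos), replace = TRUE, prob = w / sum(w)) - 1L
    }
  }
  out <- omics_matrix(x, "cnv")
  attr(out, "truth") <- list(informative = ids[inf_idx])
  out
}

#' Simulate a clinical attribute matrix with heavy missingness
#'
#' Alternating categorical (small integer codes) and numeric columns.
#' Per-column missingness rates are spread evenly across
#' `missing_rate_range`, so at moderate retention thresholds some columns
#' are always dropped and some always survive. Missing cells are `NA`.
#'
#' @param config a [synthetic_config()].
#' @return a clinical `OmicsMatrix` (numeric with `NA`s).
#' @export
generate_clinical <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed + 3L)
  n <- config$n_labelled
  p <- config$n_clinical_cols
  rng <- sort(config$missing_rate_range)
  rates <- if (p == 1) mean(rng) else seq(rng[1], rng[2], length.out = p)
  x <- matrix(NA_real_, n, p,
              dimnames = list(sprintf("PT-%06d", seq_len(n)),
                              sprintf("clin_%02d", seq_len(p))))
  for (j in seq_len(p)) {
    if (j %% 2 == 1) {
      nlev <- sample(2:5, 1)
      x[, j] <- sample.int(nlev, n, replace = TRUE) - 1
    } else {
      x[, j] <- round(stats::rnorm(n, mean = 60, sd = 12), 1)  # age-like
    }
    miss <- stats::runif(n) < rates[j]
    x[miss, j] <- NA_real_
  }
  omics_matrix(x, "clinical")
}

#' Generate a linked labelled/unlabelled multi-omic cohort
#'
#' Produces the three labelled modalities sharing a master submitter-ID
#' list (with independent per-modality patient dropout), binary vital
#' status for the labelled cohort, and an unlabelled expression corpus
#' drawn from the same per-gene distributions with per-gene location
#' jitter and the same latent class mixture — emulating a related corpus
#' of adenomas and adenocarcinomas.
#'
#' @param config a [synthetic_config()].
#' @return a `multi_omic_cohort` list with elements `expression`, `cnv`,
#'   `clinical`, `unlabelled`, `labels` (named by submitter ID), and
#'   `truth` (planted informative features per modality).
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_labelled
  set.seed(config$seed + 4L)
  n_pos <- max(1L, round(config$positive_rate * n))
  labels <- integer(n)
  labels[sample.int(n, n_pos)] <- 1L
  ids <- sprintf("PT-%06d", seq_len(n))
  names(labels) <- ids

  expr <- generate_expression(config, labels)
  cnv <- generate_cnv(config, labels)
  clin <- generate_clinical(config)

  # unlabelled corpus: same gene params, jittered locations, latent mixture
  gp <- derive_gene_params(config)
  set.seed(config$seed + 5L)
  m <- config$n_unlabelled
  jitter <- stats::rnorm(config$n_genes, 0, config$corpus_jitter_sd)
  z <- matrix(stats::rnorm(m * config$n_genes), m, config$n_genes)
  logx <- sweep(sweep(z, 2, gp$sdlog, `*`), 2, gp$meanlog + jitter, `+`)
  latent <- stats::runif(m) < config$positive_rate
  if (config$n_informative > 0 && config$effect_size > 0) {
    shift <- outer(latent, config$effect_size * gp$sdlog[gp$informative])
    logx[, gp$informative] <- logx[, gp$informative] + shift
  }
  unl <- exp(logx)
  dimnames(unl) <- list(sprintf("UN-%06d", seq_len(m)), gp$ids)
  unl <- omics_matrix(unl, "expression")

  truth <- list(expression = attr(expr, "truth")$informative,
                cnv = attr(cnv, "truth")$informative,
                effect_size = config$effect_size)

  # independent per-modality dropout
  set.seed(config$seed + 6L)
  keep <- function(x) {
    if (config$modality_dropout == 0) return(x)
    kept <- stats::runif(nrow(x)) >= config$modality_dropout
    x[kept, , drop = FALSE]
  }
  expr <- keep(expr); cnv <- keep(cnv); clin <- keep(clin)

  structure(list(expression = expr, cnv = cnv, clinical = clin,
                 unlabelled = unl, labels = labels,
                 truth = truth,
                 config = config),
            class = "multi_omic_cohort")
}

#' @export
print.multi_omic_cohort <- function(x, ...) {
  cat("multi_omic_cohort\n")
  cat(sprintf("  labelled: %d patients (%d deceased), %d genes\n",
              length(x$labels), sum(x$labels), ncol(x$expression)))
  cat(sprintf("  modalities present: expression %d, cnv %d, clinical %d patients\n",
              nrow(x$expression), nrow(x$cnv), nrow(x$clinical)))
  cat(sprintf("  unlabelled corpus: %d samples\n", nrow(x$unlabelled)))
  invisible(x)
}

#' Write a cohort to tab-separated files
#'
#' One TSV per modality (first column `submitter_id`, header row of
#' feature IDs), a labels TSV, and a JSON truth sidecar; the files match
#' the readers in the pipeline I/O layer.
#'
#' @param cohort a `multi_omic_cohort`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in c("expression", "cnv", "clinical"))
    write_omics_table(cohort[[m]], file.path(dir, paste0(m, ".tsv")))
  write_omics_table(cohort$unlabelled, file.path(dir, "unlabelled.tsv"))
  lab <- data.frame(submitter_id = names(cohort$labels),
                    vital_status = cohort$labels)
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
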