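#' Principal-component coordinates of samples
#'
#' Centered singular-value decomposition scores of the samples. Missing
#' entries are imputed to the gene mean first (logged via a message).
#'
#' @param m an [expr_matrix].
#' @param n_components number of components, at most `min(n_genes, n_samples)`.
#' @return samples x components score matrix with attribute
#'   `variance_explained` (non-increasing fractions).
#' @export
pca_coordinates <- function(m, n_components = 2) {
  vals <- m$values
  if (n_components > min(dim(vals)))
    stop("n_components exceeds min(n_genes, n_samples)")
  if (any(!m$available)) {
    message("pca_coordinates: imputing ", sum(!m$available),
            " missing entries to gene means")
    gm <- rowMeans(vals, na.rm = TRUE)
    gm[is.nan(gm)] <- 0
    vals[!m$available] <- gm[row(vals)[!m$available]]
  }
  x <- t(vals)                      # samples x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(sample_ids(m), paste0("PC", seq_len(n_components)))
  attr(scores, "variance_explained") <- sv$d[seq_len(n_components)]^2 /
    sum(sv$d^2)
  scores
}

#' Pipeline configuration
#'
#' Validates the end-to-end run configuration. Inputs may be file paths
#' (GCT/TSV as written by this package) or in-memory objects.
#'
#' @param expression an [expr_matrix] or GCT path.
#' @param survival a [surv_table] or TSV path.
#' @param clinical optional clinical covariate data.frame or TSV path (columns
#'   sample_id plus numeric covariates).
#' @param gmt optional `geneset_collection` or GMT path (required when
#'   `level = "geneset"`).
#' @param min_avail availability-filter threshold.
#' @param batch_method `"mean_shift"`, `"dwd"` or `"none"`.
#' @param subset `"all"` or `"late"` (restrict to the late-recurrence
#'   sub-cohort before prediction).
#' @param cutoff_months late-recurrence cutoff.
#' @param k_values signature sizes to sweep.
#' @param k_max signature size cap (at most 200).
#' @param level `"gene"` or `"geneset"`.
#' @param set_method set-score construction for the gene-set level.
#' @param seed integer seed recorded with the run.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, survival, clinical = NULL, gmt = NULL,
                            min_avail = 0.7, batch_method = "mean_shift",
                            subset = c("all", "late"), cutoff_months = 12,
                            k_values = c(2:30, seq(35, 150, by = 5)),
                            k_max = 200, level = c("gene", "geneset"),
                            set_method = "mean_z", seed = 1) {
  subset <- match.arg(subset)
  level <- match.arg(level)
  if (!batch_method %in% c("mean_shift", "dwd", "none"))
    stop("batch_method must be one of mean_shift, dwd, none")
  if (k_max > 200) stop("k_max must not exceed 200")
  if (level == "geneset" && is.null(gmt))
    stop("level = 'geneset' requires a gene-set collection (gmt)")
  for (p in list(expression, survival, clinical, gmt))
    if (is.character(p) && !file.exists(p)) stop("input path not found: ", p)
  structure(list(expression = expression, survival = survival,
                 clinical = clinical, gmt = gmt, min_avail = min_avail,
                 batch_method = batch_method, subset = subset,
                 cutoff_months = cutoff_months, k_values = k_values,
                 k_max = k_max, level = level, set_method = set_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full signature-discovery pipeline
#'
#' Stages: load inputs, availability filter, inter-batch adjustment, optional
#' late-recurrence subsetting, LOOCV nearest-template sweep over signature
#' sizes, Kaplan-Meier curves of the predicted classes, univariable Cox risk
#' ratios for the signature label and any clinical covariates, PCA
#' coordinates, and a heat-map-ready matrix (samples ordered by cosine
#' distance to the poor template, markers by Cox score). Every stage appends
#' a JSON record to `log.jsonl`; `config.json` snapshots the configuration;
#' the run is deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; overwritten if present).
#' @return the output directory path, invisibly; artifacts are files.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  set.seed(config$seed)

  m <- if (is.character(config$expression)) read_gct(config$expression)
       else config$expression
  surv <- if (is.character(config$survival)) read_surv_tsv(config$survival)
          else config$survival
  clinical <- if (is.character(config$clinical))
    utils::read.delim(config$clinical, stringsAsFactors = FALSE)
  else config$clinical
  gs <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
  log_stage("load", n_genes = nrow(m$values), n_samples = ncol(m$values))

  m <- availability_filter(m, config$min_avail)
  log_stage("availability_filter", min_avail = config$min_avail,
            n_genes = nrow(m$values))

  if (config$batch_method != "none" && nlevels(m$batch) > 1) {
    m <- batch_adjust(m, config$batch_method)
    log_stage("batch_adjust", method = config$batch_method,
              order = levels(m$batch))
  }

  surv <- align_surv(m, surv)
  if (config$subset == "late") {
    surv <- late_recurrence_subset(surv, config$cutoff_months)
    m <- m[, surv$sample_id]
    log_stage("late_recurrence_subset", cutoff_months = config$cutoff_months,
              n_samples = nrow(surv))
  }
  write_gct(m, file.path(out_dir, "filtered_expression.gct"))

  cv <- if (config$level == "gene")
    sweep_signature_size(m, surv, config$k_values, config$k_max)
  else
    geneset_predict(m, surv, gs, config$k_values, config$set_method,
                    config$k_max)
  utils::write.table(cv$sweep, file.path(out_dir, "sweep.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = surv$sample_id,
                                label = cv$chosen_labels),
                     file.path(out_dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("sweep", chosen_k = cv$chosen_k,
            logrank_p = cv$sweep$logrank_p[cv$sweep$k == cv$chosen_k],
            error_rate = cv$sweep$error_rate[cv$sweep$k == cv$chosen_k])

  # KM curves of the predicted classes
  for (lab in c("poor", "good")) {
    sub <- surv[cv$chosen_labels == lab, , drop = FALSE]
    km <- if (nrow(sub)) kaplan_meier(sub) else
      data.frame(time = numeric(0), n_risk = numeric(0), n_event = numeric(0),
                 n_censor = numeric(0), survival = numeric(0))
    utils::write.table(km, file.path(out_dir, paste0("km_", lab, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # univariable Cox risk ratios: signature label, then clinical covariates
  fits <- list()
  if (length(unique(cv$chosen_labels)) == 2) {
    sig <- as.numeric(cv$chosen_labels == "poor")
    fits$signature <- cox_fit(matrix(sig, ncol = 1,
                                     dimnames = list(NULL, "rfs_signature")),
                              surv)
  }
  if (!is.null(clinical)) {
    cc <- clinical[match(surv$sample_id, clinical$sample_id), , drop = FALSE]
    for (v in setdiff(names(cc), c("sample_id", "batch"))) {
      if (!is.numeric(cc[[v]])) next
      fits[[v]] <- tryCatch(
        cox_fit(matrix(cc[[v]], ncol = 1, dimnames = list(NULL, v)), surv),
        error = function(e) NULL)
    }
    fits <- Filter(Negate(is.null), fits)
  }
  if (length(fits))
    write_cox_table(fits, file.path(out_dir, "cox_univariable.tsv"))
  log_stage("cox_fits", variables = names(fits))

  # heat-map-ready matrix: full-cohort ranking for display only
  scores_full <- rank_features(m, surv)
  tmpl <- build_template(scores_full, min(cv$chosen_k,
                                          sum(!scores_full$degenerate)))
  z <- gene_zscores(m)
  dist_poor <- vapply(seq_len(ncol(m$values)), function(j)
    ntp_classify(z[tmpl$marker_ids, j], tmpl)$distance, 0)
  ord <- order(dist_poor)
  heat <- z[tmpl$marker_ids, ord, drop = FALSE]
  utils::write.table(
    data.frame(gene_id = rownames(heat), heat, check.names = FALSE),
    file.path(out_dir, "heatmap_matrix.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(sprintf("%s\t%+d", tmpl$marker_ids, tmpl$signs),
             file.path(out_dir, "signature_genes.txt"))

  pca <- pca_coordinates(m, n_components = min(3, min(dim(m$values))))
  utils::write.table(data.frame(sample_id = rownames(pca), pca),
                     file.path(out_dir, "pca.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("pca", variance_explained =
              round(attr(pca, "variance_explained"), 4))

  snap <- config
  for (nm in c("expression", "survival", "clinical", "gmt"))
    if (!is.character(snap[[nm]]) && !is.null(snap[[nm]]))
      snap[[nm]] <- paste0("<in-memory ", class(snap[[nm]])[1], ">")
  jsonlite::write_json(unclass(snap), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  log_stage("done")
  invisible(out_dir)
}
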