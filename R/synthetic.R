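#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate a two-color microarray resection cohort: ~25,000
#' transcripts on 44 subjects hybridized in a small number of batches, a
#' planted prognostic signature whose expression drives an exponential
#' recurrence hazard, uniform administrative censoring calibrated to a target
#' censored fraction, probe-level missingness, and ordinal clinical covariates
#' (tumor stage, diameter, tumor count) positively correlated with the hazard.
#'
#' @param n_samples number of subjects.
#' @param n_genes number of transcripts.
#' @param n_signature_genes number of planted prognostic genes.
#' @param beta_signature per-gene log-hazard coefficients for the planted
#'   genes; a scalar is recycled with alternating signs (half risk-increasing,
#'   half protective).
#' @param rho_signature intra-module correlation of the planted genes in
#'   `[0, 1)`: the signature is a co-expressed module sharing a latent factor
#'   (sign-aligned), each gene keeping a standard normal marginal. 0 plants
#'   mutually independent genes.
#' @param baseline_hazard baseline recurrence hazard, events per month.
#' @param censor_rate target censored fraction in `[0, 1]`; the horizon of the
#'   uniform censoring distribution is solved numerically so the expected
#'   censored fraction matches.
#' @param n_batches number of hybridization batches.
#' @param batch_shift_sd SD (log2 units) of the per-gene additive batch shift.
#' @param missing_rate probability that an entry is unavailable.
#' @param dye_bias_amplitude amplitude (log2 units) of the smooth
#'   intensity-dependent dye bias used by [generate_two_channel()].
#' @param seed integer seed; fully determines the cohort.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 44, n_genes = 25000,
                             n_signature_genes = 20, beta_signature = 1,
                             rho_signature = 0.5,
                             baseline_hazard = 0.03, censor_rate = 0.3,
                             n_batches = 2, batch_shift_sd = 0.3,
                             missing_rate = 0.05, dye_bias_amplitude = 0.5,
                             seed = 1) {
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
      stop(sprintf("invalid `%s`: must be an integer >= %d", nm, min))
  }
  chk_frac <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("invalid `%s`: must be a fraction in [0, 1]", nm))
  }
  chk_count(n_samples, "n_samples", 2)
  chk_count(n_genes, "n_genes")
  chk_count(n_signature_genes, "n_signature_genes", 0)
  if (n_signature_genes > n_genes)
    stop("invalid `n_signature_genes`: exceeds `n_genes`")
  chk_frac(censor_rate, "censor_rate")
  chk_frac(missing_rate, "missing_rate")
  chk_count(n_batches, "n_batches")
  if (n_batches > n_samples %/% 2)
    stop("invalid `n_batches`: need at least 2 samples per batch")
  if (!is.numeric(beta_signature) ||
      !(length(beta_signature) %in% c(1L, n_signature_genes)) ||
      any(!is.finite(beta_signature)))
    stop("invalid `beta_signature`: scalar or one finite value per signature gene")
  if (length(rho_signature) != 1 || !is.finite(rho_signature) ||
      rho_signature < 0 || rho_signature >= 1)
    stop("invalid `rho_signature`: must be in [0, 1)")
  if (length(baseline_hazard) != 1 || !is.finite(baseline_hazard) ||
      baseline_hazard <= 0)
    stop("invalid `baseline_hazard`: must be > 0")
  if (length(batch_shift_sd) != 1 || !is.finite(batch_shift_sd) ||
      batch_shift_sd < 0)
    stop("invalid `batch_shift_sd`: must be >= 0")
  if (length(dye_bias_amplitude) != 1 || !is.finite(dye_bias_amplitude) ||
      dye_bias_amplitude < 0)
    stop("invalid `dye_bias_amplitude`: must be >= 0")
  chk_count(seed, "seed", 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_signature_genes = as.integer(n_signature_genes),
                 beta_signature = beta_signature,
                 rho_signature = rho_signature,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 n_batches = as.integer(n_batches),
                 batch_shift_sd = batch_shift_sd,
                 missing_rate = missing_rate,
                 dye_bias_amplitude = dye_bias_amplitude,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# expand a scalar beta into an alternating-sign vector
expand_beta <- function(config) {
  k <- config$n_signature_genes
  b <- config$beta_signature
  if (k == 0) return(numeric(0))
  if (length(b) == 1) b <- b * rep_len(c(1, -1), k)
  b
}

# solve the uniform-censoring horizon tau so that the expected censored
# fraction over the realized hazards equals the target rate.
# P(censored | lambda) = (1 - exp(-lambda * tau)) / (lambda * tau)
solve_censor_horizon <- function(lambda, target) {
  if (target <= 0) return(NULL)     # no censoring
  expected <- function(log_tau) {
    lt <- lambda * exp(log_tau)
    mean((1 - exp(-lt)) / lt) - target
  }
  exp(stats::uniroot(expected, lower = -20, upper = 20, tol = 1e-10)$root)
}

#' Generate a synthetic cohort with a planted survival signature
#'
#' Expression is standard normal per gene plus per-batch additive shifts;
#' recurrence times are exponential with per-sample hazard
#' `baseline_hazard * exp(sum(beta_g * x_gs))` over the planted genes;
#' censoring is uniform administrative with a horizon calibrated to the target
#' censored fraction; an availability mask drops entries at `missing_rate`;
#' ordinal clinical covariates are noisy monotone functions of the linear
#' predictor.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `synthetic_cohort` with elements `expression`
#'   ([expr_matrix]), `survival` ([surv_table]), `clinical` (data.frame with
#'   stage, diameter_cm, n_tumors, batch), and `truth` (data.frame of planted
#'   gene ids with their log-hazard coefficients and signs).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  set.seed(config$seed)
  n <- config$n_samples; g <- config$n_genes
  genes <- sprintf("g%05d", seq_len(g))
  samples <- sprintf("s%03d", seq_len(n))

  x <- matrix(stats::rnorm(g * n), g, n, dimnames = list(genes, samples))
  batch <- rep_len(sprintf("batch%d", seq_len(config$n_batches)), n)
  batch <- sort(batch)
  if (config$batch_shift_sd > 0) {
    shift <- matrix(stats::rnorm(g * config$n_batches,
                                 sd = config$batch_shift_sd),
                    g, config$n_batches)
    x <- x + shift[, match(batch, sort(unique(batch)))]
  }

  beta <- expand_beta(config)
  sig_idx <- if (config$n_signature_genes > 0)
    sort(sample.int(g, config$n_signature_genes)) else integer(0)
  if (length(sig_idx) && config$rho_signature > 0) {
    # co-expressed signature module: shared latent factor, sign-aligned,
    # marginals remain N(0,1); batch shifts were added above and are kept
    f <- stats::rnorm(n)
    s <- ifelse(beta >= 0, 1, -1)
    raw <- x[sig_idx, , drop = FALSE] -
      if (config$batch_shift_sd > 0)
        shift[sig_idx, match(batch, sort(unique(batch))), drop = FALSE]
      else 0
    x[sig_idx, ] <- sqrt(config$rho_signature) * outer(s, f) +
      sqrt(1 - config$rho_signature) * raw +
      (x[sig_idx, , drop = FALSE] - raw)
  }
  eta <- if (length(sig_idx))
    as.numeric(crossprod(x[sig_idx, , drop = FALSE], beta)) else rep(0, n)
  lambda <- config$baseline_hazard * exp(eta)

  t_event <- stats::rexp(n, rate = lambda)
  tau <- solve_censor_horizon(lambda, config$censor_rate)
  if (is.null(tau)) {
    time <- t_event; event <- rep(1, n)
  } else {
    t_cens <- stats::runif(n, 0, tau)
    event <- as.numeric(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  }
  time <- pmax(time, 1e-6)

  available <- matrix(stats::runif(g * n) >= config$missing_rate, g, n)
  xm <- x; xm[!available] <- NA_real_

  z_eta <- if (stats::sd(eta) > 0) as.numeric(scale(eta)) else rep(0, n)
  stage_lat <- 0.8 * z_eta + 0.6 * stats::rnorm(n)
  stage <- as.integer(cut(stage_lat,
                          breaks = c(-Inf, stats::quantile(stage_lat,
                                                           c(0.2, 0.72, 0.97)),
                                     Inf)))
  diameter <- pmax(0.5, 2.9 + 1.3 * (0.6 * z_eta + 0.8 * stats::rnorm(n)))
  n_tumors <- 1L + stats::rbinom(n, 3, stats::plogis(-2 + 0.8 * z_eta))

  structure(list(
    expression = expr_matrix(xm, available, batch),
    survival = surv_table(samples, time, event),
    clinical = data.frame(sample_id = samples, stage = stage,
                          diameter_cm = round(diameter, 2),
                          n_tumors = n_tumors, batch = batch,
                          stringsAsFactors = FALSE),
    truth = data.frame(gene_id = genes[sig_idx], beta = beta,
                       sign = sign(beta), stringsAsFactors = FALSE),
    config = config), class = "synthetic_cohort")
}

#' Generate raw two-channel scans for a synthetic cohort
#'
#' Per-probe Cy5/Cy3 intensities whose log2 ratio equals the cohort expression
#' plus a smooth function of the mean log2 intensity `A`, with amplitude
#' `dye_bias_amplitude`. Probes whose intensity exceeds the saturation
#' threshold or falls below the limit of quantification are flagged.
#'
#' @param config a [synthetic_config()].
#' @param cohort optionally a cohort already produced by [generate_cohort()]
#'   with the same config (avoids regenerating it).
#' @param saturation log2-intensity saturation threshold (default 15.5, i.e.
#'   near the 16-bit scanner ceiling).
#' @param loq log2-intensity lower limit of quantification (default 4).
#' @return a list of class `two_color_scan`: a long data.frame `probes` with
#'   columns probe_id, sample_id, batch_id, cy5, cy3, saturated, below_loq,
#'   plus the originating `cohort`.
#' @export
generate_two_channel <- function(config, cohort = NULL, saturation = 15.5,
                                 loq = 4) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  if (is.null(cohort)) cohort <- generate_cohort(config)
  m <- cohort$expression
  g <- nrow(m$values); n <- ncol(m$values)
  set.seed(config$seed + 104729L)  # independent stream from the cohort draw
  a <- matrix(stats::runif(g * n, 6.5, 13.5), g, n)
  bias <- config$dye_bias_amplitude * sin((a - 10) / 1.5)
  x <- m$values
  x[!m$available] <- 0  # flagged entries still need finite intensities
  mm <- x + bias
  log_cy5 <- a + mm / 2
  log_cy3 <- a - mm / 2
  saturated <- log_cy5 > saturation | log_cy3 > saturation
  below_loq <- log_cy5 < loq | log_cy3 < loq
  # carry the cohort's missingness as below-LOQ flags so the scan reproduces
  # the cohort availability mask after log_ratio()
  below_loq <- below_loq | !m$available
  probes <- data.frame(
    probe_id = rep(gene_ids(m), times = n),
    sample_id = rep(sample_ids(m), each = g),
    batch_id = rep(as.character(m$batch), each = g),
    cy5 = as.numeric(2 ^ log_cy5),
    cy3 = as.numeric(2 ^ log_cy3),
    saturated = as.logical(saturated),
    below_loq = as.logical(below_loq),
    stringsAsFactors = FALSE)
  structure(list(probes = probes, cohort = cohort),
            class = "two_color_scan")
}

#' Write a synthetic cohort to disk
#'
#' Exports the expression matrix (TSV and GCT v1.2), the survival and clinical
#' tables (TSV) and the planted-truth gene list (plain text).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expr_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write_gct(cohort$expression, file.path(dir, "expression.gct"))
  write_surv_tsv(cohort$survival, file.path(dir, "survival.tsv"))
  clin <- merge(cohort$clinical,
                data.frame(sample_id = cohort$survival$sample_id,
                           time_months = cohort$survival$time,
                           event = cohort$survival$event),
                by = "sample_id")
  utils::write.table(clin, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\t%+d", cohort$truth$gene_id, cohort$truth$sign),
             file.path(dir, "truth_signature.txt"))
  invisible(dir)
}
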