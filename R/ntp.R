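#' Build a signed marker template from ranked Cox scores
#'
#' Takes the top-k features by absolute Cox score; the template sign of each
#' marker is the sign of its score, so the template is the prototype of the
#' poor-prognosis profile (positive score = higher expression with earlier
#' recurrence). The good-prognosis template is the negation.
#'
#' @param scores a `cox_score_result` from [rank_features()].
#' @param k signature size (number of markers).
#' @return an object of class `signature_template`: list with `marker_ids`,
#'   `signs` (+1/-1), `k`.
#' @export
build_template <- function(scores, k) {
  if (length(k) != 1 || k < 1 || k != round(k)) stop("`k` must be a positive integer")
  usable <- sum(!scores$degenerate)
  if (k > usable)
    stop(sprintf("k = %d exceeds the %d non-degenerate features", k, usable))
  top <- scores[seq_len(k), ]
  signs <- ifelse(top$score >= 0, 1, -1)
  structure(list(marker_ids = top$feature_id, signs = signs, k = as.integer(k)),
            class = "signature_template")
}

#' Nearest-template classification of one sample profile
#'
#' Assigns the label of the closer template by cosine distance
#' `d(v, t) = 1 - (v . t) / (|v| |t|)`: the poor-prognosis template `t` (the
#' signed marker vector) or its negation (good prognosis). Markers missing
#' from the profile (`NA`) are dropped from both vectors. An exact tie or a
#' zero-norm profile is resolved conservatively to "good" and flagged.
#'
#' @param profile named numeric vector of standardized expression over the
#'   template markers.
#' @param tmpl a [build_template()] result.
#' @return list with `label` ("poor"/"good"), `distance` (to the poor
#'   template) and `tied`.
#' @export
ntp_classify <- function(profile, tmpl) {
  v <- profile[tmpl$marker_ids]
  ok <- !is.na(v)
  if (!any(ok)) return(list(label = "good", distance = NA_real_, tied = TRUE))
  v <- v[ok]; t <- tmpl$signs[ok]
  nv <- sqrt(sum(v^2)); nt <- sqrt(sum(t^2))
  if (nv < 1e-12)
    return(list(label = "good", distance = 1, tied = TRUE))
  cosine <- sum(v * t) / (nv * nt)
  d_poor <- 1 - cosine
  if (cosine > 0) list(label = "poor", distance = d_poor, tied = FALSE)
  else if (cosine < 0) list(label = "good", distance = d_poor, tied = FALSE)
  else list(label = "good", distance = d_poor, tied = TRUE)
}

# Featurizer interface for the LOOCV loop: given training sample indices and
# the held-out index, return the training feature matrix/mask and the
# held-out feature vector/mask. Gene level = plain subsetting; the gene-set
# layer supplies fold-local set scoring.
gene_featurizer <- function(m) {
  function(train, test) {
    list(values = m$values[, train, drop = FALSE],
         available = m$available[, train, drop = FALSE],
         test_values = m$values[, test],
         test_available = m$available[, test],
         feature_ids = gene_ids(m))
  }
}

# One LOOCV pass: per fold, rank features on the training samples only,
# build one template per requested k, z-score markers with training-fold
# statistics, and classify the held-out sample. Returns labels (n x length(ks))
# and the per-fold ranked feature lists.
ntp_loocv <- function(featurizer, surv, ks, n) {
  labels <- matrix(NA_character_, n, length(ks),
                   dimnames = list(surv$sample_id, paste0("k", ks)))
  fold_markers <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (sum(surv$event[train]) < 1)
      stop(sprintf("fold %d has no events in its training samples", i))
    f <- featurizer(train, i)
    fm <- expr_matrix(`dimnames<-`(f$values,
                                   list(f$feature_ids,
                                        surv$sample_id[train])),
                      `dimnames<-`(f$available,
                                   list(f$feature_ids,
                                        surv$sample_id[train])))
    scores <- rank_features(fm, surv[train, , drop = FALSE])
    fold_markers[[i]] <- scores
    mu <- rowMeans(fm$values, na.rm = TRUE)
    sdv <- apply(fm$values, 1, stats::sd, na.rm = TRUE)
    names(mu) <- names(sdv) <- f$feature_ids
    tv <- stats::setNames(f$test_values, f$feature_ids)
    tv[!f$test_available] <- NA_real_
    for (j in seq_along(ks)) {
      tmpl <- build_template(scores, ks[j])
      z <- (tv[tmpl$marker_ids] - mu[tmpl$marker_ids]) / sdv[tmpl$marker_ids]
      z[!is.finite(z)] <- NA_real_
      labels[i, j] <- ntp_classify(z, tmpl)$label
    }
  }
  list(labels = labels, fold_markers = fold_markers)
}

#' Leave-one-out cross-validated nearest-template prediction
#'
#' For each fold the held-out sample plays no part in feature ranking,
#' template construction or marker standardization: the survival-correlated
#' signature is re-derived from the remaining samples (Cox-score ranking,
#' top-k markers), markers are z-scored with training-fold mean/SD, the same
#' transform is applied to the held-out sample, and the label is assigned by
#' cosine distance to the signed template.
#'
#' @param m an [expr_matrix].
#' @param surv a [surv_table] for the samples of `m`.
#' @param k signature size.
#' @return named character vector of per-sample labels ("poor"/"good") with
#'   the per-fold score tables attached as attribute `fold_markers`.
#' @export
loocv_predict <- function(m, surv, k) {
  surv <- align_surv(m, surv)
  n <- ncol(m$values)
  if (n < 10) stop("leave-one-out prediction needs n >= 10 samples")
  res <- ntp_loocv(gene_featurizer(m), surv, k, n)
  out <- res$labels[, 1]
  attr(out, "fold_markers") <- res$fold_markers
  out
}

#' Prediction error rate against observed recurrence status
#'
#' The ground-truth class of a subject is "poor" if recurrence was observed
#' (`event = 1`) and "good" if censored; the error rate is the fraction of
#' subjects whose cross-validated label disagrees. (The alternative
#' ground-truth definition — recurrence within a time horizon — is available
#' via `horizon_months`.)
#'
#' @param labels per-sample predicted labels ("poor"/"good") in `surv` order.
#' @param surv a [surv_table].
#' @param horizon_months optional horizon: ground truth is "poor" iff
#'   recurrence was observed within this many months.
#' @return misclassified fraction in `[0, 1]`.
#' @export
error_rate <- function(labels, surv, horizon_months = NULL) {
  if (length(labels) != nrow(surv)) stop("one label per sample required")
  truth <- if (is.null(horizon_months))
    ifelse(surv$event == 1, "poor", "good")
  else
    ifelse(surv$event == 1 & surv$time <= horizon_months, "poor", "good")
  mean(labels != truth)
}

#' Sweep the signature size under LOOCV
#'
#' Runs leave-one-out nearest-template prediction for every requested
#' signature size (per-fold rankings are computed once and shared across
#' sizes), assesses each size's labels by the log-rank test and the error
#' rate, and picks the size with the smallest log-rank p, ties broken toward
#' fewer genes (the strongest signature with the fewest markers).
#'
#' @param m an [expr_matrix].
#' @param surv a [surv_table].
#' @param k_values signature sizes to try (all `<= k_max`).
#' @param k_max cap on the signature size (default 200 top-ranked features).
#' @param featurizer internal override used by the gene-set layer.
#' @return an object of class `cv_result`: data.frame `sweep` (k, logrank_p,
#'   error_rate), `labels` matrix (samples x sizes), `chosen_k`,
#'   `chosen_labels`, `fold_markers`.
#' @export
sweep_signature_size <- function(m, surv, k_values, k_max = 200,
                                 featurizer = NULL) {
  if (length(k_values) < 1) stop("`k_values` must be non-empty")
  if (any(k_values > k_max))
    stop(sprintf("k_values must not exceed k_max = %d", k_max))
  k_values <- sort(unique(as.integer(k_values)))
  surv <- align_surv(m, surv)
  n <- ncol(m$values)
  if (n < 10) stop("leave-one-out prediction needs n >= 10 samples")
  if (is.null(featurizer)) featurizer <- gene_featurizer(m)
  res <- ntp_loocv(featurizer, surv, k_values, n)
  lr <- vapply(seq_along(k_values), function(j) {
    lab <- res$labels[, j]
    if (length(unique(lab)) < 2) NA_real_
    else logrank_test(surv, lab)$p_value
  }, 0)
  er <- vapply(seq_along(k_values), function(j)
    error_rate(res$labels[, j], surv), 0)
  sweep <- data.frame(k = k_values, logrank_p = lr, error_rate = er)
  chosen <- if (all(is.na(lr))) k_values[1] else
    k_values[which(lr == min(lr, na.rm = TRUE))[1]]
  structure(list(sweep = sweep, labels = res$labels,
                 chosen_k = chosen,
                 chosen_labels = res$labels[, match(chosen, k_values)],
                 fold_markers = res$fold_markers),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOOCV nearest-template sweep over %d signature sizes\n",
              nrow(x$sweep)))
  best <- x$sweep[x$sweep$k == x$chosen_k, ]
  cat(sprintf("chosen k = %d: log-rank p = %.4g, error rate = %.3f\n",
              x$chosen_k, best$logrank_p, best$error_rate))
  invisible(x)
}

#' Restrict a cohort to the late-recurrence sub-cohort
#'
#' Retains subjects whose recurrence occurred after the cutoff and censored
#' subjects followed beyond the cutoff; subjects who recurred at or before the
#' cutoff (early recurrence) and censored subjects with shorter follow-up are
#' excluded. The default 12-month cutoff separates likely de novo tumor
#' formation in the cirrhotic liver from early metastatic regrowth.
#'
#' @param surv a [surv_table].
#' @param cutoff_months positive cutoff (months).
#' @return the filtered [surv_table].
#' @export
late_recurrence_subset <- function(surv, cutoff_months = 12) {
  if (length(cutoff_months) != 1 || cutoff_months <= 0)
    stop("`cutoff_months` must be positive")
  keep <- surv$time > cutoff_months
  if (!any(keep)) stop("late-recurrence subset is empty")
  surv[keep, , drop = FALSE]
}
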