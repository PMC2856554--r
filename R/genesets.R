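#' Per-sample gene-set scores
#'
#' Each member gene is first z-scored across samples (mean/SD over its
#' available entries, or supplied externally for fold-based use); the set
#' score of a sample is then either the mean of its member z-scores
#' (`mean_z`) or the GSA maxmean construction (`maxmean`): the mean of the
#' positive parts and the mean of the negative parts of member z-scores are
#' compared and the larger in magnitude wins, with its sign. Sets with no
#' member in the expression gene universe are dropped with a message; member
#' genes absent from the matrix are ignored.
#'
#' @param m an [expr_matrix].
#' @param gs a `geneset_collection`.
#' @param method `"mean_z"` or `"maxmean"`.
#' @param stats optional list `(center, scale)` of named per-gene statistics
#'   to use for z-scoring instead of the statistics of `m` (used inside
#'   cross-validation folds).
#' @return an [expr_matrix] of sets x samples scores, a set entry being
#'   available when at least one member gene is.
#' @export
score_sets <- function(m, gs, method = c("mean_z", "maxmean"), stats = NULL) {
  method <- match.arg(method)
  z <- gene_zscores(m, stats)
  universe <- gene_ids(m)
  members <- lapply(gs, intersect, universe)
  dropped <- names(gs)[lengths(members) == 0]
  if (length(dropped)) {
    message("score_sets: dropping ", length(dropped),
            " set(s) with no member in the expression matrix: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
    members <- members[lengths(members) > 0]
  }
  if (!length(members)) stop("no usable gene set")
  scores <- matrix(NA_real_, length(members), ncol(m$values),
                   dimnames = list(names(members), sample_ids(m)))
  for (i in seq_along(members))
    scores[i, ] <- set_score_rows(z[members[[i]], , drop = FALSE], method)
  avail <- !is.na(scores)
  expr_matrix(scores, avail, as.character(m$batch))
}

# per-sample score from a members x samples z matrix
set_score_rows <- function(zz, method) {
  if (method == "mean_z") return(colMeans(zz, na.rm = TRUE))
  nn <- colSums(!is.na(zz))
  pos <- colSums(pmax(zz, 0), na.rm = TRUE) / pmax(nn, 1)
  neg <- colSums(pmax(-zz, 0), na.rm = TRUE) / pmax(nn, 1)
  out <- ifelse(pos >= neg, pos, -neg)
  out[nn == 0] <- NA_real_
  out
}

# z-score genes across samples over available entries
gene_zscores <- function(m, stats = NULL) {
  if (is.null(stats)) {
    mu <- rowMeans(m$values, na.rm = TRUE)
    sdv <- apply(m$values, 1, stats::sd, na.rm = TRUE)
  } else {
    mu <- stats$center[gene_ids(m)]
    sdv <- stats$scale[gene_ids(m)]
  }
  z <- (m$values - mu) / ifelse(sdv > 0, sdv, NA_real_)
  z[!m$available] <- NA_real_
  z
}

# featurizer running fold-local set scoring: gene z-scoring statistics come
# from the training samples only and are applied to the held-out sample
geneset_featurizer <- function(m, gs, method) {
  function(train, test) {
    mt <- m[, train]
    mu <- rowMeans(mt$values, na.rm = TRUE)
    sdv <- apply(mt$values, 1, stats::sd, na.rm = TRUE)
    names(mu) <- names(sdv) <- gene_ids(m)
    st <- list(center = mu, scale = sdv)
    strain <- suppressMessages(score_sets(mt, gs, method, stats = st))
    stest <- suppressMessages(score_sets(m[, test, drop = FALSE], gs, method,
                                         stats = st))
    list(values = strain$values, available = strain$available,
         test_values = stest$values[, 1],
         test_available = stest$available[, 1],
         feature_ids = gene_ids(strain))
  }
}

#' Gene-set-level cross-validated nearest-template prediction
#'
#' Lifts the predictor from genes to gene sets: inside every training fold,
#' member genes are z-scored with fold statistics, per-sample set scores are
#' computed ([score_sets()]), sets are ranked by absolute Cox score, and the
#' identical template/classification/sweep machinery of the gene-level
#' predictor is applied to the sets x samples matrix.
#'
#' @param m an [expr_matrix] of gene expression.
#' @param surv a [surv_table].
#' @param gs a `geneset_collection`.
#' @param k_values signature sizes (numbers of gene sets) to sweep.
#' @param method set-score construction, `"mean_z"` or `"maxmean"`.
#' @param k_max cap on the signature size.
#' @return a `cv_result`, as from [sweep_signature_size()], over set features.
#' @export
geneset_predict <- function(m, surv, gs, k_values, method = c("mean_z", "maxmean"),
                            k_max = 200) {
  method <- match.arg(method)
  # validate the collection against the universe once, up front
  invisible(suppressMessages(score_sets(m[, seq_len(ncol(m$values))], gs,
                                        method)))
  sweep_signature_size(m, surv, k_values, k_max,
                       featurizer = geneset_featurizer(m, gs, method))
}

#' Generate a synthetic gene-set collection
#'
#' Random sets drawn from a gene universe, optionally with planted sets
#' prepended (e.g. the true signature genes), for testing the set-level
#' predictor without an external GMT.
#'
#' @param gene_ids gene universe.
#' @param n_sets number of random sets.
#' @param size_range inclusive range of set sizes.
#' @param planted optional named list of fixed sets to include first.
#' @param seed integer seed.
#' @return a `geneset_collection`.
#' @export
random_geneset_collection <- function(gene_ids, n_sets, size_range = c(10, 50),
                                      planted = NULL, seed = 1) {
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(gene_ids, s))
  names(sets) <- sprintf("set%04d", seq_len(n_sets))
  if (!is.null(planted)) sets <- c(planted, sets)
  geneset_collection(sets)
}
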