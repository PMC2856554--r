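#' Univariable Cox score statistic
#'
#' The partial-likelihood score statistic at `beta = 0` for a single feature:
#' `U(0) / sqrt(I(0))`, where `U(0)` sums, over event times, the feature's
#' deviation in the failing sample from the risk-set mean, and `I(0)` sums the
#' risk-set variances (Breslow handling of ties: tied events share the same
#' risk set and each contributes separately). This measures association with
#' time to recurrence without fitting a coefficient; positive scores mean
#' higher expression goes with earlier recurrence.
#'
#' @param x per-sample feature values (may contain `NA`; those samples are
#'   excluded from risk sets for this feature).
#' @param surv a [surv_table] aligned with `x`.
#' @return a list with `score` (0 with `degenerate = TRUE` for a zero-variance
#'   feature), `u`, `info`, `degenerate`.
#' @export
cox_score <- function(x, surv) {
  if (length(x) != nrow(surv))
    stop("feature and survival table lengths differ")
  if (sum(!is.na(x)) < 3) stop("need at least 3 samples with data")
  if (sum(surv$event[!is.na(x)]) < 1) stop("no events among usable samples")
  xm <- matrix(x, nrow = 1, dimnames = list("f", surv$sample_id))
  res <- cox_score_matrix(xm, !is.na(xm), surv$time, surv$event)
  list(score = unname(res$score), u = unname(res$u), info = unname(res$info),
       degenerate = unname(res$degenerate))
}

# Vectorized score statistics for all rows of a genes x samples matrix,
# honoring a per-entry availability mask (a gene's risk sets are restricted
# to the samples where it is available).
cox_score_matrix <- function(values, available, time, event) {
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]; es <- event[ord]
  xs <- values[, ord, drop = FALSE]
  ms <- available[, ord, drop = FALSE] * 1
  xs[ms == 0] <- 0
  # suffix sums over the time-sorted samples: column i = sum over j >= i
  tri <- matrix(0, n, n); tri[row(tri) >= col(tri)] <- 1
  s1 <- xs %*% tri
  s2 <- (xs * xs) %*% tri
  nn <- ms %*% tri
  ev <- which(es == 1)
  gi <- match(ts, ts)[ev]  # first index of each event's tie group
  nr <- nn[, gi, drop = FALSE]
  mu <- s1[, gi, drop = FALSE] / nr
  m2 <- s2[, gi, drop = FALSE] / nr
  mu[nr == 0] <- 0; m2[nr == 0] <- 0
  p <- ms[, ev, drop = FALSE]
  u <- rowSums(p * (xs[, ev, drop = FALSE] - mu))
  info <- rowSums(p * pmax(m2 - mu * mu, 0))
  degenerate <- info <= 1e-12
  score <- ifelse(degenerate, 0, u / sqrt(info))
  list(score = score, u = u, info = info, degenerate = degenerate)
}

#' Rank features by absolute Cox score
#'
#' Computes the univariable Cox score of every gene against recurrence-free
#' survival and ranks genes by descending `|score|`. Missing entries are
#' handled per gene by restricting risk sets to the samples where the gene is
#' available. Ties in `|score|` are broken by lexicographic gene id;
#' zero-variance (degenerate) genes rank last.
#'
#' @param m an [expr_matrix].
#' @param surv a [surv_table] covering the samples of `m`.
#' @return a data.frame of class `cox_score_result` with columns `feature_id`,
#'   `score`, `degenerate`, ordered by rank (row i = rank i).
#' @export
rank_features <- function(m, surv) {
  surv <- align_surv(m, surv)
  if (sum(surv$event) < 1) stop("no events in the survival table")
  res <- cox_score_matrix(m$values, m$available, surv$time, surv$event)
  ids <- gene_ids(m)
  ord <- order(res$degenerate, -abs(res$score), ids)
  structure(data.frame(feature_id = ids[ord], score = res$score[ord],
                       degenerate = res$degenerate[ord],
                       stringsAsFactors = FALSE),
            class = c("cox_score_result", "data.frame"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param surv a [surv_table].
#' @return a data.frame of class `km_fit` with one row per distinct time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival` (right-continuous;
#'   `S(0) = 1` implicitly precedes the first row).
#' @export
kaplan_meier <- function(surv) {
  if (nrow(surv) < 1) stop("empty survival table")
  tt <- sort(unique(surv$time))
  n_risk <- vapply(tt, function(t) sum(surv$time >= t), 0)
  n_event <- vapply(tt, function(t) sum(surv$time == t & surv$event == 1), 0)
  n_censor <- vapply(tt, function(t) sum(surv$time == t & surv$event == 0), 0)
  s <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = s),
            class = c("km_fit", "data.frame"))
}

#' Evaluate a Kaplan-Meier estimate at arbitrary times
#'
#' @param km a `km_fit` from [kaplan_meier()].
#' @param times times at which to evaluate the right-continuous `S(t)`.
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  vapply(times, function(t) {
    i <- findInterval(t, km$time)
    if (i == 0) 1 else km$survival[i]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance: at each distinct event
#' time the observed number of events in group 1 is compared with its
#' expectation under the null, and the chi-square statistic
#' `(sum(O - E))^2 / sum(V)` is referred to a chi-square(1) distribution.
#'
#' @param surv a [surv_table].
#' @param labels a two-level grouping (factor, character or logical), one per
#'   sample in `surv` order.
#' @return a list with `statistic`, `p_value`, `observed`, `expected` (per
#'   group) and `n` per group.
#' @export
logrank_test <- function(surv, labels) {
  labels <- as.factor(as.character(labels))
  if (length(labels) != nrow(surv))
    stop("one label per sample required")
  if (nlevels(labels) != 2)
    stop("log-rank test needs exactly two non-empty groups; got ",
         nlevels(labels))
  g1 <- labels == levels(labels)[1]
  tt <- sort(unique(surv$time[surv$event == 1]))
  o <- e <- v <- 0
  for (t in tt) {
    at_risk <- surv$time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(surv$time == t & surv$event == 1)
    d1 <- sum(surv$time == t & surv$event == 1 & g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o - e)^2 / v else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p,
       observed = stats::setNames(c(o, sum(surv$event) - o), levels(labels)),
       expected = stats::setNames(c(e, sum(surv$event) - e), levels(labels)),
       n = table(labels))
}

# Breslow/Efron log partial likelihood, gradient and information at beta,
# for an n x k covariate matrix. Used by cox_fit and, explicitly coded, by
# the finite-difference test oracles.
cox_partial_loglik <- function(beta, x, time, event, ties = "breslow") {
  n <- nrow(x); k <- ncol(x)
  eta <- as.numeric(x %*% beta)
  r <- exp(eta)
  ll <- 0
  grad <- numeric(k)
  info <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    risk <- which(time >= t)
    dead <- which(time == t & event == 1)
    d <- length(dead)
    s0 <- sum(r[risk])
    s1 <- as.numeric(crossprod(x[risk, , drop = FALSE], r[risk]))
    s2 <- crossprod(x[risk, , drop = FALSE] * r[risk], x[risk, , drop = FALSE])
    if (ties == "breslow") {
      ll <- ll + sum(eta[dead]) - d * log(s0)
      grad <- grad + colSums(x[dead, , drop = FALSE]) - d * s1 / s0
      info <- info + d * (s2 / s0 - tcrossprod(s1 / s0))
    } else {  # efron
      s0d <- sum(r[dead])
      s1d <- as.numeric(crossprod(x[dead, , drop = FALSE], r[dead]))
      s2d <- crossprod(x[dead, , drop = FALSE] * r[dead], x[dead, , drop = FALSE])
      ll <- ll + sum(eta[dead])
      grad <- grad + colSums(x[dead, , drop = FALSE])
      for (l in seq_len(d) - 1) {
        f <- l / d
        s0l <- s0 - f * s0d
        s1l <- s1 - f * s1d
        s2l <- s2 - f * s2d
        ll <- ll - log(s0l)
        grad <- grad - s1l / s0l
        info <- info + s2l / s0l - tcrossprod(s1l / s0l)
      }
    }
  }
  list(loglik = ll, gradient = grad, information = info)
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the partial likelihood (Breslow tie handling
#' by default, Efron available), with Wald 95% confidence intervals
#' `exp(beta +/- 1.96 se)` — the risk-ratio-with-CI presentation used for
#' clinico-pathological prognostic tables.
#'
#' @param covariates numeric vector (single covariate) or n x k matrix;
#'   column names become coefficient names.
#' @param surv a [surv_table] aligned with the covariate rows.
#' @param ties `"breslow"` or `"efron"`.
#' @param max_iter maximum Newton-Raphson iterations.
#' @param tol convergence tolerance on the gradient max-norm.
#' @return an object of class `cox_fit`: data.frame `table` (variable, coef,
#'   risk_ratio, ci_low, ci_high, p_value), plus `loglik`, `iter`, `ties`.
#' @export
cox_fit <- function(covariates, surv, ties = c("breslow", "efron"),
                    max_iter = 100, tol = 1e-9) {
  ties <- match.arg(ties)
  x <- if (is.matrix(covariates)) covariates else
    matrix(covariates, ncol = 1, dimnames = list(NULL, "x"))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  if (nrow(x) != nrow(surv)) stop("covariate rows must match survival table")
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  time <- surv$time[keep]; event <- surv$event[keep]
  n <- nrow(x); k <- ncol(x)
  if (n <= k) stop("need more samples than covariates")
  if (sum(event) < 1) stop("no events")
  if (qr(scale(x, scale = FALSE))$rank < k)
    stop("collinear covariate columns")

  beta <- numeric(k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    pl <- cox_partial_loglik(beta, x, time, event, ties)
    if (max(abs(pl$gradient)) < tol) break
    step <- tryCatch(solve(pl$information, pl$gradient),
                     error = function(e) stop("singular information matrix; ",
                                              "check covariate scaling"))
    # step-halving to keep the likelihood non-decreasing
    h <- 1
    repeat {
      cand <- beta + h * step
      ll_new <- cox_partial_loglik(cand, x, time, event, ties)$loglik
      if (ll_new >= pl$loglik - 1e-12 || h < 1e-4) break
      h <- h / 2
    }
    beta <- beta + h * step
    if (any(abs(beta) > 20))
      stop("monotone partial likelihood (perfect separation); ",
           "consider a penalized fit")
    if (it == max_iter) {
      g <- cox_partial_loglik(beta, x, time, event, ties)$gradient
      stop(sprintf("Cox fit did not converge in %d iterations (|grad| = %.3g)",
                   max_iter, max(abs(g))))
    }
    ll_old <- pl$loglik
  }
  pl <- cox_partial_loglik(beta, x, time, event, ties)
  se <- sqrt(diag(solve(pl$information)))
  z <- beta / se
  tab <- data.frame(variable = colnames(x), coef = beta, se = se,
                    risk_ratio = exp(beta),
                    ci_low = exp(beta - 1.96 * se),
                    ci_high = exp(beta + 1.96 * se),
                    p_value = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = pl$loglik, iter = it, ties = ties,
                 n = n, n_events = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- x$table
  tab$risk_ratio <- sprintf("%.2f", tab$risk_ratio)
  tab$ci <- sprintf("%.2f-%.2f", x$table$ci_low, x$table$ci_high)
  tab$p_value <- format.pval(x$table$p_value, digits = 2)
  print(tab[, c("variable", "risk_ratio", "ci", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Export Cox fits as a risk-ratio table
#'
#' Writes a TSV with one row per variable (variable, risk ratio, 95% CI,
#' p-value), mirroring the layout of clinical prognostic-marker tables.
#'
#' @param fits a `cox_fit` or list of them.
#' @param path output TSV path.
#' @export
write_cox_table <- function(fits, path) {
  if (inherits(fits, "cox_fit")) fits <- list(fits)
  tab <- do.call(rbind, lapply(fits, function(f) f$table))
  out <- data.frame(variable = tab$variable,
                    risk_ratio = round(tab$risk_ratio, 2),
                    ci_95 = sprintf("%.2f-%.2f", tab$ci_low, tab$ci_high),
                    p_value = signif(tab$p_value, 2))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
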