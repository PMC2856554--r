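#' Extract log2 ratios and the availability mask from two-channel scans
#'
#' @param scan a `two_color_scan` (see [generate_two_channel()]) or a long
#'   data.frame with columns probe_id, sample_id, cy5, cy3, saturated,
#'   below_loq and optionally batch_id.
#' @return an [expr_matrix] with `values = log2(cy5/cy3)` and
#'   `available = !(saturated | below_loq)`.
#' @export
log_ratio <- function(scan) {
  p <- scan_probes(scan)
  bad <- !p$saturated & !p$below_loq & (p$cy5 <= 0 | p$cy3 <= 0)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("nonpositive unflagged intensity for probe %s in sample %s",
                 p$probe_id[i], p$sample_id[i]))
  }
  probes <- unique(p$probe_id)
  samples <- unique(p$sample_id)
  per_sample <- split(p$probe_id, p$sample_id)
  same <- vapply(per_sample, function(ids)
    length(ids) == length(probes) && !anyDuplicated(ids) &&
      all(ids %in% probes), TRUE)
  if (!all(same))
    stop("per-sample probe tables do not share a common probe universe")
  ri <- match(p$probe_id, probes)
  ci <- match(p$sample_id, samples)
  vals <- matrix(NA_real_, length(probes), length(samples),
                 dimnames = list(probes, samples))
  avail <- matrix(FALSE, length(probes), length(samples),
                  dimnames = list(probes, samples))
  vals[cbind(ri, ci)] <- log2(p$cy5 / p$cy3)
  avail[cbind(ri, ci)] <- !(p$saturated | p$below_loq)
  vals[!avail] <- NA_real_
  batch <- NULL
  if (!is.null(p$batch_id))
    batch <- p$batch_id[match(samples, p$sample_id)]
  expr_matrix(vals, avail, batch)
}

scan_probes <- function(scan) {
  p <- if (inherits(scan, "two_color_scan")) scan$probes else scan
  need <- c("probe_id", "sample_id", "cy5", "cy3", "saturated", "below_loq")
  if (!all(need %in% names(p)))
    stop("scan must carry columns: ", paste(need, collapse = ", "))
  p
}

# mean log2 intensity per entry, aligned with an expr_matrix
scan_a_matrix <- function(scan, m) {
  p <- scan_probes(scan)
  a <- matrix(NA_real_, nrow(m$values), ncol(m$values),
              dimnames = dimnames(m$values))
  ri <- match(p$probe_id, gene_ids(m))
  ci <- match(p$sample_id, sample_ids(m))
  keep <- !is.na(ri) & !is.na(ci)
  a[cbind(ri[keep], ci[keep])] <-
    0.5 * (log2(p$cy5[keep]) + log2(p$cy3[keep]))
  a
}

#' LOWESS intensity normalization of log ratios
#'
#' Per sample, fits a locally weighted regression (tricube weights, local
#' linear, with robustness iterations) of the log ratio `M` on the mean log2
#' intensity `A = (log2 cy5 + log2 cy3)/2` over the available entries, and
#' subtracts the fit. This removes the smooth intensity-dependent dye bias of
#' two-color arrays. Unavailable entries are untouched.
#'
#' @param m an [expr_matrix] of log ratios (e.g. from [log_ratio()]).
#' @param scan the matching two-channel scan supplying `A` values.
#' @param span LOWESS span (fraction of points in each local window), in
#'   `(0, 1]`.
#' @param iters number of robustness (bisquare reweighting) iterations.
#' @return the normalized [expr_matrix].
#' @export
normalize_lowess <- function(m, scan, span = 0.3, iters = 3) {
  if (length(span) != 1 || !is.finite(span) || span <= 0 || span > 1)
    stop("`span` must be in (0, 1]")
  a <- scan_a_matrix(scan, m)
  vals <- m$values
  for (j in seq_len(ncol(vals))) {
    ok <- m$available[, j] & !is.na(a[, j])
    if (sum(ok) < 5) next
    fit <- stats::lowess(a[ok, j], vals[ok, j], f = span, iter = iters,
                         delta = 0)
    fitted <- stats::approx(fit$x, fit$y, xout = a[ok, j], rule = 2,
                            ties = mean)$y
    vals[ok, j] <- vals[ok, j] - fitted
  }
  expr_matrix(vals, m$available, as.character(m$batch))
}

#' Filter genes by data availability
#'
#' Retains exactly the genes whose fraction of available entries across
#' samples is at least `min_fraction` (genes with fewer available data are
#' excluded); the default reproduces the conventional 70% rule.
#'
#' @param m an [expr_matrix].
#' @param min_fraction minimum available fraction in `(0, 1]`.
#' @return the filtered [expr_matrix], gene order preserved.
#' @export
availability_filter <- function(m, min_fraction = 0.7) {
  if (length(min_fraction) != 1 || !is.finite(min_fraction) ||
      min_fraction <= 0 || min_fraction > 1)
    stop("`min_fraction` must be in (0, 1]")
  frac <- rowMeans(m$available)
  keep <- frac >= min_fraction
  if (!any(keep))
    message("availability_filter: no genes pass min_fraction = ", min_fraction)
  m[keep, ]
}

#' Inter-batch normalization along a discriminating direction
#'
#' Batches are merged successively in batch-label order: at each step the next
#' batch is adjusted against the pool of already-merged batches by (1) finding
#' a unit direction separating the two groups — either the Distance Weighted
#' Discrimination direction (minimizing the sum of reciprocal margins plus
#' penalized slacks) or the normalized mean-difference direction — (2)
#' projecting all samples onto it, and (3) subtracting each group's mean
#' projection (centered so gene-wise means across all samples are preserved).
#' Missing entries are imputed to the gene mean for direction-finding only.
#'
#' @param m an [expr_matrix] with batch labels.
#' @param method `"dwd"` or `"mean_shift"`.
#' @return the batch-adjusted [expr_matrix].
#' @export
batch_adjust <- function(m, method = c("dwd", "mean_shift")) {
  method <- match.arg(method)
  batches <- levels(m$batch)
  if (length(batches) == 1) return(m)
  sizes <- table(m$batch)
  if (any(sizes < 2))
    stop("every batch needs >= 2 samples; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  vals <- m$values
  # gene-mean imputation for direction-finding only
  gm <- rowMeans(vals, na.rm = TRUE)
  gm[is.nan(gm)] <- 0
  imp <- vals
  imp[!m$available] <- gm[row(vals)[!m$available]]

  merged <- m$batch == batches[1]
  for (b in batches[-1]) {
    grp2 <- m$batch == b
    w <- switch(method,
      mean_shift = {
        d <- rowMeans(imp[, merged, drop = FALSE]) -
             rowMeans(imp[, grp2, drop = FALSE])
        nd <- sqrt(sum(d^2))
        if (nd < 1e-12) NULL else d / nd
      },
      dwd = dwd_direction(imp, merged, grp2))
    if (!is.null(w)) {
      proj <- as.numeric(crossprod(imp, w))
      mu1 <- mean(proj[merged]); mu2 <- mean(proj[grp2])
      n1 <- sum(merged); n2 <- sum(grp2)
      grand <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
      shift <- ifelse(grp2, mu2 - grand, ifelse(merged, mu1 - grand, 0))
      delta <- outer(w, shift)
      vals <- vals - delta
      imp <- imp - delta
    }
    merged <- merged | grp2
  }
  expr_matrix(vals, m$available, as.character(m$batch))
}

# Distance Weighted Discrimination direction between two sample groups.
# Works in the SVD-reduced sample space (the optimal direction lies in the
# span of the data), minimizing the smooth DWD loss
#   V(u) = 1/u            for u >= 1/sqrt(C)
#        = 2*sqrt(C) - Cu otherwise
# over margins u_i = y_i (s_i' w + b) with ||w|| = 1, via BFGS with analytic
# gradient, started from the mean-difference direction.
dwd_direction <- function(imp, grp1, grp2, maxit = 400) {
  idx <- which(grp1 | grp2)
  y <- ifelse(grp1[idx], 1, -1)
  x <- imp[, idx, drop = FALSE]
  ctr <- rowMeans(x)
  xc <- x - ctr
  sv <- svd(xc, nu = min(dim(xc)), nv = min(dim(xc)))
  r <- sum(sv$d > 1e-10 * sv$d[1])
  if (r == 0) return(NULL)
  s <- t(sv$v[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r))
  # s: r x n score matrix; direction w in score space maps back via u_r
  d2 <- as.matrix(stats::dist(t(s)))^2
  between <- d2[y == 1, y == -1, drop = FALSE]
  med2 <- stats::median(between)
  if (!is.finite(med2) || med2 <= 0) med2 <- mean(d2) + 1e-8
  cc <- 100 / med2
  thresh <- 1 / sqrt(cc)

  vloss <- function(u) ifelse(u >= thresh, 1 / u, 2 * sqrt(cc) - cc * u)
  vgrad <- function(u) ifelse(u >= thresh, -1 / u^2, -cc)

  obj <- function(theta) {
    v <- theta[seq_len(r)]; b <- theta[r + 1]
    nv <- sqrt(sum(v^2)); if (nv < 1e-12) return(1e10)
    u <- y * (as.numeric(crossprod(s, v / nv)) + b)
    sum(vloss(u))
  }
  grad <- function(theta) {
    v <- theta[seq_len(r)]; b <- theta[r + 1]
    nv <- sqrt(sum(v^2))
    w <- v / nv
    u <- y * (as.numeric(crossprod(s, w)) + b)
    g <- vgrad(u)
    gw <- as.numeric(s %*% (g * y))           # d/dw
    gv <- (gw - sum(gw * w) * w) / nv          # through the normalization
    c(gv, sum(g * y))
  }
  v0 <- rowMeans(s[, y == 1, drop = FALSE]) - rowMeans(s[, y == -1, drop = FALSE])
  if (sqrt(sum(v0^2)) < 1e-12) v0 <- rep(1 / sqrt(r), r)
  v0 <- v0 / sqrt(sum(v0^2))
  b0 <- -sum(as.numeric(crossprod(s, v0)) * rep(1 / length(y), length(y)))
  fit <- stats::optim(c(v0, b0), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  if (fit$convergence != 0 && fit$convergence != 1)
    stop(sprintf("DWD solver failed to converge (code %d, %d evaluations)",
                 fit$convergence, fit$counts[1]))
  v <- fit$par[seq_len(r)]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(NULL)
  w_full <- sv$u[, seq_len(r), drop = FALSE] %*% (v / nv)
  as.numeric(w_full) / sqrt(sum(w_full^2))
}
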