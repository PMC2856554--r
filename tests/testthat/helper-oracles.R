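# Independent oracles used across the test files. Everything here is written
# naively (plain loops, explicit formulas) and never calls the package's own
# computational path.

# Explicit Breslow log partial likelihood for a single covariate.
naive_breslow_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Finite-difference score statistic at beta = 0: U(0)/sqrt(I(0)) from the
# first and second numerical derivatives of the explicit log partial
# likelihood.
fd_cox_score <- function(x, time, event, h = 1e-4) {
  lp <- naive_breslow_loglik(h, x, time, event)
  l0 <- naive_breslow_loglik(0, x, time, event)
  lm <- naive_breslow_loglik(-h, x, time, event)
  u <- (lp - lm) / (2 * h)
  info <- -(lp - 2 * l0 + lm) / h^2
  if (info <= 1e-8) return(0)
  u / sqrt(info)
}

# Multivariate Breslow log partial likelihood (explicit), for cox_fit checks.
naive_breslow_loglik_multi <- function(beta, x, time, event) {
  eta <- as.numeric(x %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Hand log-rank chi-square: sum over event times of (O - E)^2 / V with the
# hypergeometric variance, written as explicit per-time loops.
naive_logrank_chisq <- function(time, event, grp1) {
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp1)
    o <- o + d1; e <- e + d * n1 / n
    if (n > 1) v <- v + d * n1 * (n - n1) * (n - d) / (n^2 * (n - 1))
  }
  (o - e)^2 / v
}

# Brute-force tricube locally weighted linear fit at a single target point,
# using all points in the window (span = 1).
tricube_wls_at <- function(x0, x, y) {
  dist <- abs(x - x0)
  h <- max(dist)
  w <- (1 - (dist / h)^3)^3
  w[dist >= h] <- 0
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  sum(fit$coefficients * c(1, x0))
}

# Brute-force reimplementation of the LOOCV nearest-template fold loop:
# per-gene Cox scores by explicit loops, top-k by |score| with lexicographic
# tie-break, training-fold z-scoring, cosine-distance classification.
naive_loocv_labels <- function(vals, time, event, k) {
  n <- ncol(vals)
  labels <- character(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sc <- numeric(nrow(vals))
    for (g in seq_len(nrow(vals))) {
      xg <- vals[g, tr]; tg <- time[tr]; eg <- event[tr]
      u <- 0; info <- 0
      for (ev in which(eg == 1)) {
        risk <- which(tg >= tg[ev])
        mu <- mean(xg[risk])
        u <- u + xg[ev] - mu
        info <- info + mean(xg[risk]^2) - mu^2
      }
      sc[g] <- if (info <= 1e-12) 0 else u / sqrt(info)
    }
    ord <- order(-abs(sc), rownames(vals))
    top <- ord[seq_len(k)]
    signs <- ifelse(sc[top] >= 0, 1, -1)
    mu <- apply(vals[top, tr, drop = FALSE], 1, mean)
    sdv <- apply(vals[top, tr, drop = FALSE], 1, sd)
    z <- (vals[top, i] - mu) / sdv
    cosine <- sum(z * signs) / (sqrt(sum(z^2)) * sqrt(sum(signs^2)))
    labels[i] <- if (cosine > 0) "poor" else "good"
  }
  labels
}

# Small fully-observed expression matrix with matching survival, for quick
# deterministic fixtures.
toy_cohort <- function(n = 20, g = 50, seed = 42, event_p = 0.7) {
  set.seed(seed)
  vals <- matrix(rnorm(g * n), g, n,
                 dimnames = list(sprintf("g%03d", seq_len(g)),
                                 sprintf("s%03d", seq_len(n))))
  time <- round(rexp(n, 0.05) + 0.5, 3)
  event <- rbinom(n, 1, event_p)
  if (sum(event) == 0) event[1] <- 1
  list(m = expr_matrix(vals),
       surv = surv_table(colnames(vals), time, event))
}

# Random small survival instance (n <= 8) with possible ties, for
# property-based oracle-agreement loops.
random_small_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  time <- sample(1:5, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
  event <- rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[sample(n, 1)] <- 1
  x <- round(rnorm(n), 3)
  list(x = x, time = time, event = event)
}
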