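test_that("cox_score handles constant and negated features", {
  surv <- surv_table(paste0("s", 1:6), c(1, 2, 3, 4, 5, 6),
                     c(1, 1, 0, 1, 0, 1))
  const <- cox_score(rep(2, 6), surv)
  expect_equal(const$score, 0)
  expect_true(const$degenerate)
  x <- c(2, 1, 0.5, 0, -1, 0.3)
  expect_equal(cox_score(-x, surv)$score, -cox_score(x, surv)$score)
  expect_error(cox_score(x, surv_table(paste0("s", 1:6), 1:6, rep(0, 6))),
               "events")
})

test_that("cox_score matches the finite-difference oracle on the toy instance", {
  surv <- surv_table(paste0("s", 1:5), c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 0))
  x <- c(2.0, 1.0, 0.5, 0.0, -1.0)
  got <- cox_score(x, surv)$score
  expect_equal(got, fd_cox_score(x, surv$time, surv$event), tolerance = 1e-6)
})

test_that("cox_score agrees with the finite-difference oracle on random small instances", {
  for (seed in 1:60) {
    inst <- random_small_instance(seed)
    surv <- surv_table(paste0("s", seq_along(inst$x)), inst$time, inst$event)
    got <- cox_score(inst$x, surv)$score
    expect_equal(got, fd_cox_score(inst$x, inst$time, inst$event),
                 tolerance = 1e-6,
                 label = sprintf("score, seed %d", seed))
  }
})

test_that("cox_score restricted to available samples equals the score on the subset", {
  set.seed(5)
  n <- 12
  surv <- surv_table(paste0("s", 1:n), rexp(n, 0.1) + 0.5, rbinom(n, 1, 0.8))
  x <- rnorm(n)
  miss <- c(2, 7, 11)
  xm <- x; xm[miss] <- NA
  keep <- setdiff(1:n, miss)
  sub <- surv_table(surv$sample_id[keep], surv$time[keep], surv$event[keep])
  expect_equal(cox_score(xm, surv)$score, cox_score(x[keep], sub)$score,
               tolerance = 1e-12)
})

test_that("rank_features orders by |score|, breaks ties lexicographically, ranks degenerate last", {
  tc <- toy_cohort(n = 15, g = 20, seed = 10)
  vals <- tc$m$values
  vals["g003", ] <- vals["g007", ]         # exact duplicate -> tied |score|
  vals["g012", ] <- 1.5                    # degenerate
  m <- expr_matrix(vals)
  r <- rank_features(m, tc$surv)
  expect_true(all(diff(abs(r$score[!r$degenerate])) < 1e-12))
  i3 <- which(r$feature_id == "g003"); i7 <- which(r$feature_id == "g007")
  expect_equal(abs(i3 - i7), 1)
  expect_lt(i3, i7)                        # lexicographic tie-break
  expect_equal(r$feature_id[nrow(r)], "g012")
  expect_true(r$degenerate[nrow(r)])
})

test_that("ranking is invariant under a joint permutation of samples", {
  tc <- toy_cohort(n = 18, g = 30, seed = 11)
  set.seed(1); perm <- sample(18)
  m2 <- tc$m[, perm]
  s2 <- tc$surv[perm, , drop = FALSE]
  expect_identical(rank_features(tc$m, tc$surv)$feature_id,
                   rank_features(m2, s2)$feature_id)
})

test_that("planted signature genes rank near the top", {
  # n = 100, 20 planted, |beta| = 1: >= 80% of planted genes in the top 40
  # ranks in >= 90% of seeds
  hits <- vapply(1:25, function(s) {
    co <- generate_cohort(synthetic_config(n_samples = 100, n_genes = 500,
                                           n_signature_genes = 20,
                                           beta_signature = 1,
                                           censor_rate = 0.3,
                                           batch_shift_sd = 0,
                                           missing_rate = 0, seed = s))
    r <- rank_features(co$expression, co$survival)
    mean(co$truth$gene_id %in% r$feature_id[1:40]) >= 0.8
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("Kaplan-Meier reproduces closed-form and hand-computed estimates", {
  all_cens <- kaplan_meier(surv_table(paste0("s", 1:4), c(1, 2, 3, 4),
                                      rep(0, 4)))
  expect_true(all(all_cens$survival == 1))
  all_ev <- kaplan_meier(surv_table(paste0("s", 1:3), c(1, 2, 3), rep(1, 3)))
  expect_equal(all_ev$survival, c(2 / 3, 1 / 3, 0))
  # tie and censoring: times 1,1,2+,3; S(1) = 2/4 = 0.5; the censored subject
  # leaves the risk set, so the last event empties it: S(3) = 0.5 * (1 - 1/1) = 0
  km <- kaplan_meier(surv_table(paste0("s", 1:4), c(1, 1, 2, 3),
                                c(1, 1, 0, 1)))
  expect_equal(km_survival_at(km, c(0.5, 1, 2.5, 3)), c(1, 0.5, 0.5, 0))
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("Kaplan-Meier matches the established implementation on random data", {
  skip_if_not_installed("survival")
  set.seed(12)
  n <- 40
  surv <- surv_table(paste0("s", 1:n), sample(1:15, n, replace = TRUE),
                     rbinom(n, 1, 0.6))
  km <- kaplan_meier(surv)
  sf <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
  expect_equal(km_survival_at(km, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("log-rank statistic matches the hand computation and is symmetric", {
  surv <- surv_table(paste0("s", 1:8), c(1, 2, 3, 4, 5, 6, 7, 8),
                     c(1, 1, 1, 0, 1, 1, 0, 1))
  grp <- rep(c("a", "b"), 4)
  res <- logrank_test(surv, grp)
  expect_equal(res$statistic,
               naive_logrank_chisq(surv$time, surv$event, grp == "a"),
               tolerance = 1e-12)
  swapped <- logrank_test(surv, ifelse(grp == "a", "b", "a"))
  expect_equal(swapped$statistic, res$statistic, tolerance = 1e-12)
  expect_error(logrank_test(surv, rep("a", 8)), "two")
})

test_that("log-rank p-value is invariant to monotone time transformations", {
  set.seed(13)
  n <- 30
  surv <- surv_table(paste0("s", 1:n), rexp(n, 0.1) + 0.1, rbinom(n, 1, 0.7))
  grp <- rep(c("x", "y"), n / 2)
  p1 <- logrank_test(surv, grp)$p_value
  surv2 <- surv_table(surv$sample_id, log1p(surv$time)^2 + 0.01, surv$event)
  expect_equal(logrank_test(surv2, grp)$p_value, p1, tolerance = 1e-12)
})

test_that("cox_fit matches the established implementation on a binary covariate", {
  skip_if_not_installed("survival")
  set.seed(14)
  n <- 30
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.05 * exp(0.8 * x)) + 0.01
  event <- rbinom(n, 1, 0.8)
  event[1] <- 1
  surv <- surv_table(paste0("s", 1:n), time, event)
  fit <- cox_fit(x, surv)
  ref <- survival::coxph(survival::Surv(time, event) ~ x,
                         ties = "breslow")
  expect_equal(fit$table$coef, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$table$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  # Efron ties too
  fit_e <- cox_fit(x, surv, ties = "efron")
  ref_e <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  expect_equal(fit_e$table$coef, unname(coef(ref_e)), tolerance = 1e-6)
})

test_that("cox_fit maximizes the explicit partial likelihood (grid check)", {
  inst <- random_small_instance(21)
  surv <- surv_table(paste0("s", seq_along(inst$x)), inst$time, inst$event)
  fit <- cox_fit(inst$x, surv)
  b <- fit$table$coef
  ll <- function(beta) naive_breslow_loglik(beta, inst$x, inst$time, inst$event)
  expect_equal(fit$loglik, ll(b), tolerance = 1e-8)
  expect_gt(ll(b), ll(b + 0.01))
  expect_gt(ll(b), ll(b - 0.01))
})

test_that("duplicating every sample leaves the coefficient unchanged", {
  set.seed(15)
  n <- 20
  x <- rnorm(n)
  surv <- surv_table(paste0("s", 1:n), rexp(n, 0.1) + 0.1, rbinom(n, 1, 0.8))
  fit1 <- cox_fit(x, surv)
  surv2 <- surv_table(paste0("s", 1:(2 * n)), rep(surv$time, 2),
                      rep(surv$event, 2))
  fit2 <- cox_fit(rep(x, 2), surv2)
  expect_equal(fit2$table$coef, fit1$table$coef, tolerance = 1e-6)
})

test_that("cox_fit CI structure holds and null coverage is near nominal", {
  covered <- vapply(1:60, function(s) {
    set.seed(s + 3000)
    n <- 80
    x <- rnorm(n)
    surv <- surv_table(paste0("s", 1:n), rexp(n, 0.05) + 0.01,
                       rbinom(n, 1, 0.8))
    f <- cox_fit(x, surv)$table
    f$ci_low <= 1 && 1 <= f$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.85)  # 95% nominal, binomial noise at 60 reps
  set.seed(16)
  n <- 50
  surv <- surv_table(paste0("s", 1:n), rexp(n, 0.05) + 0.01,
                     rbinom(n, 1, 0.8))
  f <- cox_fit(rnorm(n), surv)$table
  expect_true(f$ci_low <= f$risk_ratio && f$risk_ratio <= f$ci_high)
  expect_gt(f$risk_ratio, 0)
})

test_that("cox_fit rejects pathological inputs", {
  set.seed(17)
  n <- 20
  surv <- surv_table(paste0("s", 1:n), rexp(n, 0.1) + 0.1, rbinom(n, 1, 0.8))
  x <- rnorm(n)
  expect_error(cox_fit(cbind(a = x, b = 2 * x), surv), "collinear")
  # perfect separation: covariate orders time exactly among all-event data
  surv_sep <- surv_table(paste0("s", 1:8), 1:8, rep(1, 8))
  expect_error(cox_fit(8:1, surv_sep), "separation|penal")
})

test_that("score sign agrees with the fitted coefficient sign", {
  for (seed in 1:15) {
    inst <- random_small_instance(seed + 100)
    if (length(unique(inst$x)) < 2) next
    surv <- surv_table(paste0("s", seq_along(inst$x)), inst$time, inst$event)
    sc <- cox_score(inst$x, surv)
    if (sc$degenerate || abs(sc$score) < 0.05) next
    fit <- tryCatch(cox_fit(inst$x, surv), error = function(e) NULL)
    if (is.null(fit)) next
    expect_equal(sign(sc$score), sign(fit$table$coef),
                 label = sprintf("sign agreement, seed %d", seed + 100))
  }
})
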