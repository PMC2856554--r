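make_scan <- function(df) structure(list(probes = df), class = "two_color_scan")

test_that("log_ratio computes log2(cy5/cy3) and honors flags", {
  df <- data.frame(
    probe_id = rep(c("p1", "p2", "p3"), 2),
    sample_id = rep(c("s1", "s2"), each = 3),
    cy5 = c(400, 100, 800, 50, 123, 9),
    cy3 = c(100, 100, 200, 200, 123, 9),
    saturated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    below_loq = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  m <- log_ratio(make_scan(df))
  expect_equal(m$values["p1", "s1"], 2)            # log2(400/100)
  expect_equal(m$values["p2", "s1"], 0)            # cy5 == cy3
  expect_equal(m$values["p1", "s2"], -2)
  expect_false(m$available["p3", "s1"])            # saturated
  expect_false(m$available["p3", "s2"])            # below LOQ
  expect_true(m$available["p2", "s2"])
})

test_that("log_ratio rejects nonpositive unflagged intensities, naming the probe", {
  df <- data.frame(probe_id = c("p1", "p2"), sample_id = "s1",
                   cy5 = c(10, -5), cy3 = c(10, 10),
                   saturated = FALSE, below_loq = FALSE)
  expect_error(log_ratio(make_scan(df)), "p2.*s1")
})

test_that("log_ratio requires a shared probe universe across samples", {
  df <- data.frame(probe_id = c("p1", "p2", "p1"),
                   sample_id = c("s1", "s1", "s2"),
                   cy5 = 10, cy3 = 10, saturated = FALSE, below_loq = FALSE)
  expect_error(log_ratio(make_scan(df)), "probe universe")
})

test_that("lowess normalization is a near-identity when M carries no trend in A", {
  set.seed(1)
  g <- 500; f <- 0.4; sigma <- 0.2
  a <- rnorm(g, 10, 2)
  m0 <- rnorm(g, 0, sigma)
  df <- data.frame(probe_id = sprintf("p%03d", 1:g), sample_id = "s1",
                   cy5 = 2^(a + m0 / 2), cy3 = 2^(a - m0 / 2),
                   saturated = FALSE, below_loq = FALSE)
  m <- log_ratio(make_scan(df))
  mn <- normalize_lowess(m, make_scan(df), span = f)
  # noise floor: the largest per-point standard error of the local tricube
  # weighted linear fit, computed by brute force
  k <- ceiling(f * g)
  se <- vapply(seq_len(g), function(i) {
    d <- abs(a - a[i]); nb <- order(d)[1:k]; h <- max(d[nb])
    w <- (1 - (d[nb] / h)^3)^3; w[d[nb] >= h] <- 0
    x <- cbind(1, a[nb] - a[i])
    l <- solve(crossprod(x, w * x), t(x * w))[1, ]
    sigma * sqrt(sum(l^2))
  }, 0)
  expect_lt(max(abs(mn$values - m$values)), 3 * max(se))
})

test_that("lowess normalization removes a planted intensity-dependent bias", {
  set.seed(2)
  g <- 4000
  a <- runif(g, 6, 14)
  bias <- 0.5 * sin(a - 10)
  m0 <- rnorm(g, 0, 0.3)
  df <- data.frame(probe_id = sprintf("p%05d", 1:g), sample_id = "s1",
                   cy5 = 2^(a + (m0 + bias) / 2), cy3 = 2^(a - (m0 + bias) / 2),
                   saturated = FALSE, below_loq = FALSE)
  scan <- make_scan(df)
  m <- log_ratio(scan)
  mn <- normalize_lowess(m, scan, span = 0.2)
  # refit the trend on the normalized data with the same smoother
  refit <- stats::lowess(a, mn$values[, 1], f = 0.2, iter = 3, delta = 0)
  expect_lt(max(abs(refit$y)), 0.05)
  # the original trend was an order of magnitude larger
  fit0 <- stats::lowess(a, m$values[, 1], f = 0.2, iter = 3, delta = 0)
  expect_gt(max(abs(fit0$y)), 0.3)
})

test_that("the generator's own dye bias is removed by normalization", {
  cfg <- synthetic_config(n_samples = 4, n_genes = 4000,
                          dye_bias_amplitude = 0.5, missing_rate = 0, seed = 13)
  co <- generate_cohort(cfg)
  sc <- generate_two_channel(cfg, co)
  m <- log_ratio(sc)
  mn <- normalize_lowess(m, sc, span = 0.3)
  a <- 0.5 * (log2(sc$probes$cy5) + log2(sc$probes$cy3))
  a1 <- a[sc$probes$sample_id == "s001"]
  resid <- mn$values[, 1] - co$expression$values[, 1]
  refit <- stats::lowess(a1, resid, f = 0.3, iter = 3, delta = 0)
  # residual intensity trend is far below the planted 0.5-amplitude bias,
  # within the fit noise floor of N(0,1) expression at this probe count
  expect_lt(max(abs(refit$y)), 0.1)
  raw_trend <- stats::lowess(a1, m$values[, 1] - co$expression$values[, 1],
                             f = 0.3, iter = 3, delta = 0)
  expect_gt(max(abs(raw_trend$y)), 0.3)
})

test_that("the local fit matches a brute-force tricube weighted regression", {
  # 5 probes, full-window span: the fitted value at each point must equal an
  # explicit tricube weighted least-squares prediction
  a <- c(4, 5.5, 7, 8.5, 10)
  m0 <- c(0.2, -0.1, 0.4, 0.0, -0.3)
  fit <- stats::lowess(a, m0, f = 1, iter = 0, delta = 0)
  for (i in seq_along(a))
    expect_equal(fit$y[i], tricube_wls_at(a[i], a, m0), tolerance = 1e-8)
  # and normalize_lowess subtracts exactly that fit
  df <- data.frame(probe_id = paste0("p", 1:5), sample_id = "s1",
                   cy5 = 2^(a + m0 / 2), cy3 = 2^(a - m0 / 2),
                   saturated = FALSE, below_loq = FALSE)
  scan <- make_scan(df)
  m <- log_ratio(scan)
  mn <- normalize_lowess(m, scan, span = 1, iters = 0)
  expect_equal(unname(mn$values[, 1]), m0 - fit$y, tolerance = 1e-8)
})

test_that("lowess normalization leaves unavailable entries untouched", {
  set.seed(3)
  cfg <- synthetic_config(n_samples = 8, n_genes = 300, missing_rate = 0.1,
                          seed = 6)
  sc <- generate_two_channel(cfg)
  m <- log_ratio(sc)
  mn <- normalize_lowess(m, sc)
  expect_identical(mn$available, m$available)
  expect_true(all(is.na(mn$values[!mn$available])))
  expect_error(normalize_lowess(m, sc, span = 0), "span")
  expect_error(normalize_lowess(m, sc, span = 1.5), "span")
})

test_that("availability filter keeps exactly the genes at or above the threshold", {
  vals <- matrix(rnorm(30), 3, 10,
                 dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:10)))
  avail <- matrix(TRUE, 3, 10)
  avail[1, 1:4] <- FALSE   # g1: 6/10 available -> excluded at 0.7
  avail[2, 1:3] <- FALSE   # g2: 7/10 available -> retained (boundary)
  vals[!avail] <- NA
  m <- expr_matrix(vals, avail)
  f <- availability_filter(m, 0.7)
  expect_identical(rownames(f$values), c("g2", "g3"))
  # idempotence
  expect_identical(availability_filter(f, 0.7)$values, f$values)
  expect_error(availability_filter(m, 0), "min_fraction")
})

test_that("mean-shift batch adjustment exactly removes a pure additive shift", {
  vals <- matrix(c(1, 2, 1.5, 2.5, 2, 3, 2.5, 3.5), 2, 4,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  # batch B = batch A samples shifted by (+1, +1)
  m <- expr_matrix(vals, batch = c("A", "A", "B", "B"))
  adj <- batch_adjust(m, "mean_shift")
  d <- rowMeans(adj$values[, 1:2]) - rowMeans(adj$values[, 3:4])
  expect_equal(unname(d), c(0, 0), tolerance = 1e-12)
  # gene-wise grand means preserved
  expect_equal(rowMeans(adj$values), rowMeans(vals), tolerance = 1e-12)
  # idempotence on its own output
  adj2 <- batch_adjust(adj, "mean_shift")
  expect_equal(adj2$values, adj$values, tolerance = 1e-10)
})

test_that("batch adjustment removes a planted distributional shift", {
  set.seed(4)
  g <- 200; n <- 30
  vals <- matrix(rnorm(g * n), g, n,
                 dimnames = list(sprintf("g%03d", 1:g), sprintf("s%03d", 1:n)))
  shift <- 4  # a clear batch effect, well separated from within-batch spread
  vals[, 16:30] <- vals[, 16:30] + shift
  m <- expr_matrix(vals, batch = rep(c("A", "B"), each = 15))
  for (method in c("mean_shift", "dwd")) {
    adj <- batch_adjust(m, method)
    resid <- rowMeans(adj$values[, 1:15]) - rowMeans(adj$values[, 16:30])
    expect_lt(max(abs(resid)), 0.05 * shift)
    expect_equal(dim(adj$values), dim(vals))
  }
})

test_that("single-batch input and tiny batches are handled", {
  co <- generate_cohort(synthetic_config(n_samples = 10, n_genes = 50,
                                         n_batches = 1, seed = 8))
  expect_identical(batch_adjust(co$expression, "mean_shift")$values,
                   co$expression$values)
  m <- expr_matrix(co$expression$values, co$expression$available,
                   batch = c("A", rep("B", 9)))
  expect_error(batch_adjust(m, "mean_shift"), "2 samples")
})

test_that("preprocessing never changes the sample count", {
  cfg <- synthetic_config(n_samples = 12, n_genes = 200, missing_rate = 0.2,
                          seed = 9)
  sc <- generate_two_channel(cfg)
  m <- log_ratio(sc)
  expect_equal(ncol(normalize_lowess(m, sc)$values), 12)
  expect_equal(ncol(availability_filter(m, 0.7)$values), 12)
  expect_equal(ncol(batch_adjust(m, "mean_shift")$values), 12)
})
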