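test_that("lag-1 autocorrelation estimator behaves on known processes", {
  set.seed(21)
  wn <- barcode(rnorm(1e4), 500, 0)
  expect_lt(estimate_autocorrelation(wn), 3 / sqrt(1e4))

  # Gaussian-kernel-smoothed white noise has lag-1 acf exp(-1/(4 sigma^2))
  sig <- 3
  n <- 2e4
  sm <- apply_psf(rnorm(n), sig, circular = TRUE)
  expect_equal(estimate_autocorrelation(barcode(sm, 500, 0)),
               exp(-1 / (4 * sig^2)), tolerance = 0.02)

  jit <- barcode(10 + rnorm(5e3, sd = 1e-3), 500, 0)
  expect_lt(estimate_autocorrelation(jit), 0.05)
  expect_error(estimate_autocorrelation(barcode(rep(1, 50), 500, 0)),
               "variance")
})

test_that("random barcode generator matches the requested autocorrelation and seed contract", {
  a <- generate_random_barcodes(5000, 0, 2, seed = 9)
  r1 <- acf(a[, 1], lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 3 / sqrt(5000))

  b1 <- generate_random_barcodes(100, 0.5, 3, seed = 10)
  b2 <- generate_random_barcodes(100, 0.5, 3, seed = 10)
  expect_identical(b1, b2)

  c1 <- generate_random_barcodes(1e4, 0.8, 1, seed = 11)
  expect_equal(acf(c1[, 1], lag.max = 1, plot = FALSE)$acf[2], 0.8,
               tolerance = 0.02)

  k1 <- generate_random_barcodes(2e4, 0.9, 1, seed = 12,
                                 method = "kernel")
  expect_equal(acf(k1[, 1], lag.max = 1, plot = FALSE)$acf[2], 0.9,
               tolerance = 0.02)

  # every column is z-normalized
  expect_equal(colMeans(b1), rep(0, 3), tolerance = 1e-12)
})

test_that("null fit recovers parameters and quantiles of self-generated maxima", {
  set.seed(22)
  nu <- 50; ne <- 200; a <- (nu - 2) / 2
  cs <- 2 * qbeta(runif(2000)^(1 / ne), a, a) - 1
  f <- fit_null(cs, n_comparisons = 200)
  q99_true <- 2 * qbeta(0.99^(1 / ne), a, a) - 1
  expect_lt(abs(qnull_max(0.99, f) - q99_true), 0.01)
  expect_gt(f$nu_eff, 3)
  expect_gte(f$n_eff, 1)

  # more effective comparisons shift the distribution right
  med1 <- 2 * qbeta(0.5^(1 / ne), a, a) - 1
  med2 <- 2 * qbeta(0.5^(1 / (2 * ne)), a, a) - 1
  expect_gt(med2, med1)
})

test_that("p-values are exact at the endpoints and monotone in the score", {
  set.seed(23)
  cs <- 2 * qbeta(runif(500)^(1 / 100), 20, 20) - 1
  f <- fit_null(cs, n_comparisons = 100)
  expect_equal(score_to_pvalue(-1, f), 1)
  expect_equal(score_to_pvalue(1, f), 0)
  grid <- seq(-0.99, 0.99, length.out = 201)
  pv <- score_to_pvalue(grid, f)
  expect_true(all(diff(pv) <= 1e-12))
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("fitted null calibrates against the real matching machinery", {
  fix <- tiny_reference(60000, seed = 701, noise_sd = 0.3)
  W <- reference_windows(fix$ref, 40)
  X <- generate_random_barcodes(40, 0.94, 1000, seed = 24,
                                method = "kernel")
  mx <- cbscaffold:::max_scores_against(W, X)
  f <- fit_null(mx, n_comparisons = 2 * fix$ref$n_px,
                contig_len_px = 40, corr_param = 0.94)

  # p at the empirical 99th percentile is ~0.01 (the single-draw order
  # statistic is noisy at R = 1000, so the estimate averages three
  # independent draws; the tolerance stays the +-0.005 single-R band)
  q99 <- vapply(1:3, function(i) {
    Xi <- generate_random_barcodes(40, 0.94, 1000, seed = 240 + i,
                                   method = "kernel")
    quantile(cbscaffold:::max_scores_against(W, Xi), 0.99)
  }, 0)
  expect_lt(abs(mean(score_to_pvalue(q99, f)) - 0.01), 0.005)

  # sup-norm distance between fitted and empirical CDF
  Fv <- 1 - score_to_pvalue(sort(mx), f)
  ks <- max(abs(Fv - (seq_along(mx) - 0.5) / length(mx)))
  expect_lt(ks, 0.05)

  # fresh nulls: P(p < alpha) = alpha within binomial error (3 sd)
  X2 <- generate_random_barcodes(40, 0.94, 2000, seed = 25,
                                 method = "kernel")
  pv <- score_to_pvalue(cbscaffold:::max_scores_against(W, X2), f)
  for (alpha in c(0.01, 0.05)) {
    tol <- 3 * sqrt(alpha * (1 - alpha) / 2000)
    expect_lt(abs(mean(pv < alpha) - alpha), tol + 1e-9)
  }
})

test_that("null fits shift left as contig length grows", {
  fix <- tiny_reference(60000, seed = 701, noise_sd = 0.3)
  med <- vapply(c(30, 60, 90), function(m) {
    W <- reference_windows(fix$ref, m)
    X <- generate_random_barcodes(m, 0.9, 400, seed = 26 + m,
                                  method = "kernel")
    median(cbscaffold:::max_scores_against(W, X))
  }, 0)
  expect_true(all(diff(med) < 0))
})

test_that("length filter applies the 12-sigma threshold inclusively", {
  mk <- function(n) dna_sequence(strrep("ACGT", ceiling(n / 4)),
                                 id = sprintf("l%d", n))
  sqs <- list(short = dna_sequence(strrep("ACGT", 2999), id = "s11996"),
              edge = mk(12000), long = mk(20000))
  out <- length_filter(sqs, 12 * 1000)
  expect_equal(unname(vapply(out$kept, `[[`, "", "id")),
               c("l12000", "l20000"))
  expect_equal(unname(vapply(out$discarded, `[[`, "", "id")), "s11996")
  all_in <- length_filter(sqs, 0)
  expect_length(all_in$kept, 3L)
  empty <- length_filter(list(), 500)
  expect_length(empty$kept, 0L)
  expect_length(empty$discarded, 0L)
})

test_that("degenerate inputs to fit_null error", {
  expect_error(fit_null(rep(0.5, 100)), "degenerate")
  expect_error(fit_null(c(0.1, 0.2)), "few")
})

test_that("null cache round-trips through JSON", {
  set.seed(27)
  cs <- 2 * qbeta(runif(300)^(1 / 50), 15, 15) - 1
  cache <- new_null_cache()
  f <- cbscaffold:::cache_get_or_fit(cache, 40L, 0.9,
                                     function(key) fit_null(cs, 100,
                                                            40L, 0.9))
  # second call hits the cache (same object, no refit)
  f2 <- cbscaffold:::cache_get_or_fit(cache, 40L, 0.9,
                                      function(key) stop("refit!"))
  expect_identical(f, f2)
  path <- tempfile(fileext = ".json")
  null_cache_to_json(cache, path)
  back <- null_cache_from_json(path)
  g <- back[[cbscaffold:::null_cache_key(40L, 0.9)]]
  expect_s3_class(g, "cb_nullfit")
  expect_equal(g$nu_eff, f$nu_eff, tolerance = 1e-9)
  expect_equal(score_to_pvalue(0.4, g), score_to_pvalue(0.4, f),
               tolerance = 1e-9)
})
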