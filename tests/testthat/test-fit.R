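test_that("optimizer matches a fine grid-search oracle", {
  set.seed(31)
  for (i in 1:20) {
    tp <- runif(1, 0.1, 1.2)
    th <- rdsine(400, tp)
    fit <- fit_damped_sine(th)
    expect_lt(abs(fit$theta_prime - grid_mle(th)), 2e-3)
  }
})

test_that("MLE is consistent at large n for a range of true values", {
  # fixed typical draws; the estimate's own sampling SD at n = 1e5 is of
  # order 0.01 for the larger true values, so this is a regression check
  # on typical behavior, not a distributional guarantee
  for (tp in c(0.2, 0.45, 1.0)) {
    th <- rdsine(1e5, tp, seed = 4)
    fit <- fit_damped_sine(th)
    expect_lt(abs(fit$theta_prime - tp), 0.01)
  }
})

test_that("fit at the pooled study scale recovers the generating value", {
  # n matches the pooled S3+S4 piwi-1+ cell count; the +/- 0.045 scale is
  # the model's own bootstrap uncertainty at that n
  th <- rdsine(4411, 0.45, seed = 42)
  fit <- fit_damped_sine(th)
  expect_lt(abs(fit$theta_prime - 0.45), 3 * 0.045)
  expect_true(fit$converged)
})

test_that("likelihood ratio is always >= 1 and null fits sit at the boundary", {
  for (s in 1:20) {
    fit <- fit_damped_sine(rdsine(50, 0, seed = s))
    expect_gte(fit$likelihood_ratio, 1)
    expect_gte(fit$loglik_fit, fit$loglik_null)
  }
  # a large null sample: estimate near 0 and LR close to 1 (typical draw;
  # the 50-run frequency version of this check lives in the pipeline tests)
  fit0 <- fit_damped_sine(rdsine(1e4, 0, seed = 71))
  expect_lt(fit0$theta_prime, 0.1)
  expect_lte(fit0$likelihood_ratio, exp(2))
})

test_that("angles at the poles are clamped with a warning, not dropped", {
  th <- c(0, 0.5, 1.2, 2.0, pi)
  expect_warning(fit <- fit_damped_sine(th), "pole")
  expect_equal(fit$n, 5L)
  expect_true(is.finite(fit$loglik_fit))
  expect_error(fit_damped_sine(numeric(0)), "empty")
})

test_that("bootstrap SE scales as 1/sqrt(n)", {
  b1 <- bootstrap_se(0.45, n = 500, B = 300, seed = 8)
  b2 <- bootstrap_se(0.45, n = 2000, B = 300, seed = 9)
  expect_true(b2$se / b1$se > 0.4 && b2$se / b1$se < 0.6)
  expect_length(b1$estimates, 300)
})

test_that("bootstrap replicates are reproducible independently of B", {
  b_small <- bootstrap_se(0.45, n = 100, B = 10, seed = 3)
  b_big <- bootstrap_se(0.45, n = 100, B = 20, seed = 3)
  expect_identical(b_small$estimates, b_big$estimates[1:10])
})

test_that("null comparison reports the raw likelihood ratio", {
  fit <- fit_damped_sine(rdsine(500, 0.45, seed = 2))
  fit$loglik_fit <- fit$loglik_null
  fit$likelihood_ratio <- 1
  fit$log10_lr <- 0
  cmp <- compare_to_null(fit)
  expect_equal(cmp$likelihood_ratio, 1)
  expect_equal(cmp$log10_lr, 0)
  fit$loglik_fit <- fit$loglik_null + log(50)
  fit$likelihood_ratio <- exp(log(50))
  fit$log10_lr <- log(50) / log(10)
  cmp <- compare_to_null(fit)
  expect_equal(cmp$likelihood_ratio, 50, tolerance = 1e-12)
  expect_match(cmp$verdict, "more likely")
})

test_that("fit methods and JSON serialization work together", {
  th <- rdsine(800, 0.58, seed = 4)
  fit <- add_bootstrap_se(fit_damped_sine(th), B = 20, seed = 5)
  expect_named(coef(fit), "theta_prime")
  expect_s3_class(logLik(fit), "logLik")
  expect_output(print(fit), "theta'")
  expect_output(print(summary(fit)), "bootstrap SE")
  sims <- simulate(fit, nsim = 2, seed = 6)
  expect_length(sims, 2)
  expect_length(sims[[1]], fit$n)
  rec <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(rec$theta_prime_hat, fit$theta_prime)
  expect_equal(rec$n, fit$n)
  expect_equal(rec$n_boot, 20)
})

test_that("histogram export covers [0, pi] and preserves counts", {
  th <- rdsine(1000, 0.45, seed = 13)
  h <- theta_histogram(th, bins = 20)
  expect_equal(nrow(h), 20)
  expect_equal(h$bin_left[1], 0)
  expect_equal(h$bin_right[20], pi)
  expect_equal(sum(h$count), 1000)
  path <- tempfile(fileext = ".tsv")
  theta_histogram(th, bins = 10, path = path)
  back <- read.delim(path)
  expect_equal(sum(back$count), 1000)
})
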