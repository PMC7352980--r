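test_that("K = 1 equals the closed-form ML Gaussian", {
  f <- fit_gmm(c(0.4, 0.6), K = 1)
  expect_equal(f$means, 0.5)
  expect_equal(f$sds, 0.1)
  expect_equal(f$weights, 1)

  set.seed(5)
  x <- rnorm(500, 0.6, 0.12)
  f <- fit_gmm(x, K = 1)
  ml <- fit_gaussian_ml(x)
  expect_equal(f$means, ml$mu, tolerance = 1e-15)
  expect_equal(f$sds, ml$sigma, tolerance = 1e-15)
})

test_that("EM log-likelihood is non-decreasing along the trace", {
  set.seed(9)
  x <- c(rnorm(400, 0.35, 0.06), rnorm(600, 0.65, 0.08))
  for (k in c(2, 3)) {
    f <- suppressWarnings(fit_gmm(x, K = k,
                                  control = em_control(max_iter = 200)))
    expect_true(all(diff(f$trace) > -1e-9))
    expect_equal(sum(f$weights), 1, tolerance = 1e-10)
    expect_true(all(f$sds > 0))
    expect_equal(f$means, sort(f$means))   # canonical component order
  }
})

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(1234)
  n <- 10000
  comp <- rbinom(n, 1, 0.5)
  x <- rnorm(n, ifelse(comp == 1, 0.7, 0.3), 0.05)
  x <- x[x >= 0 & x <= 1]
  f <- fit_gmm(x, K = 2, control = em_control(seed = 99))
  expect_true(all(abs(f$means - c(0.3, 0.7)) < 0.01))
  expect_true(all(abs(f$weights - 0.5) < 0.03))
  expect_true(all(abs(f$sds - 0.05) < 0.01))
})

test_that("fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  set.seed(77)
  x <- c(rnorm(1500, 0.4, 0.05), rnorm(1500, 0.62, 0.09))
  ours <- fit_gmm(x, K = 2, control = em_control(seed = 3))
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_true(all(abs(sort(ours$means) -
                        sort(as.numeric(ref$parameters$mean))) < 0.01))
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-3)
})

test_that("likelihood is non-decreasing in K on right-skewed data", {
  set.seed(21)
  # right-skewed similarity-like sample with mode near 0.5
  x <- c(rnorm(3000, 0.45, 0.07), rnorm(1500, 0.6, 0.12),
         rnorm(500, 0.85, 0.15))
  x <- x[x >= 0 & x <= 2]
  ctrl <- em_control(seed = 8, max_iter = 300)
  ll <- vapply(c(1, 3, 7), function(k) {
    suppressWarnings(fit_gmm(x, K = k, control = ctrl))$loglik
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-6))
})

test_that("fit is invariant to input order and deterministic given a seed", {
  set.seed(31)
  x <- c(rnorm(800, 0.4, 0.06), rnorm(800, 0.7, 0.08))
  ctrl <- em_control(seed = 17)
  f1 <- fit_gmm(x, K = 2, control = ctrl)
  f2 <- fit_gmm(sample(x), K = 2, control = ctrl)
  f3 <- fit_gmm(x, K = 2, control = ctrl)
  expect_equal(f1$means, f2$means, tolerance = 1e-8)
  expect_identical(f1$means, f3$means)
  expect_identical(f1$loglik, f3$loglik)
})

test_that("degenerate requests error or flag as specified", {
  expect_error(fit_gmm(c(0.1, 0.2), K = 3), "at least K")
  expect_error(fit_gmm(0.5, K = 0), "K")
  f <- fit_gmm(rep(0.5, 10), K = 1)
  expect_true(f$collapsed)
  expect_gte(f$sds, 1e-6)
})

test_that("mixture pdf is normalised, symmetric when built so, and exact", {
  expect_equal(dgmm(0, 1, 0, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  w <- c(0.3, 0.7); m <- c(0.3, 0.8); s <- c(0.05, 0.12)
  total <- integrate(function(x) dgmm(x, w, m, s), -Inf, Inf)$value
  expect_equal(total, 1, tolerance = 1e-8)
  # equal weights, means symmetric about 0.5
  f <- function(x) dgmm(x, c(0.5, 0.5), c(0.3, 0.7), c(0.08, 0.08))
  expect_equal(f(0.5 + 0.123), f(0.5 - 0.123), tolerance = 1e-12)
  expect_error(dgmm(0, c(0.5, 0.6), c(0, 1), c(1, 1)), "sum to 1")
  expect_error(dgmm(0, 1, 0, -1), "positive")
})

test_that("gmm fits serialise to JSON and back", {
  set.seed(4)
  f <- fit_gmm(rnorm(300, 0.5, 0.1), K = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_gmm_json(f, path)
  back <- read_gmm_json(path)
  expect_equal(back$means, f$means, tolerance = 1e-15)
  expect_equal(back$sds, f$sds, tolerance = 1e-15)
  expect_equal(back$loglik, f$loglik, tolerance = 1e-12)
})
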