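test_that("closed form reproduces hand-computed values", {
  expect_equal(kl_gaussian_closed(c(0.3, 0.1), c(0.3, 0.1)), 0)
  expect_equal(kl_gaussian_closed(c(0, 2), c(0, 1)),
               log(1 / 2) + 2 - 0.5, tolerance = 1e-12)
  # query Gaussian (0.24055, 0.07472) against class Gaussian
  # (0.5483, 0.1458); frozen from direct evaluation of the formula,
  # cross-checked by quadrature below
  expect_equal(kl_gaussian_closed(c(0.24055, 0.07472), c(0.5483, 0.1458)),
               2.5274785, tolerance = 1e-6)
  expect_error(kl_gaussian_closed(c(0, -1), c(0, 1)), "positive")
})

test_that("closed form agrees with quadrature over random Gaussian pairs", {
  set.seed(55)
  for (i in 1:100) {
    mu <- runif(2, 0.1, 0.9)
    sd <- runif(2, 0.03, 0.3)
    closed <- kl_gaussian_closed(c(mu[1], sd[1]), c(mu[2], sd[2]))
    quad <- kl_numeric(function(x) dnorm(x, mu[1], sd[1], log = TRUE),
                       function(x) dnorm(x, mu[2], sd[2], log = TRUE),
                       lower = mu[1] - 13 * sd[1],
                       upper = mu[1] + 13 * sd[1],
                       method = "adaptive", log_pdfs = TRUE,
                       split_points = mu[2] + c(-6, 0, 6) * sd[2])
    expect_lt(abs(quad - closed), 1e-6)
  }
})

test_that("divergence is non-negative and zero only for equal Gaussians", {
  set.seed(66)
  for (i in 1:200) {
    p <- c(runif(1, 0, 1), runif(1, 0.02, 0.4))
    q <- c(runif(1, 0, 1), runif(1, 0.02, 0.4))
    d <- kl_gaussian_closed(p, q)
    expect_gte(d, -1e-9)
    if (max(abs(p - q)) > 1e-3) expect_gt(d, 0)
  }
  expect_equal(kl_gaussian_closed(c(0.4, 0.1), c(0.4, 0.1)), 0,
               tolerance = 1e-9)
})

test_that("divergence grows with the mean gap at fixed sds", {
  gaps <- seq(0, 0.5, by = 0.05)
  d <- vapply(gaps, function(g) {
    kl_gaussian_closed(c(0.3 + g, 0.08), c(0.3, 0.12))
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("quadrature handles mixtures, degenerate weights, and directions", {
  # identical pdfs
  f <- function(x) dnorm(x, 0.5, 0.1)
  expect_equal(kl_numeric(f, f, -0.5, 1.5), 0, tolerance = 1e-8)

  # K = 3 mixture that is really a single Gaussian
  cf <- fit_gmm(rnorm(100, 0.5, 0.1), K = 1)
  cf3 <- structure(list(weights = c(1, 0, 0) + c(-2e-16, 1e-16, 1e-16),
                        means = c(0.5, 0.2, 0.8), sds = c(0.1, 0.1, 0.1),
                        K = 3L), class = "gmm_fit")
  cf3$weights <- c(1, 0, 0); cf3$weights <- cf3$weights / sum(cf3$weights)
  q <- gaussian_params(0.5, 0.1)
  expect_equal(kl_query_class(q, cf3), 0, tolerance = 1e-8)

  # K = 1 dispatches to the closed form
  q2 <- gaussian_params(0.3, 0.05)
  expect_equal(kl_query_class(q2, cf),
               kl_gaussian_closed(c(0.3, 0.05), c(cf$means, cf$sds)),
               tolerance = 1e-6)

  # asymmetry and the direction flag
  fwd <- kl_query_class(q2, cf, direction = "query-to-class")
  rev <- kl_query_class(q2, cf, direction = "class-to-query")
  sym <- kl_query_class(q2, cf, direction = "symmetric")
  expect_false(isTRUE(all.equal(fwd, rev)))
  expect_equal(sym, (fwd + rev) / 2, tolerance = 1e-9)
})

test_that("divergence_table matches elementwise scalar calls", {
  set.seed(88)
  gen <- generate_matrix(separated_spec(n = 15L, seed = 5L))
  sm <- gen$matrix
  labels <- names(class_numbers(sm))
  classes <- lapply(labels, function(lab) {
    fit_gmm(intra_class_values(class_block(sm, lab)), K = 1)
  })
  names(classes) <- labels
  queries <- lapply(c(1, 20, 35, 50), function(j) {
    fit_gaussian_ml(extract_query_vector(sm, j, labels[1]))
  })
  # each query fitted against class 1 only here; table uses one fit per query
  tab <- divergence_table(queries, classes)
  expect_s3_class(tab, "divergence_table")
  expect_equal(dim(divergence_matrix(tab)), c(4L, 4L))
  expect_true(all(divergence_matrix(tab) >= -1e-9))
  for (i in seq_along(queries)) {
    for (lab in labels) {
      expect_equal(tab[i, lab],
                   kl_query_class(queries[[i]], classes[[lab]]),
                   tolerance = 1e-12)
    }
  }
  # single query, single class, identical parameters
  same <- gaussian_params(classes[[1]]$means, classes[[1]]$sds)
  tab1 <- divergence_table(list(same), classes[1])
  expect_equal(unname(divergence_matrix(tab1)[1, 1]), 0, tolerance = 1e-12)
})
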