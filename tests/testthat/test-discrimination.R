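test_that("assignment takes the minimal-divergence class with low tie-break", {
  # a published example row of query-versus-class divergences: the
  # minimum sits in the fourth (CTSD) column
  expect_equal(assign_class(c(2.6310, 5.2420, 2.9952, 1.9426)), 4L)
  expect_equal(assign_class(c(0.5, 0.5)), 1L)
  expect_error(assign_class(c(1, NaN)), "NA")
  set.seed(12)
  for (i in 1:50) {
    row <- runif(sample(2:8, 1), 0, 5)
    brute <- which(row == min(row))[1]
    expect_equal(assign_class(row), brute)
  }
})

test_that("probability matrix tallies assignments row-stochastically", {
  P <- probability_matrix(c(1L, 2L, 2L, 2L), c(1L, 1L, 2L, 2L))
  expect_equal(P, matrix(c(0.5, 0, 0.5, 1), 2, 2))
  expect_rows_sum_to_one(P)
  expect_error(probability_matrix(c(1L, 1L), c(1L, 1L), M = 2),
               "no queries")

  set.seed(23)
  for (i in 1:20) {
    M <- sample(2:5, 1)
    n <- 200
    truth <- sample(M, n, replace = TRUE)
    truth[1:M] <- 1:M                    # every class populated
    pred <- sample(M, n, replace = TRUE)
    P <- probability_matrix(pred, truth, M)
    expect_rows_sum_to_one(P)
    brute <- table(factor(truth, 1:M), factor(pred, 1:M))
    expect_equal(unname(P), unname(brute / rowSums(brute)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("necessary condition flags the benchmark's COX2 row at K = 1", {
  b <- benchmark_prob_matrix()
  P1 <- as.matrix(b[b$K == 1, c("ESR", "VDR", "COX2", "CTSD")])
  expect_equal(unname(necessary_condition(P1)), c(TRUE, TRUE, FALSE, TRUE))
  expect_true(all(necessary_condition(diag(4))))
  expect_true(all(necessary_condition(matrix(0.25, 4, 4))))  # >=, not >
})

test_that("feasibility conventions match their definitions", {
  expect_equal(feasibility_index(0.9404), 3.9722, tolerance = 1e-3)
  expect_equal(feasibility_index(0.9404, "eq26"), 0.9404 / 0.0596,
               tolerance = 1e-6)
  expect_equal(feasibility_index(0.5), 1)
  expect_equal(feasibility_index(0.5, "eq26"), 1)
  expect_equal(feasibility_index(0), 0)
  expect_warning(out <- feasibility_index(1), "infinite")
  expect_identical(out, Inf)
  expect_error(feasibility_index(1.2), "\\[0, 1\\]")
  # square-root convention squared is the odds convention, everywhere
  p <- seq(0, 0.99, by = 0.01)
  expect_equal(feasibility_index(p)^2, feasibility_index(p, "eq26"),
               tolerance = 1e-12)
})

test_that("cumulative divergence is the sorted empirical CDF", {
  one <- cumulative_divergence(0.7)
  expect_equal(one$divergence, 0.7)
  expect_equal(one$cumulative, 1)
  set.seed(9)
  d <- rexp(40)
  cd <- cumulative_divergence(d)
  expect_equal(cd$cumulative[length(d)], 1)
  expect_equal(cd$divergence, sort(d))
  expect_equal(cd$cumulative, rank(sort(d)) / length(d))
  expect_error(cumulative_divergence(c(1, Inf)), "finite")
})

test_that("discrimination_report assembles all pieces coherently", {
  gen <- generate_matrix(overlap_spec(n = 30L, seed = 13L, gap = 0.015))
  scr <- kl_screen(gen$matrix, K = 1)
  rep1 <- scr$reports[[1]]
  expect_s3_class(rep1, "discrimination_report")
  expect_rows_sum_to_one(rep1$prob_matrix)
  expect_true(all(rep1$feasibility >= 0))
  expect_equal(length(rep1$assignments), nrow(scr$divergences[[1]]))
  # report recomputes from the table
  manual <- discrimination_report(scr$divergences[[1]])
  expect_equal(manual$prob_matrix, rep1$prob_matrix)
  expect_equal(manual$feasibility, rep1$feasibility)
})
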