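# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

# A small hand-addressable similarity matrix with two classes.
tiny_matrix <- function(score_range = c(0, 1)) {
  set.seed(11)
  n <- 6L
  v <- matrix(runif(n * n, 0.1, 0.9), n, n)
  diag(v) <- score_range[2]
  ids <- sprintf("L%02d", 1:n)
  cls <- rep(c("A", "B"), each = 3)
  similarity_matrix(v, ids, ids, cls, cls, score_range = score_range)
}

# Four well-separated classes: intra-class means far apart (gap >= 3 SD),
# cross-class similarity centred well below every class mean, so queries
# discriminate essentially perfectly.
separated_spec <- function(n = 50L, seed = 101L,
                           gap_means = c(0.30, 0.45, 0.60, 0.75),
                           sd = 0.05) {
  synthetic_spec(
    classes = lapply(1:4, function(i) {
      list(label = paste0("C", i), n = as.integer(n), weights = 1,
           means = gap_means[i], sds = sd)
    }),
    cross_params = function(a, b) c(0.20, sd),
    seed = seed)
}

# Four classes with identical intra-class distributions but cross-class
# similarity shifted by `gap`: discrimination strength is tunable and,
# for small gaps, imperfect (finite feasibility).
overlap_spec <- function(n = 40L, seed = 303L, gap = 0.02) {
  synthetic_spec(
    classes = lapply(1:4, function(i) {
      list(label = paste0("C", i), n = as.integer(n), weights = 1,
           means = 0.5, sds = 0.05)
    }),
    cross_params = function(a, b) c(0.5 + gap, 0.05),
    seed = seed)
}

# Four statistically identical classes: no signal at all.
identical_spec <- function(n = 50L, seed = 202L) {
  synthetic_spec(
    classes = lapply(1:4, function(i) {
      list(label = paste0("N", i), n = as.integer(n), weights = 1,
           means = 0.5, sds = 0.1)
    }),
    cross_params = function(a, b) c(0.5, 0.1),
    seed = seed)
}

expect_rows_sum_to_one <- function(P, tol = 1e-10) {
  expect_true(all(abs(rowSums(P) - 1) < tol))
}
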