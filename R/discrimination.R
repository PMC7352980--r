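#' Assign a query to the class with minimal divergence
#'
#' The assignment rule: a query is predicted to belong to the class whose
#' Q-distribution is closest in Kullback-Leibler divergence. Ties go to
#' the lowest class number.
#'
#' @param divergences numeric vector of per-class divergences (ordered by
#'   class number).
#' @return 1-based class number of the minimum.
#' @export
assign_class <- function(divergences) {
  d <- as.numeric(divergences)
  if (length(d) == 0L) stop("empty divergence row", call. = FALSE)
  if (any(is.na(d))) stop("divergence row contains NA/NaN", call. = FALSE)
  which.min(d)   # which.min returns the first (lowest-index) minimum
}

#' Assignment probability matrix
#'
#' Entry (m, i) is the fraction of class-`m` queries whose minimal
#' divergence points at class `i`; each row is an empirical distribution
#' over predicted classes and sums to one.
#'
#' @param assignments integer vector of predicted class numbers, one per
#'   query.
#' @param true_classes integer vector of the queries' annotated class
#'   numbers.
#' @param M number of classes; default `max(true_classes)`.
#' @return `M x M` numeric matrix with rows = true class, columns =
#'   predicted class.
#' @export
probability_matrix <- function(assignments, true_classes,
                               M = max(true_classes)) {
  assignments <- as.integer(assignments)
  true_classes <- as.integer(true_classes)
  if (length(assignments) != length(true_classes)) {
    stop("assignments and true classes differ in length", call. = FALSE)
  }
  counts <- matrix(0, M, M)
  for (m in seq_len(M)) {
    idx <- true_classes == m
    if (!any(idx)) {
      stop(sprintf("class %d has no queries", m), call. = FALSE)
    }
    counts[m, ] <- tabulate(assignments[idx], nbins = M)
  }
  counts / rowSums(counts)
}

#' Necessary condition for class discriminability
#'
#' Class `m` passes when its self-assignment probability is at least the
#' largest off-diagonal probability in its row:
#' `P(m, m) >= max_{i != m} P(m, i)`.
#'
#' @param prob_matrix square assignment probability matrix.
#' @return Logical vector, one flag per class.
#' @export
necessary_condition <- function(prob_matrix) {
  P <- as.matrix(prob_matrix)
  if (nrow(P) != ncol(P)) stop("probability matrix must be square",
                               call. = FALSE)
  vapply(seq_len(nrow(P)), function(m) {
    P[m, m] >= max(P[m, -m])
  }, logical(1))
}

#' Feasibility index from a self-assignment probability
#'
#' Quantifies how sharply a class is discriminated from all others via
#' the self-assignment odds `P/(1-P)`. Two conventions are provided:
#' `"eq26"` returns the odds themselves, while `"table4"` (the default)
#' returns their square root, the convention under which the published
#' four-target benchmark's feasibility column is reproduced from its
#' probability matrix. The two are algebraically linked:
#' `feasibility("table4")^2 == feasibility("eq26")`.
#'
#' @param p_mm self-assignment probability (or vector of them) in
#'   `[0, 1]`; `p = 1` yields `Inf` with a warning.
#' @param mode `"table4"` (square root of odds, default) or `"eq26"`
#'   (odds).
#' @return Numeric feasibility index, >= 0.
#' @examples
#' feasibility_index(0.9404)            # about 3.972
#' feasibility_index(0.9404, "eq26")    # about 15.78
#' @export
feasibility_index <- function(p_mm, mode = c("table4", "eq26")) {
  mode <- match.arg(mode)
  p <- as.numeric(p_mm)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("self-assignment probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(p == 1)) {
    warning("self-assignment probability of 1 gives an infinite index",
            call. = FALSE)
  }
  odds <- p / (1 - p)
  if (mode == "table4") sqrt(odds) else odds
}

#' Empirical cumulative distribution of divergences
#'
#' The step-function CDF of a set of query-to-class divergences, the
#' curve used to compare how tightly each query class concentrates
#' around a target's Q-distribution.
#'
#' @param divergences non-empty numeric vector of finite divergences.
#' @return Object of class `cumulative_divergence`: a data frame with
#'   columns `divergence` (sorted) and `cumulative` (rank/n).
#' @export
cumulative_divergence <- function(divergences) {
  d <- as.numeric(divergences)
  if (length(d) == 0L || any(!is.finite(d))) {
    stop("divergences must be non-empty and finite", call. = FALSE)
  }
  s <- sort(d)
  out <- data.frame(divergence = s,
                    cumulative = seq_along(s) / length(s))
  class(out) <- c("cumulative_divergence", "data.frame")
  out
}

#' @export
plot.cumulative_divergence <- function(x, ...) {
  graphics::plot(x$divergence, x$cumulative, type = "s",
                 xlab = "K-L divergence", ylab = "cumulative density", ...)
  invisible(x)
}

#' Discrimination report from a divergence table
#'
#' Runs the whole discrimination stage: per-query class assignment,
#' assignment probability matrix, necessary-condition flags, and
#' per-class feasibility indices.
#'
#' @param tab a [divergence_table()]; its class columns must be in
#'   class-number order and `query_class` must name one of them.
#' @param mode feasibility convention, see [feasibility_index()].
#' @return Object of class `discrimination_report`: `assignments`
#'   (integer per query), `prob_matrix` (M x M, labelled), `necessary_ok`
#'   (logical per class), `feasibility` (per class), `mode`,
#'   `class_labels`.
#' @export
discrimination_report <- function(tab, mode = c("table4", "eq26")) {
  mode <- match.arg(mode)
  D <- divergence_matrix(tab)
  labels <- colnames(D)
  true_cls <- match(tab$query_class, labels)
  if (anyNA(true_cls)) {
    stop("query_class values must match the divergence table's class columns",
         call. = FALSE)
  }
  assignments <- apply(D, 1L, assign_class)
  P <- probability_matrix(assignments, true_cls, M = length(labels))
  dimnames(P) <- list(true = labels, predicted = labels)
  structure(list(assignments = as.integer(assignments),
                 prob_matrix = P,
                 necessary_ok = stats::setNames(necessary_condition(P),
                                                labels),
                 feasibility = stats::setNames(
                   feasibility_index(diag(P), mode), labels),
                 mode = mode,
                 class_labels = labels),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, digits = 4, ...) {
  cat("Discrimination report (", length(x$class_labels), " classes, ",
      length(x$assignments), " queries)\n", sep = "")
  cat("\nAssignment probability matrix P(nu = i):\n")
  print(round(x$prob_matrix, digits))
  cat("\nNecessary condition (diagonal maximal in its row):\n")
  print(x$necessary_ok)
  cat(sprintf("\nFeasibility index (mode '%s'):\n", x$mode))
  print(round(x$feasibility, digits))
  invisible(x)
}

#' Write a discrimination report to JSON
#'
#' @param report a `discrimination_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(
    class_labels = report$class_labels,
    assignments = report$assignments,
    prob_matrix = unname(apply(report$prob_matrix, 1L, identity,
                               simplify = FALSE)),
    necessary_ok = unname(report$necessary_ok),
    feasibility = unname(report$feasibility),
    mode = report$mode
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
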