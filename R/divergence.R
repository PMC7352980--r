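as_gauss_pair <- function(p) {
  if (inherits(p, "gaussian_fit")) c(p$mu, p$sigma)
  else if (inherits(p, "gmm_fit") && p$K == 1L) c(p$means, p$sds)
  else if (is.numeric(p) && length(p) == 2L) as.numeric(p)
  else stop("expected a gaussian_fit, a K=1 gmm_fit, or c(mu, sigma)",
            call. = FALSE)
}

#' Closed-form Kullback-Leibler divergence between two Gaussians
#'
#' \deqn{D(p \parallel q) = \ln(\sigma_q/\sigma_p) +
#'   \frac{\sigma_p^2 + (\mu_p - \mu_q)^2}{2\sigma_q^2} - \frac12}
#' in nats. In the screening context `p` is the query's ML Gaussian and
#' `q` is a class's single-component Q-distribution.
#'
#' @param p,q Gaussian parameters: a `gaussian_fit`, a `K = 1`
#'   `gmm_fit`, or a numeric `c(mu, sigma)`.
#' @return Non-negative divergence in nats.
#' @examples
#' kl_gaussian_closed(c(0, 2), c(0, 1))   # log(1/2) + 2 - 1/2
#' @export
kl_gaussian_closed <- function(p, q) {
  p <- as_gauss_pair(p); q <- as_gauss_pair(q)
  if (p[2] <= 0 || q[2] <= 0) stop("standard deviations must be positive",
                                   call. = FALSE)
  log(q[2] / p[2]) + (p[2]^2 + (p[1] - q[1])^2) / (2 * q[2]^2) - 0.5
}

#' Kullback-Leibler divergence by numerical quadrature
#'
#' Integrates `p(x) * log(p(x)/q(x))` on `[lower, upper]`, either on a
#' fixed trapezoidal grid (default; deterministic and cheap) or with
#' adaptive Gauss-Kronrod quadrature via [stats::integrate()] when high
#' absolute accuracy is needed on strongly divergent pairs. `q` is
#' floored at a tiny positive value before the logarithm so that
#' vanishing tail density cannot produce infinities; where `p(x) = 0`
#' the integrand is taken as 0.
#'
#' @param p_pdf,q_pdf vectorised density functions.
#' @param lower,upper integration bounds; choose them to cover
#'   essentially all of `p`'s mass (e.g. the score range padded by
#'   several SDs).
#' @param n_grid number of trapezoid points; default 4096.
#' @param floor lower clamp applied to `q` before the log; default
#'   `1e-300`.
#' @param method `"trapezoid"` (default) or `"adaptive"`.
#' @param split_points optional interior points (e.g. the modes of `p`
#'   and `q`) at which the adaptive integral is split, so that features
#'   much narrower than the integration interval are not stepped over.
#' @param log_pdfs when `TRUE`, `p_pdf` and `q_pdf` return log
#'   densities; the integrand `exp(lp) * (lp - lq)` is then formed
#'   without flooring, which keeps far-tail contributions exact where a
#'   linear-scale density would underflow.
#' @return Divergence estimate in nats.
#' @export
kl_numeric <- function(p_pdf, q_pdf, lower, upper, n_grid = 4096,
                       floor = 1e-300,
                       method = c("trapezoid", "adaptive"),
                       split_points = NULL, log_pdfs = FALSE) {
  method <- match.arg(method)
  stopifnot(is.function(p_pdf), is.function(q_pdf), floor > 0,
            upper > lower)
  integrand <- if (log_pdfs) {
    function(x) {
      lp <- p_pdf(x)
      lq <- q_pdf(x)
      if (any(is.na(lp)) || any(is.na(lq))) {
        stop("log density evaluated to NA on the grid", call. = FALSE)
      }
      ifelse(lp > -Inf, exp(lp) * (lp - lq), 0)
    }
  } else function(x) {
    p <- p_pdf(x)
    q <- pmax(q_pdf(x), floor)
    if (any(!is.finite(p)) || any(!is.finite(q))) {
      stop("density evaluated to a non-finite value on the grid",
           call. = FALSE)
    }
    ifelse(p > 0, p * log(p / q), 0)
  }
  if (method == "adaptive") {
    brk <- sort(unique(c(lower, upper,
                         split_points[split_points > lower &
                                        split_points < upper])))
    total <- 0
    for (i in seq_len(length(brk) - 1L)) {
      total <- total + stats::integrate(
        integrand, brk[i], brk[i + 1L], rel.tol = 1e-10,
        abs.tol = 1e-12, subdivisions = 1000L,
        stop.on.error = FALSE)$value
    }
    return(total)
  }
  f <- integrand(seq(lower, upper, length.out = n_grid))
  h <- (upper - lower) / (n_grid - 1)
  h * (sum(f) - (f[1] + f[n_grid]) / 2)
}

#' Divergence between a query's Gaussian and a class's mixture
#'
#' Uses the closed form when the class model has a single component and
#' trapezoidal quadrature otherwise, integrating over the score range
#' padded by six pooled standard deviations on each side.
#'
#' @param query a `gaussian_fit` (the query's ML Gaussian).
#' @param class_fit a `gmm_fit` (the class Q-distribution).
#' @param direction `"query-to-class"` (default, `D(query || class)`),
#'   `"class-to-query"`, or `"symmetric"` (the mean of both).
#' @param score_range nominal support used to build the quadrature
#'   interval; default `c(0, 2)`.
#' @param n_grid,floor quadrature settings, see [kl_numeric()].
#' @return Divergence in nats.
#' @export
kl_query_class <- function(query, class_fit,
                           direction = c("query-to-class",
                                         "class-to-query", "symmetric"),
                           score_range = c(0, 2), n_grid = 4096,
                           floor = 1e-300) {
  direction <- match.arg(direction)
  if (!inherits(query, "gaussian_fit")) {
    stop("`query` must be a gaussian_fit", call. = FALSE)
  }
  if (!inherits(class_fit, "gmm_fit")) {
    stop("`class_fit` must be a gmm_fit", call. = FALSE)
  }
  one_way <- function(a_pdf, b_pdf, closed) {
    if (!is.null(closed)) return(closed())
    pad <- 6 * max(query$sigma, class_fit$sds)
    kl_numeric(a_pdf, b_pdf, score_range[1] - pad, score_range[2] + pad,
               n_grid = n_grid, floor = floor)
  }
  q_pdf <- function(x) stats::dnorm(x, query$mu, query$sigma)
  c_pdf <- function(x) dgmm(x, class_fit$weights, class_fit$means,
                            class_fit$sds)
  closed_ok <- class_fit$K == 1L
  fwd <- function() one_way(q_pdf, c_pdf,
    if (closed_ok) function() kl_gaussian_closed(query, class_fit) else NULL)
  rev <- function() one_way(c_pdf, q_pdf,
    if (closed_ok) function() kl_gaussian_closed(class_fit, query) else NULL)
  switch(direction,
         "query-to-class" = fwd(),
         "class-to-query" = rev(),
         "symmetric" = (fwd() + rev()) / 2)
}

#' Divergence table of queries against all class models
#'
#' Computes `D(query || class)` for every fitted query against every
#' class Q-distribution, the quantity that drives target assignment.
#'
#' @param queries list of `gaussian_fit` objects; each should carry
#'   `query_id` and `query_class` (as produced by fitting
#'   [extract_query_vector()] columns).
#' @param classes named list of `gmm_fit` objects, one per target class;
#'   names are the class labels in class-number order.
#' @param ... passed on to [kl_query_class()] (direction, quadrature
#'   settings, score range).
#' @return Object of class `divergence_table`: a data frame with columns
#'   `query_id`, `query_class`, then one divergence column per target
#'   class.
#' @export
divergence_table <- function(queries, classes, ...) {
  if (is.null(names(classes)) || any(names(classes) == "")) {
    stop("`classes` must be a named list of gmm_fit objects", call. = FALSE)
  }
  rows <- lapply(queries, function(qf) {
    d <- vapply(classes, function(cf) kl_query_class(qf, cf, ...),
                numeric(1))
    c(list(query_id = qf$query_id %||% NA_character_,
           query_class = qf$query_class %||% NA_character_),
      as.list(d))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("divergence_table", "data.frame")
  out
}

#' Numeric part of a divergence table
#' @param tab a `divergence_table`.
#' @return Numeric matrix (queries x classes).
#' @export
divergence_matrix <- function(tab) {
  as.matrix(tab[, setdiff(names(tab), c("query_id", "query_class")),
                drop = FALSE])
}

#' Write a divergence table as delimited text
#' @param tab a `divergence_table`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_divergence_table <- function(tab, path, sep = "\t") {
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
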