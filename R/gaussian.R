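#' Maximum-likelihood Gaussian fit of a query's similarity vector
#'
#' A single query's similarities against one target class are summarised
#' by one Gaussian, fitted by maximum likelihood: mean = sample mean,
#' standard deviation = divide-by-n SD. A single query is assumed simpler
#' than a whole class, so no mixture is used. By default the fit uses the
#' raw similarity vector; `binned = TRUE` instead fits the moments of the
#' 100-bin histogram (midpoints weighted by bin mass), replicating a
#' fully binned pipeline.
#'
#' @param values numeric similarity vector (length >= 2), e.g. from
#'   [extract_query_vector()].
#' @param sigma_floor lower bound applied to the fitted SD; a
#'   zero-variance vector is clamped here and flagged. Default `1e-6`.
#' @param binned fit on the binned density instead of the raw values?
#' @param n_bins bins used when `binned = TRUE`; default 100.
#' @param score_range bin interval when `binned = TRUE`; defaults to the
#'   vector's own range attribute, else `c(0, 2)`.
#' @return Object of class `gaussian_fit`: `mu`, `sigma`, `n`,
#'   `floored` (TRUE when sigma was clamped) plus any `query_id`,
#'   `query_class`, `target_class` attributes carried by `values`.
#' @examples
#' fit_gaussian_ml(c(0.2, 0.4))   # mu 0.3, sigma 0.1
#' @seealso [fit_gmm()], [kl_gaussian_closed()]
#' @export
fit_gaussian_ml <- function(values, sigma_floor = 1e-6, binned = FALSE,
                            n_bins = 100, score_range = NULL) {
  v <- as.numeric(values)
  if (length(v) < 2L) {
    stop("need at least 2 values for a Gaussian fit", call. = FALSE)
  }
  if (any(!is.finite(v))) stop("values contain non-finite entries",
                               call. = FALSE)
  if (binned) {
    d <- query_density(values, n_bins = n_bins,
                       score_range = score_range %||%
                         attr(values, "score_range") %||% c(0, 2))
    mid <- density_midpoints(d)
    mu <- sum(mid * d$masses)
    sigma <- sqrt(sum(d$masses * (mid - mu)^2))
  } else {
    mu <- mean(v)
    sigma <- sqrt(sum((v - mu)^2) / length(v))
  }
  floored <- sigma < sigma_floor
  if (floored) sigma <- sigma_floor
  structure(list(mu = mu, sigma = sigma, n = length(v), floored = floored,
                 query_id = attr(values, "query_id"),
                 query_class = attr(values, "query_class"),
                 target_class = attr(values, "target_class")),
            class = "gaussian_fit")
}

#' Construct Gaussian parameters directly
#'
#' @param mu mean.
#' @param sigma standard deviation (> 0).
#' @return A `gaussian_fit` object without data provenance.
#' @export
gaussian_params <- function(mu, sigma) {
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) {
    stop("need finite mu and positive sigma", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, n = NA_integer_, floored = FALSE,
                 query_id = NULL, query_class = NULL, target_class = NULL),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, digits = 5, ...) {
  lab <- if (!is.null(x$query_id)) sprintf(" for query '%s'", x$query_id)
         else ""
  cat(sprintf("ML Gaussian fit%s: mu = %.*f, sigma = %.*f (n = %s)\n",
              lab, digits, x$mu, digits, x$sigma, x$n))
  if (x$floored) cat("note: sigma clamped at the floor (zero variance)\n")
  invisible(x)
}

#' @export
coef.gaussian_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma)
}

#' @export
predict.gaussian_fit <- function(object, newdata, ...) {
  stats::dnorm(newdata, object$mu, object$sigma)
}
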