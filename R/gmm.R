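#' Control parameters for the EM fit
#'
#' @param tol convergence threshold on the log-likelihood increment
#'   between iterations (nats); default `1e-8`.
#' @param max_iter iteration cap per EM run; default 500.
#' @param seed RNG seed controlling the randomised restarts; the fit is
#'   deterministic given this seed and does not disturb the caller's
#'   random stream.
#' @param n_restarts number of EM runs: the first starts from
#'   quantile-spread means, the rest from seeded random perturbations;
#'   the run with the highest log-likelihood wins. Default 5.
#' @param sigma_floor lower bound on any component standard deviation;
#'   a component shrinking below it is clamped and flagged. Default
#'   `1e-6`.
#' @return A list of class `em_control`.
#' @export
em_control <- function(tol = 1e-8, max_iter = 500, seed = 1L,
                       n_restarts = 5, sigma_floor = 1e-6) {
  stopifnot(tol > 0, max_iter >= 1, n_restarts >= 1, sigma_floor > 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts),
                 sigma_floor = sigma_floor),
            class = "em_control")
}

# log of the mixture density at x, and the per-component log responsibilities
gmm_loglik_matrix <- function(x, weights, means, sds) {
  K <- length(weights)
  n <- length(x)
  lp <- matrix(0, n, K)
  for (k in seq_len(K)) {
    lp[, k] <- log(weights[k]) + stats::dnorm(x, means[k], sds[k],
                                              log = TRUE)
  }
  m <- lp[, 1L]
  if (K > 1L) for (k in 2:K) m <- pmax(m, lp[, k])
  lse <- m + log(rowSums(exp(lp - m)))
  list(log_density = lse, log_weighted = lp)
}

em_run <- function(x, K, means, weights, sds, control) {
  n <- length(x)
  trace <- numeric(0)
  collapsed <- FALSE
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(control$max_iter)) {
    # E-step: responsibilities
    lm <- gmm_loglik_matrix(x, weights, means, sds)
    ll <- sum(lm$log_density)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < control$tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r <- exp(lm$log_weighted - lm$log_density)   # n x K
    nk <- colSums(r)
    nk <- pmax(nk, .Machine$double.xmin)
    # M-step
    weights <- nk / n
    means <- colSums(r * x) / nk
    sds <- sqrt(pmax(colSums(r * x^2) / nk - means^2, 0))
    if (any(sds < control$sigma_floor)) {
      sds <- pmax(sds, control$sigma_floor)
      collapsed <- TRUE
    }
  }
  list(weights = weights, means = means, sds = sds,
       loglik = trace[length(trace)], trace = trace,
       n_iter = length(trace), converged = converged,
       collapsed = collapsed)
}

#' Fit a univariate Gaussian mixture by expectation-maximisation
#'
#' Estimates the representative ("Q") distribution of a target class from
#' its intra-class ligand-pair similarities: a `K`-component mixture
#' \deqn{\sum_{k=1}^{K} \omega_k \, g(x; m_k, \sigma_k)}
#' fitted by EM. Each E-step computes component responsibilities, each
#' M-step re-estimates weights, means and standard deviations; iteration
#' stops when the log-likelihood increment drops below `control$tol`.
#' Several restarts guard against poor local optima: the first start
#' places component means at evenly spaced sample quantiles with equal
#' weights and the pooled SD, further starts perturb the means with
#' seeded noise, and the best log-likelihood wins. For `K = 1` the fit is
#' the closed-form maximum-likelihood Gaussian (sample mean,
#' divide-by-n SD).
#'
#' The Gaussians are not truncated to the similarity range even though
#' the data live in a bounded interval; the fitted class distributions
#' sit well inside the range, where truncation mass is negligible.
#'
#' @param x numeric vector of similarity values (`length(x) >= K`).
#' @param K number of mixture components (>= 1); typical choices 1, 3, 7.
#' @param control an [em_control()] list.
#' @return Object of class `gmm_fit`: `weights`, `means`, `sds` (sorted
#'   by mean), `K`, `loglik`, `trace` (per-iteration log-likelihood of
#'   the winning run, non-decreasing), `n_iter`, `converged`,
#'   `collapsed` (any component clamped at the sigma floor) and `n`.
#' @examples
#' x <- c(rnorm(300, 0.4, 0.05), rnorm(700, 0.6, 0.08))
#' fit <- fit_gmm(x, K = 2)
#' coef(fit)
#' @seealso [fit_gaussian_ml()], [dgmm()], [kl_query_class()]
#' @export
fit_gmm <- function(x, K = 1, control = em_control()) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  if (length(x) < K) {
    stop(sprintf("need at least K = %d values, got %d", K, length(x)),
         call. = FALSE)
  }
  n <- length(x)
  if (K == 1L) {
    mu <- mean(x)
    sigma <- max(sqrt(sum((x - mu)^2) / n), control$sigma_floor)
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    return(structure(list(weights = 1, means = mu, sds = sigma, K = 1L,
                          loglik = ll, trace = ll, n_iter = 1L,
                          converged = TRUE,
                          collapsed = sigma <= control$sigma_floor,
                          n = n),
                     class = "gmm_fit"))
  }
  pooled_sd <- max(stats::sd(x), control$sigma_floor)
  probs <- seq(0, 1, length.out = K + 2L)[2L:(K + 1L)]
  base_means <- as.numeric(stats::quantile(x, probs, names = FALSE))
  best <- NULL
  with_seed(control$seed, {
    for (r in seq_len(control$n_restarts)) {
      means0 <- if (r == 1L) base_means else {
        sort(base_means + stats::rnorm(K, 0, pooled_sd / 2))
      }
      fit <- em_run(x, K, means = means0,
                    weights = rep(1 / K, K),
                    sds = rep(pooled_sd, K), control = control)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (!best$converged) {
    warning("EM did not converge within max_iter; returning best parameters",
            call. = FALSE)
  }
  ord <- order(best$means)
  structure(list(weights = best$weights[ord], means = best$means[ord],
                 sds = best$sds[ord], K = K,
                 loglik = best$loglik, trace = best$trace,
                 n_iter = best$n_iter, converged = best$converged,
                 collapsed = best$collapsed, n = n),
            class = "gmm_fit")
}

#' Gaussian mixture density
#'
#' @param x numeric vector of evaluation points (anywhere on the real
#'   line).
#' @param weights,means,sds mixture parameters; weights must sum to 1.
#' @return `sum_k weights[k] * dnorm(x, means[k], sds[k])` evaluated
#'   pointwise.
#' @export
dgmm <- function(x, weights, means, sds) {
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("mixture weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(sds <= 0)) stop("component sds must be positive", call. = FALSE)
  y <- numeric(length(x))
  for (k in seq_along(weights)) {
    y <- y + weights[k] * stats::dnorm(x, means[k], sds[k])
  }
  y
}

#' Evaluate a fitted mixture's density
#'
#' @param object a `gmm_fit`.
#' @param newdata evaluation points; defaults to 512 points over the
#'   fitted mean +/- 4 pooled SD.
#' @param ... unused.
#' @return Numeric vector of density values.
#' @export
predict.gmm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    lo <- min(object$means - 4 * object$sds)
    hi <- max(object$means + 4 * object$sds)
    newdata <- seq(lo, hi, length.out = 512)
  }
  dgmm(newdata, object$weights, object$means, object$sds)
}

#' @export
print.gmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Gaussian mixture fit (EM), K = %d, n = %d\n", x$K, x$n))
  print(round(coef(x), digits))
  cat(sprintf("log-likelihood %.4f after %d iteration(s)%s\n",
              x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  if (x$collapsed) cat("note: a component sd was clamped at the floor\n")
  invisible(x)
}

#' @export
coef.gmm_fit <- function(object, ...) {
  cbind(weight = object$weights, mean = object$means, sd = object$sds)
}

#' @export
logLik.gmm_fit <- function(object, ...) {
  structure(object$loglik, df = 3 * object$K - 1, nobs = object$n,
            class = "logLik")
}

#' @export
simulate.gmm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  expr <- quote({
    k <- sample.int(object$K, nsim, replace = TRUE, prob = object$weights)
    stats::rnorm(nsim, object$means[k], object$sds[k])
  })
  if (is.null(seed)) eval(expr) else with_seed(seed, eval(expr))
}

#' @export
plot.gmm_fit <- function(x, data = NULL, n_grid = 512, ...) {
  lo <- min(x$means - 4 * x$sds)
  hi <- max(x$means + 4 * x$sds)
  g <- seq(lo, hi, length.out = n_grid)
  if (!is.null(data)) {
    graphics::hist(data, breaks = 50, freq = FALSE,
                   main = "mixture fit", xlab = "similarity", ...)
    graphics::lines(g, predict(x, g), col = "red", lwd = 2)
  } else {
    graphics::plot(g, predict(x, g), type = "l", xlab = "similarity",
                   ylab = "density", ...)
  }
  invisible(x)
}

#' Serialise a fitted mixture to JSON
#'
#' @param fit a `gmm_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmm_json <- function(fit, path) {
  jsonlite::write_json(list(K = fit$K, weights = fit$weights,
                            means = fit$means, sds = fit$sds,
                            loglik = fit$loglik, converged = fit$converged,
                            n_iter = fit$n_iter, n = fit$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted mixture from JSON
#'
#' @param path path written by [write_gmm_json()].
#' @return A `gmm_fit`.
#' @export
read_gmm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = j$weights, means = j$means, sds = j$sds,
                 K = as.integer(j$K), loglik = j$loglik,
                 trace = j$loglik, n_iter = as.integer(j$n_iter),
                 converged = isTRUE(j$converged), collapsed = FALSE,
                 n = as.integer(j$n)),
            class = "gmm_fit")
}
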