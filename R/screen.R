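#' Fit the full query-versus-class screening model
#'
#' The central fitting function. Given a class-annotated similarity
#' matrix it runs the three-step procedure:
#' \enumerate{
#'   \item fit each target class's representative Q-distribution — a
#'     `K`-component Gaussian mixture fitted by EM to the intra-class
#'     ligand-pair similarities (self-pairs excluded by default);
#'   \item fit each query's similarity vector against each class with a
#'     maximum-likelihood Gaussian;
#'   \item score every query-class pair by Kullback-Leibler divergence,
#'     assign each query to its minimal-divergence class, and summarise
#'     discriminability by the assignment probability matrix,
#'     necessary-condition flags and feasibility indices.
#' }
#'
#' @param x a [similarity_matrix()] (square, rows and columns over the
#'   same conformer set), or a path to a delimited matrix file (then
#'   `annotations` is required).
#' @param annotations annotation table/path when `x` is a file path.
#' @param K integer vector of mixture sizes to fit (e.g. `c(1, 3, 7)`);
#'   each gets its own divergence table and report.
#' @param control [em_control()] settings for the EM fits.
#' @param include_diagonal keep intra-class self-pairs in the class
#'   distributions? Default `FALSE`.
#' @param direction divergence direction, see [kl_query_class()].
#' @param feasibility_mode convention for [feasibility_index()].
#' @param class_bins,query_bins histogram resolutions for the stored
#'   class and query densities (defaults 1000 and 100).
#' @param queries `"all"` (every column is a query) or an integer number
#'   of query columns sampled per class (seeded by `control$seed`).
#' @return Object of class `kl_screen` with components `class_labels`,
#'   `K`, `class_values` (intra-class similarity vectors),
#'   `class_densities`, `class_models` (per K, named list of
#'   [fit_gmm()] fits), `query_params` (per target class, data frame of
#'   per-query `mu`/`sigma`), `divergences` (per K,
#'   [divergence_table()]), `reports` (per K,
#'   [discrimination_report()]), and `settings`.
#' @examples
#' gen <- generate_matrix(synthetic_spec(seed = 7))
#' scr <- kl_screen(gen$matrix, K = 1)
#' scr$reports[[1]]$feasibility
#' @seealso [recovery_experiment()], [run_pipeline()]
#' @export
kl_screen <- function(x, annotations = NULL, K = 1,
                      control = em_control(), include_diagonal = FALSE,
                      direction = c("query-to-class", "class-to-query",
                                    "symmetric"),
                      feasibility_mode = c("table4", "eq26"),
                      class_bins = 1000, query_bins = 100,
                      queries = "all") {
  direction <- match.arg(direction)
  feasibility_mode <- match.arg(feasibility_mode)
  if (is.character(x)) {
    if (is.null(annotations)) {
      stop("reading a matrix from file requires `annotations`",
           call. = FALSE)
    }
    x <- read_similarity_matrix(x, annotations)
  }
  stopifnot(inherits(x, "similarity_matrix"))
  if (nrow(x) != ncol(x)) {
    stop("screening requires a square matrix over one conformer set",
         call. = FALSE)
  }
  K <- sort(unique(as.integer(K)))
  if (any(K < 1L)) stop("all K must be >= 1", call. = FALSE)
  rng <- attr(x, "score_range")
  labels <- names(class_numbers(x))
  col_class <- attr(x, "col_class")
  row_class <- attr(x, "row_class")
  v <- unclass(x)
  attributes(v) <- list(dim = dim(v))

  # Step 1: class values, densities, Q-distributions
  class_values <- lapply(labels, function(lab) {
    ri <- which(row_class == lab)
    ci <- which(col_class == lab)
    blk <- v[ri, ci, drop = FALSE]
    if (include_diagonal) as.vector(blk)
    else as.vector(blk[outer(ri, ci, `!=`)])
  })
  names(class_values) <- labels
  class_densities <- lapply(class_values, class_density,
                            n_bins = class_bins, score_range = rng)
  class_models <- lapply(K, function(k) {
    fits <- lapply(class_values, fit_gmm, K = k, control = control)
    names(fits) <- labels
    fits
  })
  names(class_models) <- paste0("K", K)

  # Step 2: per-query ML Gaussians against every class, computed from
  # column sums (identical to fit_gaussian_ml on each extracted vector)
  qcols <- seq_len(ncol(v))
  if (is.numeric(queries)) {
    qcols <- with_seed(control$seed, unlist(lapply(labels, function(lab) {
      cand <- which(col_class == lab)
      sort(sample(cand, min(queries, length(cand))))
    })))
  }
  qids <- colnames(x)[qcols]
  qcls <- col_class[qcols]
  query_params <- lapply(labels, function(lab) {
    ri <- which(row_class == lab)
    sub <- v[ri, qcols, drop = FALSE]
    s1 <- colSums(sub)
    s2 <- colSums(sub^2)
    n <- rep(length(ri), length(qcols))
    self <- which(qcls == lab)
    if (length(self)) {
      dg <- v[cbind(qcols[self], qcols[self])]
      s1[self] <- s1[self] - dg
      s2[self] <- s2[self] - dg^2
      n[self] <- n[self] - 1L
    }
    mu <- s1 / n
    sigma <- sqrt(pmax(s2 / n - mu^2, 0))
    sigma <- pmax(sigma, 1e-6)
    data.frame(query_id = qids, query_class = qcls, mu = mu,
               sigma = sigma, n = n, stringsAsFactors = FALSE)
  })
  names(query_params) <- labels

  # Step 3: divergence tables and discrimination reports per K
  divergences <- lapply(seq_along(K), function(ki) {
    D <- vapply(labels, function(lab) {
      cf <- class_models[[ki]][[lab]]
      qp <- query_params[[lab]]
      kl_to_class(qp$mu, qp$sigma, cf, direction = direction,
                  score_range = rng)
    }, numeric(length(qcols)))
    D <- matrix(D, nrow = length(qcols), ncol = length(labels),
                dimnames = list(NULL, labels))
    out <- cbind(data.frame(query_id = qids, query_class = qcls,
                            stringsAsFactors = FALSE),
                 as.data.frame(D))
    class(out) <- c("divergence_table", "data.frame")
    out
  })
  names(divergences) <- paste0("K", K)
  reports <- lapply(divergences, discrimination_report,
                    mode = feasibility_mode)

  structure(list(class_labels = labels, K = K,
                 class_values = class_values,
                 class_densities = class_densities,
                 class_models = class_models,
                 query_params = query_params,
                 divergences = divergences,
                 reports = reports,
                 settings = list(direction = direction,
                                 feasibility_mode = feasibility_mode,
                                 include_diagonal = include_diagonal,
                                 class_bins = class_bins,
                                 query_bins = query_bins,
                                 score_range = rng,
                                 seed = control$seed,
                                 control = control)),
            class = "kl_screen")
}

# Divergence of many query Gaussians against one class model: closed form
# when K = 1, shared-grid trapezoidal quadrature otherwise. Matches
# kl_query_class() applied query by query.
kl_to_class <- function(mu, sigma, class_fit, direction = "query-to-class",
                        score_range = c(0, 2), n_grid = 4096,
                        floor = 1e-300) {
  if (class_fit$K == 1L && direction == "query-to-class") {
    m2 <- class_fit$means[1]; s2 <- class_fit$sds[1]
    return(log(s2 / sigma) + (sigma^2 + (mu - m2)^2) / (2 * s2^2) - 0.5)
  }
  vapply(seq_along(mu), function(i) {
    kl_query_class(gaussian_params(mu[i], sigma[i]), class_fit,
                   direction = direction, score_range = score_range,
                   n_grid = n_grid, floor = floor)
  }, numeric(1))
}

#' @export
print.kl_screen <- function(x, ...) {
  cat(sprintf("kl_screen fit: %d classes (%s), %d queries, K = %s\n",
              length(x$class_labels),
              paste(x$class_labels, collapse = ", "),
              nrow(x$divergences[[1]]),
              paste(x$K, collapse = ", ")))
  for (k in names(x$reports)) {
    r <- x$reports[[k]]
    cat(sprintf("  %s: feasibility %s\n", k,
                paste(sprintf("%s=%.3f", r$class_labels,
                              r$feasibility), collapse = " ")))
  }
  invisible(x)
}

#' @export
summary.kl_screen <- function(object, ...) {
  cat("Query-versus-class screening by K-L divergence\n\n")
  for (ki in seq_along(object$K)) {
    cat(sprintf("== K = %d ==\n", object$K[ki]))
    cat("Class models (weight / mean / sd):\n")
    for (lab in object$class_labels) {
      f <- object$class_models[[ki]][[lab]]
      cat(sprintf("  %-6s", lab))
      cat(paste(sprintf("(%.3f, %.4f, %.4f)", f$weights, f$means, f$sds),
                collapse = " "), "\n")
    }
    print(object$reports[[ki]])
    cat("\n")
  }
  invisible(object)
}

#' @export
coef.kl_screen <- function(object, K = object$K[1], ...) {
  fits <- object$class_models[[paste0("K", K)]]
  do.call(rbind, lapply(names(fits), function(lab) {
    cbind(data.frame(class = lab, component = seq_len(fits[[lab]]$K)),
          as.data.frame(coef(fits[[lab]])))
  }))
}

#' Cumulative divergence curves of a fitted screen
#'
#' Plots, for one target class's Q-distribution, the empirical
#' cumulative distribution of divergences from the queries of each
#' class — the curves that visualise how sharply the target separates
#' its own ligands from the rest.
#'
#' @param x a `kl_screen`.
#' @param target_class class label whose Q-distribution is the
#'   reference; default the first class.
#' @param K which mixture size; default the first fitted.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.kl_screen <- function(x, target_class = x$class_labels[1],
                           K = x$K[1], ...) {
  tab <- x$divergences[[paste0("K", K)]]
  cols <- grDevices::hcl.colors(length(x$class_labels), "Dark 3")
  first <- TRUE
  for (i in seq_along(x$class_labels)) {
    qc <- x$class_labels[i]
    cd <- cumulative_divergence(
      tab[tab$query_class == qc, target_class])
    if (first) {
      graphics::plot(cd$divergence, cd$cumulative, type = "s",
                     col = cols[i], xlab = "K-L divergence",
                     ylab = "cumulative density",
                     main = sprintf("queries vs %s (K = %d)",
                                    target_class, K), ...)
      first <- FALSE
    } else {
      graphics::lines(cd$divergence, cd$cumulative, type = "s",
                      col = cols[i])
    }
  }
  graphics::legend("bottomright", legend = x$class_labels, col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Predict the target class of new queries
#'
#' Scores a new (possibly unannotated) query compound against the fitted
#' class models: its similarity vector against each class is fitted by an
#' ML Gaussian and the divergence to each Q-distribution computed; the
#' predicted class minimises the divergence.
#'
#' @param object a `kl_screen`.
#' @param newdata a named list (one element per class label) of numeric
#'   similarity vectors between the new query and that class's ligands;
#'   or a list of such lists for several queries.
#' @param K which fitted mixture size to score against; default the
#'   first.
#' @param ... unused.
#' @return Data frame with one row per query: divergence per class,
#'   `assigned` (class label) and `assigned_number`.
#' @export
predict.kl_screen <- function(object, newdata, K = object$K[1], ...) {
  if (!is.list(newdata)) stop("`newdata` must be a list", call. = FALSE)
  if (!is.list(newdata[[1]])) newdata <- list(newdata)
  fits <- object$class_models[[paste0("K", K)]]
  rows <- lapply(newdata, function(q) {
    if (!all(object$class_labels %in% names(q))) {
      stop("newdata must supply a similarity vector for every class",
           call. = FALSE)
    }
    d <- vapply(object$class_labels, function(lab) {
      kl_query_class(fit_gaussian_ml(q[[lab]]), fits[[lab]],
                     direction = object$settings$direction,
                     score_range = object$settings$score_range)
    }, numeric(1))
    i <- assign_class(d)
    c(as.list(d), list(assigned = object$class_labels[i],
                       assigned_number = i))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  rownames(out) <- names(newdata) %||% NULL
  out
}
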