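#' Binned probability density of similarity values
#'
#' Converts a sample of Jaccard-Tanimoto coefficients into a binned
#' univariate probability density over the score range: `n_bins` equal
#' bins, each carrying the fraction of values falling in it, so the bin
#' masses sum to one. Bins are half-open `[x_k, x_{k+1})` with the last
#' bin right-closed, so a value at the range maximum is counted exactly
#' once. Class distributions conventionally use 1000 bins; per-query
#' distributions use 100 (see [query_density()]).
#'
#' @param values numeric vector of similarity coefficients, all inside
#'   `score_range`.
#' @param n_bins number of equal-width bins (>= 2); default 1000.
#' @param score_range closed interval spanned by the bins; default
#'   `c(0, 2)`.
#' @return Object of class `hist_density` with fields `bin_edges`
#'   (length `n_bins + 1`), `masses` (probability mass per bin, sums to 1),
#'   `delta_x` (bin width) and `n_samples`.
#' @examples
#' d <- class_density(runif(500), n_bins = 50, score_range = c(0, 1))
#' sum(d$masses)
#' @export
class_density <- function(values, n_bins = 1000, score_range = c(0, 2)) {
  score_range <- check_score_range(score_range)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no similarity values supplied",
                                 call. = FALSE)
  if (!is.numeric(n_bins) || n_bins < 2) stop("`n_bins` must be >= 2",
                                              call. = FALSE)
  n_bins <- as.integer(n_bins)
  check_values_in_range(values, score_range, "similarity values")
  delta_x <- diff(score_range) / n_bins
  edges <- score_range[1] + delta_x * (0:n_bins)
  # bin by comparison against the edge values themselves (not by division)
  # so boundary values land per the [x_k, x_{k+1}) convention exactly
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(
    bin_edges = edges,
    masses = counts / length(values),
    delta_x = delta_x,
    n_samples = length(values)
  ), class = "hist_density")
}

#' Binned density of a single query's similarity vector
#'
#' Same construction as [class_density()], applied to one query's column
#' of similarities against a target class; the conventional bin count for
#' queries is 100.
#'
#' @param vector a [extract_query_vector()] result or plain numeric
#'   vector.
#' @param n_bins number of bins; default 100.
#' @param score_range bin interval; defaults to the vector's own
#'   `score_range` attribute, else `c(0, 2)`.
#' @return A `hist_density`.
#' @export
query_density <- function(vector, n_bins = 100, score_range = NULL) {
  score_range <- score_range %||% attr(vector, "score_range") %||% c(0, 2)
  class_density(as.numeric(vector), n_bins = n_bins,
                score_range = score_range)
}

#' @export
print.hist_density <- function(x, ...) {
  cat(sprintf(
    "hist_density: %d bins of width %g over [%g, %g], n = %d values\n",
    length(x$masses), x$delta_x, x$bin_edges[1],
    x$bin_edges[length(x$bin_edges)], x$n_samples))
  invisible(x)
}

#' Bin midpoints of a binned density
#' @param d a `hist_density`.
#' @return Numeric vector of bin midpoints.
#' @export
density_midpoints <- function(d) {
  (d$bin_edges[-1] + d$bin_edges[-length(d$bin_edges)]) / 2
}

#' Density height per bin
#'
#' The stored quantity is probability mass per bin; the corresponding
#' density height is mass divided by the bin width, which is what
#' histogram figures plot.
#'
#' @param d a `hist_density`.
#' @return Numeric vector, `masses / delta_x`.
#' @export
density_height <- function(d) d$masses / d$delta_x

#' Export a binned density as a two-column table
#'
#' @param d a `hist_density`.
#' @param path output path.
#' @param what `"mass"` (default) or `"height"` for the second column.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_density <- function(d, path, what = c("mass", "height"), sep = "\t") {
  what <- match.arg(what)
  y <- if (what == "mass") d$masses else density_height(d)
  utils::write.table(
    data.frame(midpoint = density_midpoints(d), value = y),
    path, sep = sep, quote = FALSE, row.names = FALSE,
    col.names = c("midpoint", what))
  invisible(path)
}

#' @export
plot.hist_density <- function(x, what = c("height", "mass"), ...) {
  what <- match.arg(what)
  y <- if (what == "height") density_height(x) else x$masses
  graphics::plot(density_midpoints(x), y, type = "h",
                 xlab = "similarity", ylab = what, ...)
  invisible(x)
}
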