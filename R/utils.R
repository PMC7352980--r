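# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

check_score_range <- function(score_range) {
  if (!is.numeric(score_range) || length(score_range) != 2L ||
      any(!is.finite(score_range)) || score_range[1] >= score_range[2]) {
    stop("`score_range` must be two finite increasing numbers", call. = FALSE)
  }
  as.numeric(score_range)
}

check_values_in_range <- function(values, score_range, what = "values") {
  if (any(!is.finite(values))) {
    stop(sprintf("%s contain non-finite entries", what), call. = FALSE)
  }
  bad <- values < score_range[1] | values > score_range[2]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "%s contain entries outside [%g, %g] (first offending value %g at position %d)",
      what, score_range[1], score_range[2], values[i], i), call. = FALSE)
  }
  invisible(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
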