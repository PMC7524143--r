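# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_counts <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) <= 0) stop("empty community", call. = FALSE)
  counts
}

#' Standardize a numeric vector to mean 0, SD 1
#'
#' Centres and scales with the sample standard deviation (denominator
#' \eqn{n - 1}), the convention used for diversity indices and score inputs
#' throughout the package.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return numeric vector of the same length with mean 0 and SD 1.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero variance", call. = FALSE)
  as.numeric((values - mean(values)) / s)
}
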