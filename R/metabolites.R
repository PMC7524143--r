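# Metabolite panel preprocessing: run-day minimum imputation followed by
# rank-based inverse-normal transformation. The state flag enforces that
# order: raw -> imputed -> inverse_normalized.

#' Construct a metabolite matrix
#'
#' Bundles a subjects-by-metabolites value matrix with its run-day (batch)
#' labels and a processing-state flag. Missing measurements are `NA` in
#' `values`.
#'
#' @param values numeric matrix, subjects in rows (rownames = subject IDs),
#'   metabolites in columns (colnames = metabolite IDs). Raw mass-spec
#'   intensities are non-negative; transformed values are unrestricted.
#' @param runday character or factor of length `nrow(values)`: the
#'   measurement batch of each subject.
#' @param state processing state, one of `"raw"`, `"imputed"`,
#'   `"inverse_normalized"`.
#' @param pathway optional character vector (length `ncol`) of super-pathway
#'   class labels (amino acid, xenobiotic, steroid, ...).
#' @return object of class `metab_matrix`.
#' @export
metabolite_matrix <- function(values, runday,
                              state = c("raw", "imputed", "inverse_normalized"),
                              pathway = NULL) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (length(runday) != nrow(values))
    stop("runday must have one label per subject (row)", call. = FALSE)
  if (is.null(colnames(values)))
    stop("values must have metabolite IDs as colnames", call. = FALSE)
  if (!is.null(pathway) && length(pathway) != ncol(values))
    stop("pathway must have one label per metabolite", call. = FALSE)
  structure(list(values = values, runday = as.character(runday),
                 state = state, pathway = pathway),
            class = "metab_matrix")
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf("<metab_matrix> %d subjects x %d metabolites, state = %s\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("  run-days: %d, missing cells: %d\n",
              length(unique(x$runday)), sum(is.na(x$values))))
  invisible(x)
}

#' Impute missing metabolite values with the run-day minimum
#'
#' Each missing cell is replaced by the minimum observed value of that
#' metabolite within the same run-day, the natural fill when missingness is
#' driven by detection limits (left-censoring).
#'
#' @param m `metab_matrix` in state `"raw"`.
#' @return `metab_matrix` with no missing values and state `"imputed"`.
#' @export
impute_runday_min <- function(m) {
  stopifnot(inherits(m, "metab_matrix"))
  if (m$state != "raw")
    stop("impute_runday_min expects state 'raw', got '", m$state, "'",
         call. = FALSE)
  v <- m$values
  bad <- character(0)
  for (rd in unique(m$runday)) {
    rows <- which(m$runday == rd)
    block <- v[rows, , drop = FALSE]
    miss <- is.na(block)
    if (!any(miss)) next
    mins <- unname(suppressWarnings(apply(block, 2L, min, na.rm = TRUE)))
    need <- which(colSums(miss) > 0L)
    empty <- need[!is.finite(mins[need])]
    if (length(empty))
      bad <- c(bad, paste0(rd, ":", colnames(v)[empty]))
    for (j in setdiff(need, empty))
      block[miss[, j], j] <- mins[j]
    v[rows, ] <- block
  }
  if (length(bad))
    stop("run-day x metabolite cells with no observed values: ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- m
  out$values <- v
  out$state <- "imputed"
  out
}

#' Rank-based inverse-normal transformation
#'
#' Maps a column onto standard-normal quantiles by rank, using the Blom
#' offset: \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}. Ties receive the average
#' rank, so the transform is deterministic and equivariant to any strictly
#' monotone distortion of the input.
#'
#' @param column numeric vector, n >= 3, not constant, no missing values.
#' @return transformed numeric vector, approximately standard normal.
#' @export
inverse_normal <- function(column) {
  if (anyNA(column)) stop("missing values: impute first", call. = FALSE)
  n <- length(column)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  if (length(unique(column)) < 2L)
    stop("untransformable: constant", call. = FALSE)
  r <- rank(column, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Inverse-normal transform every metabolite column
#'
#' @param m `metab_matrix` in state `"imputed"`.
#' @return `metab_matrix` with state `"inverse_normalized"`.
#' @export
inverse_normal_transform <- function(m) {
  stopifnot(inherits(m, "metab_matrix"))
  if (m$state != "imputed")
    stop("inverse_normal_transform expects state 'imputed', got '",
         m$state, "' (pipeline order is impute, then transform)",
         call. = FALSE)
  out <- m
  out$values <- apply(m$values, 2L, inverse_normal)
  dimnames(out$values) <- dimnames(m$values)
  out$state <- "inverse_normalized"
  out
}

#' Full metabolite preprocessing: impute, then inverse-normalize
#'
#' @param m `metab_matrix` in state `"raw"`.
#' @return `metab_matrix` in state `"inverse_normalized"`.
#' @export
prep_metabolites <- function(m) {
  inverse_normal_transform(impute_runday_min(m))
}
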