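# Alpha diversity: closed-form indices and rarefaction averaging.

#' Shannon diversity index
#'
#' Entropy of the taxon relative-abundance distribution,
#' \eqn{H = -\sum_i p_i \log_b p_i} over taxa with nonzero counts. The
#' default base 2 (bits) follows the QIIME 1.9 convention, which puts a
#' typical 16S gut community in the 3-6 range.
#'
#' @param counts non-negative numeric vector of per-taxon counts, sum > 0.
#' @param base logarithm base; 2 for bits (default), `exp(1)` for nats.
#' @return Shannon index (scalar, >= 0).
#' @examples
#' shannon(c(25, 25, 25, 25))  # 2 bits
#' @export
shannon <- function(counts, base = 2) {
  counts <- check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Simpson diversity index
#'
#' \eqn{D = 1 - \sum_i p_i^2}: the probability that two reads drawn at
#' random belong to different taxa.
#'
#' @inheritParams shannon
#' @return Simpson index in \[0, 1).
#' @export
simpson <- function(counts) {
  counts <- check_counts(counts)
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Chao1 richness estimator
#'
#' Augments the observed richness with an estimate of unseen taxa from the
#' singleton and doubleton counts. The default is the bias-corrected form
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}, which stays finite when
#' no doubletons are present; `bias_corrected = FALSE` gives the classic
#' \eqn{S_{obs} + F_1^2 / (2 F_2)}.
#'
#' @inheritParams shannon
#' @param bias_corrected logical; use the bias-corrected form (default).
#' @return estimated richness, always >= the observed taxon count.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) {
      if (f1 == 0) return(s_obs)
      return(s_obs + f1 * (f1 - 1) / 2)
    }
    s_obs + f1^2 / (2 * f2)
  }
}

# Subsample a count vector WITHOUT replacement to exactly `depth` reads.
# Reads are indexed 1..N; OTU j owns the index interval (cs[j-1], cs[j]].
rarefy_counts <- function(counts, depth) {
  total <- sum(counts)
  stopifnot(total >= depth)
  cs <- cumsum(counts)
  idx <- sample.int(total, depth)
  tabulate(findInterval(idx, c(0, cs), left.open = TRUE), nbins = length(counts))
}

#' Rarefaction-averaged alpha diversity
#'
#' Repeatedly subsamples each subject's OTU counts without replacement to a
#' common depth, computes Shannon, Simpson, observed-OTU and Chao1 indices
#' on every subsample, and reports the per-subject mean across repetitions.
#' Subjects with fewer total reads than `depth` are dropped (standard
#' rarefaction semantics), and each retained index is also returned
#' standardized to mean 0, SD 1 across subjects.
#'
#' @param otu_table integer matrix, subjects in rows (rownames = subject
#'   IDs), OTUs in columns; no negative entries.
#' @param depth rarefaction depth (reads per subsample), default 10000.
#' @param reps number of independent subsamples per subject, default 50.
#' @param seed RNG seed for the subsampling (optional).
#' @param base Shannon logarithm base, default 2.
#' @return data.frame with one row per retained subject: `subject_id`,
#'   `shannon`, `simpson`, `observed_otus`, `chao1` and `*_std` columns;
#'   attributes `depth`, `reps`, `n_dropped`, `dropped_ids`.
#' @export
rarefied_alpha <- function(otu_table, depth = 10000, reps = 50, seed = NULL,
                           base = 2) {
  if (!is.matrix(otu_table)) otu_table <- as.matrix(otu_table)
  if (any(otu_table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  ids <- rownames(otu_table)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(otu_table)))
  totals <- rowSums(otu_table)
  keep <- totals >= depth
  if (!any(keep)) stop("all subjects below rarefaction depth", call. = FALSE)
  out <- with_seed(seed, {
    res <- matrix(NA_real_, sum(keep), 4L,
                  dimnames = list(NULL, c("shannon", "simpson",
                                          "observed_otus", "chao1")))
    rows <- which(keep)
    for (k in seq_along(rows)) {
      cnt <- otu_table[rows[k], ]
      acc <- matrix(NA_real_, reps, 4L)
      for (r in seq_len(reps)) {
        rc <- rarefy_counts(cnt, depth)
        p <- rc[rc > 0] / depth
        acc[r, 1L] <- -sum(p * log(p, base = base))
        acc[r, 2L] <- 1 - sum(p^2)
        acc[r, 3L] <- length(p)
        f1 <- sum(rc == 1); f2 <- sum(rc == 2)
        acc[r, 4L] <- length(p) + f1 * (f1 - 1) / (2 * (f2 + 1))
      }
      res[k, ] <- colMeans(acc)
    }
    res
  })
  df <- data.frame(subject_id = ids[keep], out,
                   stringsAsFactors = FALSE, row.names = NULL)
  for (m in c("shannon", "simpson", "observed_otus", "chao1"))
    df[[paste0(m, "_std")]] <- if (nrow(df) >= 2 && stats::sd(df[[m]]) > 0)
      standardize(df[[m]]) else NA_real_
  attr(df, "depth") <- depth
  attr(df, "reps") <- reps
  attr(df, "n_dropped") <- sum(!keep)
  attr(df, "dropped_ids") <- ids[!keep]
  df
}

#' Log-transformed relative abundances with pseudocount
#'
#' Converts an OTU count table to log10 relative abundances, replacing zero
#' proportions with a small pseudocount before taking logs. This is the
#' transform used for taxon-level abundance analyses; it is deliberately
#' *not* part of the diversity computation, which operates on raw rarefied
#' counts.
#'
#' @inheritParams rarefied_alpha
#' @param pseudo value added in place of zero proportions, default `1e-6`.
#' @return numeric matrix of log10 relative abundances.
#' @export
log_relative_abundance <- function(otu_table, pseudo = 1e-6) {
  if (!is.matrix(otu_table)) otu_table <- as.matrix(otu_table)
  if (any(rowSums(otu_table) <= 0)) stop("empty community", call. = FALSE)
  p <- otu_table / rowSums(otu_table)
  log10(p + pseudo)
}
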