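#' Maximum fold change of a relative profile
#'
#' Ratio between the highest and lowest value of a profile across time
#' points (linear scale), a measure of regulation amplitude. Missing values
#' are ignored; at least two positive values are required.
#'
#' @param profile Numeric vector of linear relative values.
#' @return Fold change >= 1.
#' @examples
#' max_fold_change(c(1, 2, 4, 2)) # 4
#' @export
max_fold_change <- function(profile) {
  v <- profile[!is.na(profile)]
  if (length(v) < 2L)
    stop("need at least 2 non-missing values")
  if (any(v <= 0))
    stop("profile values must be positive on the linear scale")
  max(v) / min(v)
}

#' Correlation between transcription and expression profiles
#'
#' Pearson correlation computed on the log2 profiles (the scale on which
#' array ratios are analyzed). Profiles with zero variance have an
#' undefined correlation, reported as `NA`.
#'
#' @param f,y Log2-ratio profiles of equal length without missing values.
#' @param method Correlation method (default `"pearson"`).
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
profile_correlation <- function(f, y, method = "pearson") {
  if (length(f) != length(y)) stop("profiles must have equal length")
  if (anyNA(f) || anyNA(y)) stop("profiles must be complete")
  if (sd(f) == 0 || sd(y) == 0) return(NA_real_)
  cor(f, y, method = method)
}

#' Timing of the transcriptional response
#'
#' For each consecutive pair of time points, the variance across genes of
#' the log2 fold change in transcription over that interval. The interval
#' with the largest variance marks when most transcriptional regulation is
#' launched.
#'
#' @param f Gene-by-time matrix of log2-ratio transcription profiles
#'   (complete).
#' @param time Time grid (min); defaults to column count order.
#' @return Data frame with columns `interval`, `t_from`, `t_to`,
#'   `variance`; the index of the most variable interval is attached as
#'   attribute `"argmax_interval"`.
#' @export
transition_variance <- function(f, time = NULL) {
  stopifnot(is.matrix(f))
  if (ncol(f) < 2L) stop("need at least 2 time points")
  if (anyNA(f)) stop("transcription table must be complete")
  time <- time %||% seq_len(ncol(f))
  d <- f[, -1L, drop = FALSE] - f[, -ncol(f), drop = FALSE]
  v <- apply(d, 2L, var)
  out <- data.frame(interval = seq_len(ncol(f) - 1L),
                    t_from = time[-length(time)], t_to = time[-1L],
                    variance = as.numeric(v))
  attr(out, "argmax_interval") <- which.max(out$variance)
  out
}

#' Per-gene profile statistics
#'
#' Maximum fold changes of expression (`mfc_exp`) and transcription
#' (`mfc_pol`, computed on the linear scale) and the per-gene Pearson
#' correlation between the two log2 profiles.
#'
#' @param f Gene-by-time matrix of log2-ratio transcription profiles, or a
#'   `"stress_cohort"` (then `y` is taken from it).
#' @param y Gene-by-time matrix of log2-ratio expression profiles.
#' @return Data frame with `gene_id`, `mfc_exp`, `mfc_pol`,
#'   `log2_mfc_exp`, `log2_mfc_pol`, `corr_fy`.
#' @export
profile_stats <- function(f, y = NULL) {
  if (inherits(f, "stress_cohort")) {
    y <- f$y
    f <- f$f
  }
  stopifnot(is.matrix(f), is.matrix(y), all(dim(f) == dim(y)))
  ids <- rownames(f) %||% sprintf("g%04d", seq_len(nrow(f)))
  mfc_exp <- apply(2^y, 1L, function(v)
    if (sum(!is.na(v)) >= 2L) max_fold_change(v) else NA_real_)
  mfc_pol <- apply(2^f, 1L, function(v)
    if (sum(!is.na(v)) >= 2L) max_fold_change(v) else NA_real_)
  corr_fy <- vapply(seq_len(nrow(f)), function(i) {
    if (anyNA(f[i, ]) || anyNA(y[i, ])) return(NA_real_)
    profile_correlation(f[i, ], y[i, ])
  }, numeric(1))
  data.frame(gene_id = ids, mfc_exp = mfc_exp, mfc_pol = mfc_pol,
             log2_mfc_exp = log2(mfc_exp), log2_mfc_pol = log2(mfc_pol),
             corr_fy = corr_fy, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Median maximum fold changes of a gene cluster
#'
#' @param members Character vector of member gene ids (non-empty).
#' @param stats Per-gene statistics from [profile_stats()].
#' @param cluster_id Identifier recorded in the output.
#' @return Data frame with `cluster_id`, `n_genes`, `medmfc_exp`,
#'   `medmfc_pol`.
#' @export
median_mfc <- function(members, stats, cluster_id = "cluster") {
  if (length(members) == 0L) stop("cluster must be non-empty")
  idx <- match(members, stats$gene_id)
  if (anyNA(idx))
    stop("stats missing for genes: ",
         paste(head(members[is.na(idx)], 5), collapse = ", "))
  data.frame(cluster_id = as.character(cluster_id),
             n_genes = length(members),
             medmfc_exp = median(stats$mfc_exp[idx], na.rm = TRUE),
             medmfc_pol = median(stats$mfc_pol[idx], na.rm = TRUE),
             stringsAsFactors = FALSE)
}
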