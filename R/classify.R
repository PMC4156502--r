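#' Label a cluster's regulatory strategy
#'
#' Clusters with strong regulation in both expression and transcription
#' (both median maximum fold changes above 1.7) are labelled
#' `"strong_both"`; clusters with large expression changes but marginal
#' transcriptional changes (medMFC_POL below 1.2 and medMFC_EXP above 1.7)
#' are labelled `"post_transcriptional"`; the rest are `"unassigned"`.
#'
#' @param medmfc_exp,medmfc_pol Median maximum fold changes (vectorized).
#' @param strong_cutoff Cut-off for strong regulation (default 1.7).
#' @param post_pol_cutoff Transcription cut-off below which regulation is
#'   called post-transcriptional (default 1.2).
#' @return Character vector of labels.
#' @examples
#' label_cluster_strategy(c(2.5, 2.0, 1.5), c(2.0, 1.1, 1.5))
#' @export
label_cluster_strategy <- function(medmfc_exp, medmfc_pol,
                                   strong_cutoff = 1.7,
                                   post_pol_cutoff = 1.2) {
  stopifnot(length(medmfc_exp) == length(medmfc_pol))
  ifelse(medmfc_exp > strong_cutoff & medmfc_pol > strong_cutoff,
         "strong_both",
         ifelse(medmfc_exp > strong_cutoff & medmfc_pol < post_pol_cutoff,
                "post_transcriptional", "unassigned"))
}

#' Detect return to pre-stress expression levels
#'
#' Operationalizes "resuming pre-stress levels": for an up-regulated mean
#' profile the flag is set when both of the last two time points have
#' receded from the peak toward the baseline (the t = 0 value) by at least a
#' fraction `theta` of the peak excursion; the rule is symmetric for
#' down-regulated profiles. Flat profiles are never flagged.
#'
#' @param profile Cluster mean log2 profile (complete).
#' @param theta Required recession fraction of the peak-minus-baseline
#'   excursion (default 0.25).
#' @return List with `flag`, `direction` (`"up"` or `"down"`), and the
#'   recession fractions of the last two points.
#' @export
returns_to_baseline <- function(profile, theta = 0.25) {
  if (anyNA(profile)) stop("mean profile must be complete")
  n <- length(profile)
  if (n < 3L) stop("profile too short")
  base <- profile[1L]
  dev <- profile - base
  peak_idx <- which.max(abs(dev))
  excursion <- dev[peak_idx]
  if (abs(excursion) < 1e-12)
    return(list(flag = FALSE, direction = "up", recession = c(NA, NA)))
  direction <- if (excursion > 0) "up" else "down"
  last2 <- profile[c(n - 1L, n)]
  recession <- (profile[peak_idx] - last2) / excursion
  list(flag = all(recession >= theta), direction = direction,
       recession = recession)
}

#' Gene-set enrichment by the hypergeometric test
#'
#' One-sided tail probability of observing at least the seen overlap
#' between a cluster and a gene set, both drawn from a common universe
#' (Fisher's exact test for enrichment).
#'
#' @param cluster Character vector of cluster gene ids.
#' @param set Character vector of gene-set ids.
#' @param universe Character vector of all gene ids under consideration.
#' @return List with `overlap`, `expected`, and `p_value`.
#' @export
enrichment_test <- function(cluster, set, universe) {
  if (length(universe) == 0L) stop("universe must be non-empty")
  universe <- unique(universe)
  cluster <- unique(cluster)
  set <- unique(set)
  if (!all(cluster %in% universe) || !all(set %in% universe))
    stop("cluster and set must be subsets of the universe")
  N <- length(universe)
  m <- length(set)
  n_cl <- length(cluster)
  q <- length(intersect(cluster, set))
  p <- phyper(q - 1L, m, N - m, n_cl, lower.tail = FALSE)
  list(overlap = q, expected = n_cl * m / N, p_value = p)
}

#' Classify clusters as regulator-dependent or -independent
#'
#' Generalizes the transcription-factor dependence analysis: a cluster is
#' called `"dependent"` on the regulator when it significantly overlaps the
#' regulator-regulated gene list and its median expression amplitude drops
#' more than `ratio_threshold`-fold in the regulator mutant;
#' `"independent"` when it significantly overlaps the not-regulated list
#' and the amplitude ratio stays below the threshold; otherwise
#' `"unassigned"`. Overlap p-values are corrected across clusters
#' (Benjamini-Hochberg by default).
#'
#' @param clusters Named list of character vectors (cluster gene ids).
#' @param wt_medmfc,mut_medmfc Named numeric vectors of medMFC_EXP per
#'   cluster in the wild-type and mutant time courses (`NA` mutant values
#'   give `"unassigned"`).
#' @param regulated,not_regulated Gene lists defining regulator-regulated
#'   and regulator-unaffected genes.
#' @param universe All gene ids under consideration.
#' @param alpha Significance level on the (adjusted) overlap p-value.
#' @param ratio_threshold medMFC_EXP wild-type/mutant ratio threshold
#'   (default 1.5).
#' @param adjust Multiple-testing correction method (see
#'   [stats::p.adjust()]).
#' @return Data frame with one row per cluster: amplitude ratio, overlap
#'   p/q-values against both lists, and the `dependence` label.
#' @export
regulator_dependence <- function(clusters, wt_medmfc, mut_medmfc,
                                 regulated, not_regulated, universe,
                                 alpha = 0.05, ratio_threshold = 1.5,
                                 adjust = "BH") {
  stopifnot(is.list(clusters), length(clusters) >= 1L)
  ids <- names(clusters) %||% as.character(seq_along(clusters))
  p_reg <- vapply(clusters, function(g)
    enrichment_test(g, regulated, universe)$p_value, numeric(1))
  p_not <- vapply(clusters, function(g)
    enrichment_test(g, not_regulated, universe)$p_value, numeric(1))
  q_reg <- p.adjust(p_reg, method = adjust)
  q_not <- p.adjust(p_not, method = adjust)
  wt <- wt_medmfc[ids]
  mut <- mut_medmfc[ids]
  ratio <- as.numeric(wt) / as.numeric(mut)
  label <- character(length(ids))
  for (i in seq_along(ids)) {
    if (is.na(ratio[i])) {
      label[i] <- "unassigned"
    } else if (q_reg[i] < alpha && ratio[i] > ratio_threshold) {
      label[i] <- "dependent"
    } else if (q_not[i] < alpha && ratio[i] < ratio_threshold) {
      label[i] <- "independent"
    } else {
      label[i] <- "unassigned"
    }
  }
  data.frame(cluster_id = ids, n_genes = lengths(clusters),
             medmfc_wt = as.numeric(wt), medmfc_mut = as.numeric(mut),
             medmfc_ratio = ratio, p_regulated = p_reg,
             q_regulated = q_reg, p_not_regulated = p_not,
             q_not_regulated = q_not, dependence = label,
             stringsAsFactors = FALSE, row.names = NULL)
}
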