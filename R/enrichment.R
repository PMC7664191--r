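# Differential motif enrichment between two enhancer sets: per-enhancer
# presence counts, proportion-ratio fold, hypergeometric significance and
# Bonferroni correction.

#' Count enhancers containing at least one site per motif
#'
#' Presence/absence semantics: multiple sites of a motif in one enhancer
#' count once. Sites referencing enhancers outside `enhancer_names` are an
#' error.
#'
#' @param sites Binding-site data.frame (typically conservation-filtered).
#' @param enhancer_names Character vector of all enhancer names in the set.
#' @param motif_ids Motifs to report (default: those present in `sites`);
#'   motifs without sites get count 0.
#' @return Named integer vector of enhancer counts.
#' @export
count_presence <- function(sites, enhancer_names,
                           motif_ids = unique(sites$motif_id)) {
  unknown <- setdiff(unique(sites$enhancer_name), enhancer_names)
  if (length(unknown))
    stop("count_presence: site(s) reference unknown enhancer(s): ",
         paste(unknown, collapse = ", "))
  counts <- stats::setNames(integer(length(motif_ids)), motif_ids)
  if (nrow(sites)) {
    sites <- sites[sites$motif_id %in% motif_ids, , drop = FALSE]
    pairs <- unique(sites[, c("motif_id", "enhancer_name")])
    tab <- table(pairs$motif_id)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Proportion-ratio enrichment fold between two enhancer sets
#'
#' (k_b / n_b) / (k_a / n_a): the proportion of set-B enhancers containing
#' the motif divided by the proportion in set A. +Inf when the motif occurs
#' only in set B; defined as 1 when it occurs in neither.
#'
#' @param k_b,n_b Enhancers with the motif, and set size, in set B.
#' @param k_a,n_a Same for set A.
#' @return Numeric fold (vectorised).
#' @export
enrichment_fold <- function(k_b, n_b, k_a, n_a) {
  stopifnot(all(n_a > 0), all(n_b > 0))
  ifelse(k_a == 0 & k_b == 0, 1,
         ifelse(k_a == 0, Inf, (k_b / n_b) / (k_a / n_a)))
}

#' Hypergeometric over-representation test for motif presence
#'
#' One-sided upper tail P(X >= k_b) for drawing `n_b` enhancers (set B)
#' from the pooled universe of `n_a + n_b` enhancers of which `k_a + k_b`
#' contain the motif.
#'
#' @inheritParams enrichment_fold
#' @return Raw p-value (vectorised).
#' @export
hypergeom_enrichment <- function(k_b, n_b, k_a, n_a) {
  K <- k_a + k_b
  N <- n_a + n_b
  stats::phyper(k_b - 1, K, N - K, n_b, lower.tail = FALSE)
}

#' Bonferroni correction
#' @param p_values Numeric vector of raw p-values.
#' @param m Number of tests (default: length of the vector).
#' @return Corrected p-values, capped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(m >= 1)
  pmin(1, p_values * m)
}

#' Differential motif enrichment table
#'
#' Combines presence counts from the two enhancer sets into per-motif fold,
#' raw hypergeometric p-value and Bonferroni-corrected p-value (m = number
#' of motifs tested, i.e. cluster representatives after deduplication), and
#' flags which motifs pass the selection thresholds.
#'
#' @param presence_a,presence_b Named counts from [count_presence()], one
#'   entry per tested motif (same names).
#' @param n_a,n_b Enhancer-set sizes.
#' @param fold_min,p_max Selection thresholds recorded in the `passes`
#'   column (defaults 1.5 and 0.05 on the corrected p-value).
#' @return data.frame with columns motif_id, k_a, n_a, k_b, n_b, fold,
#'   p_raw, p_bonf, passes; ranked by fold descending then p_raw ascending.
#' @export
motif_enrichment <- function(presence_a, presence_b, n_a, n_b,
                             fold_min = 1.5, p_max = 0.05) {
  ids <- names(presence_b)
  if (!setequal(ids, names(presence_a)))
    stop("motif_enrichment: presence vectors cover different motifs")
  k_a <- as.integer(presence_a[ids])
  k_b <- as.integer(presence_b[ids])
  stopifnot(all(k_a >= 0), all(k_a <= n_a), all(k_b >= 0), all(k_b <= n_b))
  p_raw <- hypergeom_enrichment(k_b, n_b, k_a, n_a)
  res <- data.frame(
    motif_id = ids, k_a = k_a, n_a = n_a, k_b = k_b, n_b = n_b,
    fold = enrichment_fold(k_b, n_b, k_a, n_a),
    p_raw = p_raw,
    p_bonf = bonferroni(p_raw),
    stringsAsFactors = FALSE)
  res$passes <- res$fold >= fold_min & res$p_bonf <= p_max
  res <- res[order(-res$fold, res$p_raw, res$motif_id, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select significantly enriched motifs
#'
#' Subset with fold >= `fold_min` and Bonferroni-corrected p <= `p_max`,
#' ranked by fold descending (+Inf first) then raw p ascending.
#'
#' @param results data.frame from [motif_enrichment()].
#' @param fold_min Minimum enrichment fold (default 1.5).
#' @param p_max Maximum corrected p-value (default 0.05).
#' @return Filtered, ranked data.frame.
#' @export
select_enriched <- function(results, fold_min = 1.5, p_max = 0.05) {
  out <- results[results$fold >= fold_min & results$p_bonf <= p_max, ,
                 drop = FALSE]
  out <- out[order(-out$fold, out$p_raw, out$motif_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
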