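# Functional enrichment statistics: GREAT-style region-based binomial test
# with a parallel gene-based hypergeometric test, gene-list
# over-representation analysis, term filters, and predicted-target versus
# differential-expression overlap tests.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment, capped at 1; adjusted values are monotone after rank
#' sorting and never below the raw p-values.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Region-based term enrichment (GREAT-style)
#'
#' For each term, the fraction `p_term` of the assignable genome (the union
#' of all regulatory domains) covered by the domains of the term's genes is
#' the per-region hit probability; the binomial tail P(Bin(n, p_term) >= k)
#' tests whether `k` of the `n` regions fall in term domains. A gene-based
#' hypergeometric test is computed in parallel: of the genes owning a
#' domain, how many of those hit by at least one region are annotated to
#' the term. Both p-value families are BH-adjusted across terms; results
#' are ranked by the region-test FDR then raw p.
#'
#' @param regions Interval data.frame (chrom, start, end, name).
#' @param domains Regulatory domains from [build_domains()].
#' @param term_annotation Named list of gene-symbol vectors (see
#'   [read_gmt()]). Terms annotating no gene with a domain are skipped with
#'   a warning.
#' @return data.frame with one row per term: term, n_regions, k_regions,
#'   p_term, fold_enrich, binom_p, binom_fdr, gene_universe, term_genes,
#'   gene_hits, hyper_fold, hyper_p, hyper_fdr.
#' @export
region_term_enrichment <- function(regions, domains, term_annotation) {
  n <- nrow(regions)
  widths <- domains$end - domains$start
  assignable <- sum(widths)
  gene_upper <- toupper(domains$gene_id)
  width_by_gene <- stats::setNames(widths, gene_upper)
  # midpoint-in-domain assignment (domains are disjoint by construction)
  mid <- floor((regions$start + regions$end) / 2)
  assigned <- rep(NA_character_, n)
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    cd <- domains[domains$chrom == chr, , drop = FALSE]
    if (nrow(cd) == 0) next
    cd <- cd[order(cd$start), , drop = FALSE]
    j <- findInterval(mid[ri], cd$start)
    inside <- j >= 1 & ifelse(j >= 1, mid[ri] < cd$end[pmax(j, 1)], FALSE)
    assigned[ri[inside]] <- toupper(cd$gene_id[j[inside]])
  }
  hit_genes <- unique(assigned[!is.na(assigned)])
  universe <- unique(gene_upper)
  U <- length(universe)
  D <- length(hit_genes)
  rows <- list()
  skipped <- character()
  for (term in names(term_annotation)) {
    tg <- intersect(toupper(term_annotation[[term]]), universe)
    if (length(tg) == 0) {
      skipped <- c(skipped, term)
      next
    }
    p_term <- sum(width_by_gene[tg]) / assignable
    k <- sum(!is.na(assigned) & assigned %in% tg)
    binom_p <- stats::pbinom(k - 1, n, p_term, lower.tail = FALSE)
    kg <- length(intersect(tg, hit_genes))
    hyper_p <- stats::phyper(kg - 1, length(tg), U - length(tg), D,
                             lower.tail = FALSE)
    rows[[term]] <- data.frame(
      term = term, n_regions = n, k_regions = k, p_term = p_term,
      fold_enrich = if (p_term > 0) k / (n * p_term) else NA_real_,
      binom_p = binom_p,
      gene_universe = U, term_genes = length(tg), gene_hits = kg,
      hyper_fold = if (D > 0) (kg / D) / (length(tg) / U) else NA_real_,
      hyper_p = hyper_p,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("region_term_enrichment: skipped term(s) annotating no gene ",
            "with a domain: ", paste(skipped, collapse = ", "))
  if (!length(rows))
    return(data.frame(term = character(), n_regions = integer(),
                      k_regions = integer(), p_term = numeric(),
                      fold_enrich = numeric(), binom_p = numeric(),
                      binom_fdr = numeric(), gene_universe = integer(),
                      term_genes = integer(), gene_hits = integer(),
                      hyper_fold = numeric(), hyper_p = numeric(),
                      hyper_fdr = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$binom_fdr <- bh_fdr(res$binom_p)
  res$hyper_fdr <- bh_fdr(res$hyper_p)
  res <- res[, c("term", "n_regions", "k_regions", "p_term", "fold_enrich",
                 "binom_p", "binom_fdr", "gene_universe", "term_genes",
                 "gene_hits", "hyper_fold", "hyper_p", "hyper_fdr")]
  res <- res[order(res$binom_fdr, res$binom_p, res$term, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene-list over-representation analysis
#'
#' Per-term hypergeometric upper tail for the overlap between `gene_list`
#' and the term's genes within `universe`, with BH FDR across terms.
#' Matching is case-insensitive. List genes absent from the universe are
#' dropped with a message.
#'
#' @param gene_list Character vector of genes of interest.
#' @param universe Character vector of all testable genes (e.g. the
#'   protein-coding genome).
#' @param term_annotation Named list of gene-symbol vectors.
#' @return data.frame with columns term, universe_size, list_size,
#'   term_genes, gene_hits, fold_enrich, p, fdr; ranked by FDR then p.
#' @export
gene_list_ora <- function(gene_list, universe, term_annotation) {
  universe <- unique(toupper(universe))
  gene_list <- unique(toupper(gene_list))
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    message("gene_list_ora: dropped ", length(outside),
            " list gene(s) absent from the universe")
    gene_list <- intersect(gene_list, universe)
  }
  U <- length(universe)
  nl <- length(gene_list)
  rows <- list()
  for (term in names(term_annotation)) {
    tg <- intersect(toupper(term_annotation[[term]]), universe)
    K <- length(tg)
    if (K == 0) next
    k <- length(intersect(tg, gene_list))
    rows[[term]] <- data.frame(
      term = term, universe_size = U, list_size = nl, term_genes = K,
      gene_hits = k,
      fold_enrich = if (nl > 0) (k / nl) / (K / U) else NA_real_,
      p = stats::phyper(k - 1, K, U - K, nl, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(term = character(), universe_size = integer(),
                      list_size = integer(), term_genes = integer(),
                      gene_hits = integer(), fold_enrich = numeric(),
                      p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$p)
  res <- res[order(res$fdr, res$p, res$term, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter term-enrichment results on fold, FDR and gene support
#'
#' Keeps terms with enrichment fold >= `fold_min`, FDR <= `fdr_max` and at
#' least `min_genes` associated genes (all inclusive). For region-based
#' results the gene-based (hypergeometric) fold and FDR are used, matching
#' how such tables are conventionally filtered; ORA results use their
#' single fold/FDR pair. `top_n` optionally truncates the ranked result
#' (e.g. top-10 reporting).
#'
#' @param results Output of [region_term_enrichment()] or [gene_list_ora()].
#' @param fold_min Minimum fold enrichment (default 2).
#' @param fdr_max Maximum FDR (default 0.05).
#' @param min_genes Minimum associated genes (default 5).
#' @param top_n Optional maximum number of terms to return.
#' @return Filtered data.frame, ranked by the filtering FDR.
#' @export
apply_term_filters <- function(results, fold_min = 2, fdr_max = 0.05,
                               min_genes = 5, top_n = NULL) {
  fold <- if ("hyper_fold" %in% names(results)) results$hyper_fold else
    results$fold_enrich
  fdr <- if ("hyper_fdr" %in% names(results)) results$hyper_fdr else
    results$fdr
  keep <- !is.na(fold) & fold >= fold_min & fdr <= fdr_max &
    results$gene_hits >= min_genes
  out <- results[keep, , drop = FALSE]
  out <- out[order(fdr[keep], method = "radix"), , drop = FALSE]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}

#' Overlap test between predicted targets and a DE gene set
#'
#' Hypergeometric upper tail P(X >= overlap) for drawing
#' `|target_genes|` genes from a universe containing `|de_genes|`
#' successes. The universe must be supplied explicitly; the natural default
#' is the set of genes tested for differential expression.
#'
#' @param target_genes Predicted target genes.
#' @param de_genes Differentially expressed genes (e.g. knockdown-
#'   downregulated set).
#' @param universe All genes the DE test considered.
#' @return One-row data.frame: target_set_size, de_set_size, universe_size,
#'   overlap, hyper_p.
#' @export
target_de_overlap <- function(target_genes, de_genes, universe) {
  universe <- unique(toupper(universe))
  tg <- unique(toupper(target_genes))
  dg <- unique(toupper(de_genes))
  out_t <- setdiff(tg, universe)
  out_d <- setdiff(dg, universe)
  if (length(out_t) || length(out_d)) {
    message("target_de_overlap: dropped ", length(out_t), " target and ",
            length(out_d), " DE gene(s) absent from the universe")
    tg <- intersect(tg, universe)
    dg <- intersect(dg, universe)
  }
  ov <- length(intersect(tg, dg))
  if (length(tg) == 0) {
    warning("target_de_overlap: empty target set; p = 1")
    p <- 1
  } else {
    p <- stats::phyper(ov - 1, length(dg), length(universe) - length(dg),
                       length(tg), lower.tail = FALSE)
  }
  data.frame(target_set_size = length(tg), de_set_size = length(dg),
             universe_size = length(universe), overlap = ov, hyper_p = p)
}
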