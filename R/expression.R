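# Selection of highly expressed, upregulated genes and their TF subset.

#' Filter for highly expressed, upregulated genes
#'
#' Retains records with condition-B abundance `fpkm_b >= fpkm_min`, linear
#' fold change `fold >= fold_min` and `q_value <= q_max` (all thresholds
#' inclusive). Records with missing q_value are excluded, with a warning
#' reporting how many: significance cannot be asserted for them. The result
#' is ordered by gene_id so it is independent of input row order.
#'
#' @param records Expression data.frame (see [read_expression_table()]).
#' @param fpkm_min Minimum condition-B FPKM (default 10).
#' @param fold_min Minimum linear fold change B/A (default 2).
#' @param q_max Maximum FDR-adjusted q-value (default 0.05).
#' @return Filtered data.frame, sorted by gene_id.
#' @export
filter_upregulated <- function(records, fpkm_min = 10, fold_min = 2,
                               q_max = 0.05) {
  stopifnot(fpkm_min > 0, fold_min > 0, q_max > 0)
  na_q <- is.na(records$q_value)
  if (any(na_q))
    warning("filter_upregulated: excluded ", sum(na_q),
            " record(s) with missing q_value")
  keep <- !na_q & !is.na(records$fold) &
    records$fpkm_b >= fpkm_min &
    records$fold >= fold_min &
    records$q_value <= q_max
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict expression records to transcription factors
#'
#' Keeps records whose gene_id is in the TF catalog; matching is
#' case-insensitive (mouse and human symbol casing differ).
#'
#' @param records Expression data.frame.
#' @param catalog Character vector of TF gene symbols.
#' @param strict When TRUE, an empty catalog is an error; when FALSE
#'   (default) it yields an empty result with a warning.
#' @return Subset of `records`, order preserved.
#' @export
restrict_to_tfs <- function(records, catalog, strict = FALSE) {
  if (length(catalog) == 0) {
    if (strict) stop("restrict_to_tfs: empty TF catalog")
    warning("restrict_to_tfs: empty TF catalog; returning no records")
    return(records[0, , drop = FALSE])
  }
  out <- records[toupper(records$gene_id) %in% toupper(catalog), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}
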