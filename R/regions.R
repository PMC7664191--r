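# GREAT-style region-gene association: single nearest gene by TSS distance
# and midpoint-anchored regulatory domains.

.validate_tss <- function(tss_table) {
  need <- c("gene_id", "chrom", "tss")
  missing <- setdiff(need, names(tss_table))
  if (length(missing))
    stop("TSS table: missing column(s) ", paste(missing, collapse = ", "))
  if (anyDuplicated(tss_table$gene_id))
    stop("TSS table: one TSS per gene required; duplicated gene_id(s): ",
         paste(unique(tss_table$gene_id[duplicated(tss_table$gene_id)]),
               collapse = ", "))
  tss_table
}

#' Build regulatory domains around gene TSSs
#'
#' Each gene's domain extends from its TSS toward each neighbouring gene up
#' to the midpoint between the adjacent TSSs, capped at `max_extension` on
#' each side and clipped to chromosome bounds. Domains of adjacent genes
#' therefore tile without overlapping. Intervals are 0-based half-open.
#'
#' @param tss_table data.frame with columns gene_id, chrom, tss (strand
#'   optional). Genes at duplicate TSS positions are ordered by gene_id.
#' @param max_extension Maximum extension per side in bp (default 1e6).
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   clip domain ends.
#' @return data.frame with columns gene_id, chrom, start, end.
#' @export
build_domains <- function(tss_table, max_extension = 1e6,
                          chrom_sizes = NULL) {
  tss_table <- .validate_tss(tss_table)
  ord <- order(tss_table$chrom, tss_table$tss, tss_table$gene_id,
               method = "radix")
  tt <- tss_table[ord, , drop = FALSE]
  out <- lapply(split(tt, tt$chrom), function(ct) {
    t <- ct$tss
    k <- length(t)
    mid <- if (k > 1) floor((t[-k] + t[-1]) / 2) else integer(0)
    start <- pmax(t - max_extension, c(-Inf, mid), 0)
    end <- pmin(t + max_extension, c(mid, Inf))
    if (!is.null(chrom_sizes) && ct$chrom[1] %in% names(chrom_sizes))
      end <- pmin(end, chrom_sizes[[ct$chrom[1]]])
    data.frame(gene_id = ct$gene_id, chrom = ct$chrom,
               start = start, end = end, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign each region to its single nearest gene
#'
#' The anchor is the region midpoint; the assigned gene is the one whose
#' TSS (on the same chromosome) is closest, provided it lies within
#' `max_distance`; ties are broken toward the lexicographically smaller
#' gene_id. Regions with no gene in range are left unassigned (NA).
#'
#' @param regions Interval data.frame (chrom, start, end, name).
#' @param tss_table data.frame with columns gene_id, chrom, tss.
#' @param max_distance Maximum TSS distance in bp (default 1e6).
#' @return data.frame with columns name, chrom, midpoint, gene_id, distance.
#' @export
assign_nearest_gene <- function(regions, tss_table, max_distance = 1e6) {
  tss_table <- .validate_tss(tss_table)
  mid <- floor((regions$start + regions$end) / 2)
  gene <- rep(NA_character_, nrow(regions))
  dist <- rep(NA_real_, nrow(regions))
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    ct <- tss_table[tss_table$chrom == chr, , drop = FALSE]
    if (nrow(ct) == 0) next
    ct <- ct[order(ct$tss, ct$gene_id, method = "radix"), , drop = FALSE]
    for (i in ri) {
      d <- abs(ct$tss - mid[i])
      best <- min(d)
      if (best <= max_distance) {
        cand <- ct$gene_id[d == best]
        gene[i] <- sort(cand, method = "radix")[1]
        dist[i] <- best
      }
    }
  }
  data.frame(name = regions$name, chrom = regions$chrom, midpoint = mid,
             gene_id = gene, distance = dist, stringsAsFactors = FALSE)
}
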