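# Motif redundancy collapsing: pairwise PWM similarity and single-linkage
# grouping, keeping the member seen in the most enhancers.

#' Similarity between two motifs
#'
#' Maximum, over all ungapped offsets with at least `min_overlap`
#' overlapping columns and over both orientations of the second motif, of
#' the Pearson correlation between the flattened overlapping probability
#' columns. Symmetric in its arguments. Returns the sentinel -1 when no
#' offset reaches the minimum overlap.
#'
#' @param pwm_a,pwm_b `pwm` objects.
#' @param min_overlap Minimum number of aligned columns (default 4).
#' @return Similarity in [-1, 1].
#' @export
pwm_similarity <- function(pwm_a, pwm_b, min_overlap = 4L) {
  pa <- pwm_a$probs
  La <- ncol(pa)
  Lb <- ncol(pwm_b$probs)
  if (min(La, Lb) < min_overlap) return(-1)
  best <- -1
  for (pb in list(pwm_b$probs, .revcomp_matrix(pwm_b$probs))) {
    for (d in seq(-(Lb - min_overlap), La - min_overlap)) {
      ia <- max(1L, 1L + d):min(La, Lb + d)
      ib <- ia - d
      va <- as.vector(pa[, ia, drop = FALSE])
      vb <- as.vector(pb[, ib, drop = FALSE])
      sa <- stats::sd(va)
      sb <- stats::sd(vb)
      r <- if (sa == 0 && sb == 0) {
        if (max(abs(va - vb)) < 1e-12) 1 else NA_real_
      } else if (sa == 0 || sb == 0) {
        NA_real_  # flat against non-flat: correlation undefined
      } else {
        stats::cor(va, vb)
      }
      if (!is.na(r) && r > best) best <- r
    }
  }
  best
}

#' Group similar motifs and pick one representative per group
#'
#' Single-linkage grouping over motif pairs with similarity >= `sim_min`:
#' clusters are the connected components of the similarity graph, so every
#' motif belongs to exactly one cluster. The representative is the member
#' present in the most enhancers (per `occurrences`), ties broken by
#' lexicographic motif_id.
#'
#' @param pwms List of `pwm` objects.
#' @param occurrences Named integer vector: enhancers containing each motif
#'   (missing motifs count 0).
#' @param sim_min Similarity threshold (default 0.8).
#' @param min_overlap Passed to [pwm_similarity()].
#' @return data.frame with columns representative, members (comma-joined,
#'   sorted), n_members, occurrence_count; one row per cluster, ordered by
#'   representative.
#' @export
cluster_motifs <- function(pwms, occurrences, sim_min = 0.8,
                           min_overlap = 4L) {
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  if (anyDuplicated(ids)) stop("cluster_motifs: duplicate motif ids")
  n <- length(pwms)
  if (n == 0)
    return(data.frame(representative = character(), members = character(),
                      n_members = integer(), occurrence_count = integer(),
                      stringsAsFactors = FALSE))
  occ <- stats::setNames(rep(0L, n), ids)
  hit <- intersect(names(occurrences), ids)
  occ[hit] <- as.integer(occurrences[hit])
  # union-find over similar pairs (single linkage = connected components)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (pwm_similarity(pwms[[i]], pwms[[j]], min_overlap) >= sim_min) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- split(ids, roots)
  rows <- lapply(clusters, function(members) {
    o <- occ[members]
    # max occurrences, ties by lexicographic id
    ord <- order(-o, members, method = "radix")
    data.frame(representative = members[ord[1]],
               members = paste(sort(members, method = "radix"),
                               collapse = ","),
               n_members = length(members),
               occurrence_count = max(o),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$representative, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
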