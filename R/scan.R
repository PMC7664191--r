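# PWM scanning of enhancer sequences, with relative match score and exact
# site p-value filters, plus the phylofootprint conservation filter.

#' Encode a DNA string as integers
#'
#' A,C,G,T map to 1..4; N (and any other ambiguity code) maps to NA so that
#' windows containing it propagate NA scores and are skipped.
#' @param s A single DNA string.
#' @return Integer vector.
#' @keywords internal
encode_dna <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES)
}

# Score every window of an encoded sequence with a log-odds matrix.
# Returns numeric vector of window scores (NA where a window covers an
# NA base), one per 0-based offset 0..(n-L).
.score_windows <- function(lo, x) {
  L <- ncol(lo)
  nW <- length(x) - L + 1L
  if (nW < 1L) return(numeric(0))
  s <- numeric(nW)
  for (j in seq_len(L)) {
    s <- s + lo[, j][x[j:(j + nW - 1L)]]
  }
  s
}

.empty_sites <- function() {
  data.frame(motif_id = character(), enhancer_name = character(),
             offset = integer(), strand = character(), score = numeric(),
             rel_score = numeric(), p_value = numeric(),
             stringsAsFactors = FALSE)
}

# Precompute plus/minus score distributions for a pwm, reusing the plus
# distribution when the background is complement-symmetric.
.pwm_dists <- function(pwm, step = 1e-4) {
  dp <- score_distribution(pwm, step = step, strand = "+")
  bg <- pwm$background
  dm <- if (bg[1] == bg[4] && bg[2] == bg[3]) dp else
    score_distribution(pwm, step = step, strand = "-")
  list(`+` = dp, `-` = dm)
}

#' Precompute score distributions for a motif library
#'
#' Computes the plus/minus-strand null score distributions of each motif
#' once, for reuse across repeated [scan_enhancers()] or
#' [run_motif_stages()] calls (e.g. replicate simulations), where
#' recomputing the DP convolution would dominate the runtime.
#'
#' @param pwms List of `pwm` objects.
#' @param step Score grid granularity.
#' @return Named list of distribution pairs keyed by motif_id.
#' @export
precompute_dists <- function(pwms, step = 1e-4) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  stats::setNames(lapply(pwms, .pwm_dists, step = step), ids)
}

#' Scan a set of sequences for binding sites of one or more motifs
#'
#' Both strands are scanned; a site is reported at every offset where the
#' relative match score is at least `match_min` and (when `p_max` is not
#' NULL) the exact background p-value of its score is at most `p_max`.
#' The relative match score rescales the log-odds sum to [0, 1] between the
#' worst- and best-possible site score of the matrix. Windows containing N
#' are skipped. Minus-strand sites are reported at their forward-strand
#' start offset (0-based), so site coordinates always refer to the input
#' sequence.
#'
#' @param pwms A `pwm` object or list of them.
#' @param seqs Named character vector of sequences (names = enhancer ids).
#' @param match_min Minimum relative match score in (0, 1] (default 0.8).
#' @param p_max Maximum site p-value (default 0.05); `NULL` disables the
#'   p-value filter (no distributions are computed, `p_value` is NA).
#' @param dists Optional named list (by motif_id) of precomputed
#'   distribution pairs as returned by the internal `.pwm_dists()`; reusing
#'   them across calls avoids recomputing the DP convolution.
#' @param step Score grid granularity.
#' @return data.frame of binding sites with columns motif_id,
#'   enhancer_name, offset, strand, score, rel_score, p_value.
#' @export
scan_enhancers <- function(pwms, seqs, match_min = 0.8, p_max = 0.05,
                           dists = NULL, step = 1e-4) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(match_min > 0, match_min <= 1)
  if (length(seqs) == 0) return(.empty_sites())
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("scan_enhancers: sequences must have unique names")
  enc <- lapply(seqs, encode_dna)
  lens <- vapply(enc, length, integer(1))
  maxL <- max(vapply(pwms, pwm_width, integer(1)))
  # concatenate with NA separators so no window spans two sequences
  sep <- rep(NA_integer_, maxL)
  x <- unlist(lapply(enc, function(e) c(e, sep)), use.names = FALSE)
  starts <- cumsum(c(1L, lens + maxL))[seq_along(enc)]  # 1-based starts in x
  out <- vector("list", 2L * length(pwms))
  oi <- 0L
  for (pwm in pwms) {
    L <- pwm_width(pwm)
    lo <- pwm_logodds(pwm, step = step)
    rng <- .lo_range(lo)
    d <- if (!is.null(p_max)) {
      if (!is.null(dists) && !is.null(dists[[pwm$motif_id]]))
        dists[[pwm$motif_id]] else .pwm_dists(pwm, step = step)
    }
    for (strand in c("+", "-")) {
      mat <- if (strand == "+") lo else .revcomp_matrix(lo)
      s <- .score_windows(mat, x)
      rel <- (s - rng["smin"]) / (rng["smax"] - rng["smin"])
      hit <- which(!is.na(s) & rel >= match_min - 1e-9)
      if (!is.null(p_max) && length(hit)) {
        pv <- site_pvalue(pwm, s[hit], dist = d[[strand]])
        keep <- pv <= p_max
        hit <- hit[keep]
        pv <- pv[keep]
      } else {
        pv <- rep(NA_real_, length(hit))
      }
      if (length(hit)) {
        si <- findInterval(hit, starts)
        oi <- oi + 1L
        out[[oi]] <- data.frame(
          motif_id = pwm$motif_id,
          enhancer_name = names(seqs)[si],
          offset = hit - starts[si],
          strand = strand,
          score = unname(s[hit]),
          rel_score = unname(pmin(rel[hit], 1)),
          p_value = pv,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- out[seq_len(oi)]
  if (!length(out)) return(.empty_sites())
  res <- do.call(rbind, out)
  res <- res[order(res$motif_id, res$enhancer_name, res$offset, res$strand,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a single sequence with one motif
#'
#' Convenience wrapper around [scan_enhancers()] for one unnamed sequence.
#'
#' @inheritParams scan_enhancers
#' @param pwm A `pwm` object.
#' @param sequence A single DNA string.
#' @return data.frame of binding sites (enhancer_name = "seq").
#' @export
scan_sequence <- function(pwm, sequence, match_min = 0.8, p_max = 0.05,
                          dists = NULL, step = 1e-4) {
  scan_enhancers(list(pwm), c(seq = sequence), match_min = match_min,
                 p_max = p_max, dists = dists, step = step)
}

#' Flag binding sites as conserved in an orthologous sequence
#'
#' A site is conserved when the ortholog sequence mapped to its enhancer
#' contains at least one match of the same motif with relative score >=
#' `match_min` on either strand (no site p-value filter is applied to the
#' ortholog search). Enhancers absent from the map, or mapped to nothing,
#' yield `conserved = FALSE`; their number is reported in the
#' `no_ortholog` attribute.
#'
#' @param sites data.frame from [scan_enhancers()].
#' @param ortholog_map data.frame with columns `enhancer` and `ortholog`.
#' @param ortholog_seqs Named character vector of ortholog sequences.
#' @param pwms List of `pwm` objects covering every motif_id in `sites`.
#' @param match_min Minimum relative match score in the ortholog.
#' @return `sites` with a logical `conserved` column added.
#' @export
apply_conservation <- function(sites, ortholog_map, ortholog_seqs, pwms,
                               match_min = 0.8) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  names(pwms) <- vapply(pwms, function(p) p$motif_id, character(1))
  sites$conserved <- FALSE
  if (nrow(sites) == 0) {
    attr(sites, "no_ortholog") <- 0L
    return(sites)
  }
  map <- stats::setNames(as.character(ortholog_map$ortholog),
                         ortholog_map$enhancer)
  enh <- unique(sites$enhancer_name)
  mapped <- enh[enh %in% names(map)]
  missing_ids <- setdiff(map[mapped], names(ortholog_seqs))
  if (length(missing_ids))
    stop("apply_conservation: ortholog id(s) missing from sequences: ",
         paste(missing_ids, collapse = ", "))
  unknown <- setdiff(unique(sites$motif_id), names(pwms))
  if (length(unknown))
    stop("apply_conservation: no pwm supplied for motif(s): ",
         paste(unknown, collapse = ", "))
  # one ortholog scan per motif over the orthologs of its enhancers
  for (m in unique(sites$motif_id)) {
    menh <- unique(sites$enhancer_name[sites$motif_id == m])
    menh <- menh[menh %in% mapped]
    if (!length(menh)) next
    oseq <- ortholog_seqs[map[menh]]
    names(oseq) <- menh  # index ortholog hits by the enhancer they back
    ohits <- scan_enhancers(pwms[[m]], oseq, match_min = match_min,
                            p_max = NULL)
    ok <- unique(ohits$enhancer_name)
    sel <- sites$motif_id == m & sites$enhancer_name %in% ok
    sites$conserved[sel] <- TRUE
  }
  attr(sites, "no_ortholog") <- length(setdiff(enh, mapped))
  sites
}
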