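DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' A `pwm` bundles a per-position nucleotide probability matrix with the
#' background model it is scored against. Raw counts, when available (e.g.
#' from a JASPAR PFM), are kept so that information content can be computed
#' on the un-pseudocounted frequencies.
#'
#' @param motif_id Motif identifier (typically the TF gene symbol).
#' @param probs 4 x L numeric matrix, rows A/C/G/T, columns summing to 1.
#' @param background Length-4 background base probabilities (A, C, G, T).
#' @param counts Optional 4 x L raw count matrix the probabilities came from.
#' @param altname Optional alternative name (e.g. MEME alt field).
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(motif_id, probs, background = rep(0.25, 4),
                    counts = NULL, altname = NULL) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L)
    stop("PWM '", motif_id, "': probability matrix must have 4 rows (A,C,G,T)")
  if (ncol(probs) < 1L)
    stop("PWM '", motif_id, "': empty probability matrix")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-9))
    stop("PWM '", motif_id, "': column(s) ",
         paste(which(abs(cs - 1) > 1e-9), collapse = ","),
         " do not sum to 1")
  if (any(probs < 0))
    stop("PWM '", motif_id, "': negative probabilities")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0))
    stop("PWM '", motif_id, "': background must be 4 positive probabilities summing to 1")
  rownames(probs) <- DNA_BASES
  structure(
    list(motif_id = motif_id, probs = probs,
         background = as.numeric(background), counts = counts,
         altname = altname),
    class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id,
      if (!is.null(x$altname)) paste0(" (", x$altname, ")"),
      "  width=", ncol(x$probs),
      "  IC=", format(information_content(x), digits = 4), " bits\n", sep = "")
  invisible(x)
}

#' Motif width
#' @param pwm A `pwm` object.
#' @return Integer number of columns.
#' @export
pwm_width <- function(pwm) ncol(pwm$probs)

#' Build a pwm from a raw count matrix with a per-cell pseudocount
#'
#' Each cell receives `pseudocount` before column normalisation, so a column
#' with counts (10,0,0,0) becomes (10.25, 0.25, 0.25, 0.25) / 11. The raw
#' counts are retained for information-content computation.
#'
#' @inheritParams new_pwm
#' @param counts 4 x L non-negative count matrix.
#' @param pseudocount Added to every cell before normalisation (default 0.25).
#' @export
pwm_from_counts <- function(motif_id, counts, pseudocount = 0.25,
                            background = rep(0.25, 4), altname = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("PWM '", motif_id, "': count matrix must have 4 rows (A,C,G,T)")
  if (any(counts < 0))
    stop("PWM '", motif_id, "': negative counts")
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("PWM '", motif_id, "': zero-total column(s) ",
         paste(which(cs == 0), collapse = ","))
  probs <- sweep(counts + pseudocount, 2, cs + 4 * pseudocount, "/")
  new_pwm(motif_id, probs, background = background, counts = counts,
          altname = altname)
}

#' Information content of a motif, in bits
#'
#' IC = sum over columns of (2 + sum_b p log2 p), computed on the raw count
#' frequencies when counts are available (i.e. before pseudocounting),
#' otherwise on the stored probabilities. Ranges from 0 (uniform columns) to
#' 2 per column (deterministic columns).
#'
#' @param pwm A `pwm` object.
#' @return Information content in bits.
#' @export
information_content <- function(pwm) {
  p <- if (!is.null(pwm$counts)) {
    sweep(pwm$counts, 2, colSums(pwm$counts), "/")
  } else {
    pwm$probs
  }
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sum(2 + colSums(plogp))
}

# Reverse complement of a probability (or log-odds) matrix: complement the
# base rows (A<->T, C<->G) and reverse the column order.
.revcomp_matrix <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]

#' Log-odds scoring matrix of a motif
#'
#' Entries are log2(p / background), with probabilities floored at
#' `prob_floor` so indicator columns stay finite, then quantised to the
#' `step` score grid. Quantisation makes the exact dynamic-programming null
#' distribution of [site_pvalue()] consistent with the scores produced by
#' scanning: every attainable word score lies exactly on the grid.
#'
#' @param pwm A `pwm` object.
#' @param step Score grid granularity (default 1e-4).
#' @param prob_floor Lower bound applied to probabilities before taking logs.
#' @return 4 x L matrix of grid-aligned log-odds scores.
#' @export
pwm_logodds <- function(pwm, step = 1e-4, prob_floor = 1e-4) {
  lo <- log2(pmax(pwm$probs, prob_floor) / pwm$background)
  round(lo / step) * step
}

# min/max attainable total scores of a log-odds matrix
.lo_range <- function(lo) {
  c(smin = sum(apply(lo, 2, min)), smax = sum(apply(lo, 2, max)))
}

#' Exact null distribution of PWM scores under the background model
#'
#' Convolves the per-column score distributions on a discretised grid
#' (granularity `step`), yielding the exact probability that a random L-mer
#' drawn from the background scores at least any given value. Because the
#' scoring matrix itself is grid-aligned (see [pwm_logodds()]) the result is
#' exact for the scores the scanner produces, not an approximation.
#'
#' @param pwm A `pwm` object.
#' @param step Score grid granularity; must match the scanning step.
#' @param strand `"+"` scores the matrix as-is, `"-"` its reverse complement
#'   (the two distributions differ only for complement-asymmetric
#'   backgrounds).
#' @return A list with elements `step`, `smin`, `smax` and `survival`
#'   (`survival[i]` = P(score >= smin + (i-1)*step)).
#' @export
score_distribution <- function(pwm, step = 1e-4, strand = "+") {
  lo <- pwm_logodds(pwm, step = step)
  if (strand == "-") lo <- .revcomp_matrix(lo)
  # rows of the (possibly reverse-complemented) matrix are still indexed by
  # the forward-strand base being read, so the background weights are unchanged
  bg <- pwm$background
  colmin <- apply(lo, 2, min)
  bins <- round(sweep(lo, 2, colmin) / step)  # integer offsets per column
  dist <- 1
  for (j in seq_len(ncol(bins))) {
    bj <- bins[, j]
    nd <- numeric(length(dist) + max(bj))
    for (b in 1:4) {
      idx <- seq_along(dist) + bj[b]
      nd[idx] <- nd[idx] + dist * bg[b]
    }
    dist <- nd
  }
  smin <- sum(colmin)
  list(step = step, smin = smin, smax = smin + (length(dist) - 1) * step,
       survival = rev(cumsum(rev(dist))))
}

#' P-value of a PWM site score
#'
#' Probability that a random L-mer drawn from the background model scores at
#' least `score` (one-sided upper tail). Scores outside the attainable
#' [smin, smax] range are clamped with a warning.
#'
#' @param pwm A `pwm` object.
#' @param score Numeric vector of log-odds scores.
#' @param dist Optional precomputed [score_distribution()]; computing it once
#'   and passing it in avoids repeating the convolution.
#' @return Numeric vector of tail probabilities in [0, 1].
#' @export
site_pvalue <- function(pwm, score, dist = NULL) {
  if (is.null(dist)) dist <- score_distribution(pwm)
  n <- length(dist$survival)
  qbin <- round((score - dist$smin) / dist$step) + 1
  if (any(qbin < 1 | qbin > n, na.rm = TRUE)) {
    warning("site_pvalue: score(s) outside attainable range [",
            format(dist$smin), ", ", format(dist$smax), "]; clamped")
    qbin <- pmin(pmax(qbin, 1), n)
  }
  dist$survival[qbin]
}

#' Consensus word of a motif
#' @param pwm A `pwm` object.
#' @return Character string of the per-column most probable bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}
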