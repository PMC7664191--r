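---
title: "Differential TF motif enrichment in condition-specific enhancers: methods"
author: "enhancerMotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential TF motif enrichment in condition-specific enhancers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerMotifs)
```

## The analysis this package implements

Active enhancers can be mapped genome-wide from chromatin marks such as
H3K27ac, and comparing the enhancer repertoires of two developmental
timepoints (or any two conditions) yields condition-specific enhancer sets.
A natural question follows: which upregulated transcription factors (TFs)
are plausibly driving the condition-specific set? This package answers it
with a reusable, fully testable pipeline:

1. **Expression filtering.** From a two-condition expression table, retain
   genes highly expressed in condition B (FPKM >= 10) and significantly
   upregulated relative to condition A (linear fold >= 2, q <= 0.05), then
   intersect with a TF catalog. All thresholds are inclusive and
   user-settable; the defaults are the conventional operating point for
   this analysis.
2. **Conserved binding-site prediction.** Scan both enhancer sets with the
   position weight matrices (PWMs) of the retained TFs, keeping matrices of
   high information content (>= 10 bits). A site is called where the
   relative match score is >= 0.8 and the exact score p-value is <= 0.05,
   and it is kept only if the orthologous sequence of a second species
   contains a match of the same motif (phylogenetic footprinting).
3. **Redundancy collapsing.** PWMs of paralogous TFs are often nearly
   identical; motifs with pairwise similarity >= 0.8 are grouped and the
   member occurring in the most condition-B enhancers represents its group.
4. **Differential enrichment.** For each representative, the fraction of
   condition-B enhancers containing at least one conserved site is divided
   by the same fraction in condition A (the *enrichment fold*), with a
   one-sided hypergeometric test and Bonferroni correction; motifs with
   fold >= 1.5 and corrected p <= 0.05 are reported.
5. **Downstream interpretation.** The enhancers carrying the top motif are
   assigned to their single nearest gene (GREAT-style), tested for
   functional-term enrichment, and the predicted target genes are tested
   for overlap with an independent knockdown-downregulated gene set.

## Scoring model and the exact site p-value

A PWM column *j* gives probabilities $p_{jb}$ over bases $b$. A window
$w_1 \dots w_L$ scores $S = \sum_j \log_2(p_{j w_j} / q_{w_j})$ against the
background $q$ (uniform by default, overridable). Probabilities are floored
at $10^{-4}$ before the logarithm so indicator-like columns stay finite.
The *relative match score* rescales $S$ to $[0,1]$ between the worst- and
best-possible sums of the matrix, which makes the 0.8 match threshold
comparable across motifs; it is invariant to per-column affine shifts of
the log-odds.

The site p-value is $P(S_{\text{random}} \ge s)$ for a random L-mer drawn
from the background, computed by exact dynamic programming: the per-column
score distributions (four atoms each) are convolved on a score grid of
granularity $10^{-4}$. One refinement matters: the log-odds matrix itself
is quantised to that grid *before* scanning, so every score the scanner can
produce lies exactly on the grid and the convolution is exact for those
queries — there is no rounding mismatch between a scanned score and its own
probability mass. The test suite verifies the DP tail against brute-force
enumeration of all $4^L$ words for widths up to 8, where agreement is exact
to floating-point error. Scores of plus- and minus-strand windows use the
matrix and its reverse complement; for complement-asymmetric backgrounds
the two null distributions are computed separately. Windows containing N
are skipped rather than scored, since their background probability is
undefined.

```{r pvalue-example}
pwm <- new_pwm("demo", matrix(c(0.7, 0.1, 0.1, 0.1,
                                0.1, 0.7, 0.1, 0.1), nrow = 4))
d <- score_distribution(pwm)
site_pvalue(pwm, c(d$smin, d$smax), d)  # all words qualify; only the best
```

## Conservation, and what it stands in for

Phylogenetic footprinting in the original analyses maps each enhancer to an
orthologous region through a whole-genome alignment. That machinery is out
of scope here; instead the pipeline consumes an explicit *ortholog sequence
map* (enhancer name to ortholog sequence id). A site is conserved when the
mapped ortholog contains at least one match of the same motif at the same
relative-score threshold, on either strand; positional orthology within the
region is deliberately not required, since alignment coordinates are not
part of the contract. Unmapped enhancers are counted and treated as
non-conserved. Identical filters — including conservation — are applied to
both enhancer sets before any counting, so the enrichment fold compares
like with like.

## Motif similarity and grouping

No similarity metric is canonical for "motifs at threshold 0.8", so the
package uses a Tomtom-like but deliberately simple definition: the maximum,
over all ungapped column offsets with at least four overlapping columns and
both orientations, of the Pearson correlation between the flattened
overlapping probability columns. Grouping is single linkage (connected
components of the thresholded similarity graph): the simplest semantics
consistent with "grouping", stated explicitly so alternatives can be
plugged in. The representative is the member present in the most
condition-B enhancers, ties broken lexicographically, which makes the
partition independent of input order.

## Enrichment statistic

Presence is counted per enhancer (a motif occurring three times in one
enhancer counts once), so overlapping or repeated sites cannot inflate the
statistic. With $k_A, k_B$ enhancers containing the motif out of
$n_A, n_B$, the fold is $(k_B/n_B)/(k_A/n_A)$, $+\infty$ when the motif is
absent from set A but present in B, and 1 when absent from both. The test
is the one-sided hypergeometric upper tail with the pooled enhancers as the
universe and set B as the draw — the natural margin of the 2x2 table; the
paper-facing alternative framings differ only in which margin is fixed.
Bonferroni multiplies by the number of cluster representatives actually
tested, not the raw library size. Under equal planted frequencies the
family-wise rate of the full selection step stays well below 0.05 (the
acceptance suite measures about 0.001 over 2000 motif tests — Bonferroni
plus the fold cutoff is conservative).

## Region-gene association and term enrichment

Gene assignment follows the single-nearest-gene reading: the anchor is the
region midpoint (stated explicitly because conventions differ) and the
assigned gene is the nearest TSS within 1 Mb, ties toward the smaller gene
id. Regulatory domains extend from each TSS to the midpoint toward each
neighbour, capped at 1 Mb per side and clipped to chromosome bounds, so
domains tile without overlap and midpoint-in-domain membership agrees with
nearest-TSS assignment wherever a domain exists (a property the test suite
checks by construction). Curated regulatory-domain exceptions of the
original GREAT tool are knowingly not reproduced.

Two term statistics are computed side by side, because region-based tables
are conventionally filtered on a gene-based ("hypergeometric") fold even
though the native region statistic is binomial: (i) the binomial tail
$P(\mathrm{Bin}(n, p_t) \ge k)$ where $p_t$ is the fraction of the
assignable genome (union of domains) covered by the term's domains, and
(ii) the hypergeometric tail on distinct assigned genes. Both are
BH-adjusted across terms. The term filters (fold >= 2, FDR <= 0.05, >= 5
associated genes) apply to the gene-based pair; ranking is by FDR.

For the target-versus-knockdown overlap test the universe is an explicit
parameter, defaulting to the genes tested for differential expression in
the supplied DE table. Published overlap p-values of this kind depend on an
unstated universe; making it explicit lets any candidate universe be
probed, and the package asserts calibration (uniform randomised-PIT of the
null p-value) rather than any particular printed number.

## The synthetic-data generator

`synth_config()` fixes the benchmark conditions: two sets of 300 enhancers
of 500 bp, uniform base composition (GC adjustable, since score p-values
depend on background), a library of ten sharp width-14 PWMs (dominant
probability 0.97, IC about 24.6 bits, comfortably past the 10-bit filter),
one motif planted at per-enhancer probability 0.05 in set A versus 0.30 in
set B with conservation probability 0.9, and nine unplanted nulls. Planted
instances are *sampled from the PWM columns*, not pasted as consensus, so
planted sites have realistically varying match scores (a consensus-only
mode exists for exact-recall tests). Each enhancer's ortholog is an
identical copy except that a failed conservation draw rerandomises only the
instance window, keeping flanks identical — this isolates the conservation
filter's effect from everything else. Width 14 was chosen so that chance
matches at the 0.8 relative-score threshold (which tolerates two worst-case
mismatches, since the relative score of a k-mismatch word is $1 - k/L$ for
uniform sharp columns) occur in well under 1% of enhancers; shorter sharp
motifs admit enough two-mismatch background hits to bias the fold toward 1.

Expression tables plant upregulated genes strictly separated from the
selection thresholds (fold >= 2.5, FPKM >= 12, q <= 0.01 versus null folds
capped at 1.8), so filter recovery is exact by construction and any
deviation is a bug, not noise. DE tables plant a configured fraction of a
target set into the downregulated genes; with `overlap_frac = NULL` the
down set is drawn uniformly, the null configuration used for calibration.

What the generator does *not* emulate: real enhancer base composition and
repeat structure, clustered or homotypic sites, alignment errors in the
ortholog map, and motif libraries with correlated (paralogous) matrices
beyond what the redundancy module is separately tested on. Passing the
benchmark therefore demonstrates correctness of the statistics and the
plumbing under known truth, not performance on any particular genome.

## Benchmark results the suite recomputes

With the default conditions (one motif at 0.30 vs 0.05, conservation 0.9,
nine nulls, 300 enhancers per set), 50 seeded replicates recover the
planted motif with no null false positive in every replicate, and the mean
estimated fold is within one per-replicate binomial standard error of the
planted ratio 6.0 (the ratio estimator's $1/k_A$ bias pushes it slightly
above 6). These numbers, the DP-versus-enumeration error, the family-wise
type-I rate, the planted-term ORA rank rate and the expression-filter
recovery are recomputed from scratch by `scripts/acceptance.R`.

## Problem sizes and numerical choices

Replicate counts (50 for motif recovery, 200 for type-I, 100 for ORA
ranking) and enhancer counts (300 per set) are the package's benchmark
conditions; they keep each property estimate's Monte-Carlo error small
relative to its acceptance margin. The score grid at $10^{-4}$ bounds
per-PWM distribution arrays at about one million entries for the default
motif widths. Degenerate inputs are handled explicitly: empty enhancer
sets, empty motif libraries (warning), all-N sequences (no sites), motifs
absent from one set (fold conventions above), terms annotating no gene with
a domain (skipped with a warning), and empty target sets (p = 1 with a
warning). Ties are always broken lexicographically after a radix sort, so
results are locale-independent and byte-stable across reruns.

## A small end-to-end run

```{r pipeline, message = FALSE}
cfg <- synth_config(seed = 11, n_enhancers_a = 40, n_enhancers_b = 40,
                    enhancer_length = 300, n_tfs = 400,
                    pwms = {set.seed(11); synth_pwm_library(6, width = 12)},
                    plant_prob_a = c(0.05, rep(0, 5)),
                    plant_prob_b = c(0.5, rep(0, 5)))
fx <- generate_pipeline_fixture(cfg)
res <- run_pipeline(fx)
res$selected[, c("motif_id", "k_a", "k_b", "fold", "p_bonf")]
res$target_overlap
```

The selected motif is the planted one (its synthetic id is the TF gene
symbol the fixture assigned it), and the overlap test flags the planted
target/knockdown relationship.

## Known limitations

- Conservation is presence-based within the mapped ortholog sequence, not
  alignment-positional; a distant spurious match in a long ortholog region
  counts as conserved.
- The similarity metric and single-linkage rule are explicit substitutes
  for an unstated grouping procedure; different choices change cluster
  granularity (they are parameters, not constants, for that reason).
- The binomial region test inherits GREAT's assumption that regions are
  independent draws; clustered enhancer sets violate it.
- Bit-exact reproduction of published counts from the motivating analyses
  requires their genome builds, alignment chains and deposited data, which
  are inputs, not parts, of this package.
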