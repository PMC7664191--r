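# Seeded synthetic-data generator: two enhancer sets with per-motif planted
# occurrence proportions, ortholog copies with controlled conservation,
# expression tables with known upregulated genes and TF labels, DE tables
# with known overlap structure, and gene-set collections with one planted
# enriched term. Every generator is deterministic under the config seed.

#' Generate a library of sharp synthetic motifs
#'
#' Random-consensus PWMs with `dominant` probability on the consensus base
#' and the remainder spread evenly, mimicking the high-information-content
#' matrices a curated library retains (IC per column =
#' 2 + d log2 d + (1-d) log2((1-d)/3)).
#'
#' @param n_motifs Number of motifs.
#' @param width Motif width in bp (default 14).
#' @param dominant Consensus-base probability (default 0.97).
#' @param motif_ids Optional ids (default synthM01, synthM02, ...).
#' @param background Background model attached to each pwm.
#' @return List of `pwm` objects, named by motif_id.
#' @export
synth_pwm_library <- function(n_motifs = 10, width = 14, dominant = 0.97,
                              motif_ids = NULL,
                              background = rep(0.25, 4)) {
  if (is.null(motif_ids))
    motif_ids <- sprintf("synthM%02d", seq_len(n_motifs))
  stopifnot(length(motif_ids) == n_motifs)
  pwms <- lapply(seq_len(n_motifs), function(i) {
    cons <- sample.int(4, width, replace = TRUE)
    probs <- matrix((1 - dominant) / 3, nrow = 4, ncol = width)
    probs[cbind(cons, seq_len(width))] <- dominant
    new_pwm(motif_ids[i], probs, background = background)
  })
  stats::setNames(pwms, motif_ids)
}

#' Synthetic-data configuration
#'
#' Bundles the knobs of the generators with validation. The defaults are
#' the benchmark conditions used throughout the package: 300 enhancers per
#' set of 500 bp, a 10-motif library with one motif planted at per-enhancer
#' probability 0.05 (set A) versus 0.30 (set B) and conservation 0.9, the
#' other nine motifs unplanted; 2000 genes of which 10% are upregulated and
#' 150 are TFs.
#'
#' @param seed Integer seed fixing every generated byte.
#' @param n_enhancers_a,n_enhancers_b Enhancers per set.
#' @param enhancer_length Enhancer length in bp.
#' @param pwms Motif library (list of `pwm`); default [synth_pwm_library()]
#'   drawn deterministically from `seed`.
#' @param plant_prob_a,plant_prob_b Per-motif planting probabilities (one
#'   value per motif, recycled if length 1).
#' @param conservation_prob Probability a planted instance is retained in
#'   the ortholog copy.
#' @param frac_unmapped Fraction of enhancers left out of the ortholog map.
#' @param gc GC content of background sequence (default 0.5).
#' @param consensus_only Plant exact consensus words instead of sampling
#'   instances from the PWM columns (for exact-recall tests).
#' @param n_genes,n_tfs,frac_upregulated Expression-table dimensions.
#' @param de_effect Minimum log2 fold separation of planted upregulated
#'   genes (default 1.32, i.e. linear fold >= 2.5).
#' @return A list with class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_enhancers_a = 300L, n_enhancers_b = 300L,
                         enhancer_length = 500L,
                         pwms = NULL,
                         plant_prob_a = c(0.05, rep(0, 9)),
                         plant_prob_b = c(0.30, rep(0, 9)),
                         conservation_prob = 0.9,
                         frac_unmapped = 0,
                         gc = 0.5,
                         consensus_only = FALSE,
                         n_genes = 2000L, n_tfs = 150L,
                         frac_upregulated = 0.1,
                         de_effect = 1.32) {
  if (is.null(pwms)) {
    set.seed(seed)
    pwms <- synth_pwm_library()
  }
  m <- length(pwms)
  if (length(plant_prob_a) == 1) plant_prob_a <- rep(plant_prob_a, m)
  if (length(plant_prob_b) == 1) plant_prob_b <- rep(plant_prob_b, m)
  stopifnot(length(plant_prob_a) == m, length(plant_prob_b) == m,
            all(plant_prob_a >= 0 & plant_prob_a <= 1),
            all(plant_prob_b >= 0 & plant_prob_b <= 1),
            conservation_prob >= 0, conservation_prob <= 1,
            frac_unmapped >= 0, frac_unmapped < 1,
            gc > 0, gc < 1, frac_upregulated >= 0, frac_upregulated <= 1)
  maxw <- max(vapply(pwms, pwm_width, integer(1)))
  if (enhancer_length < maxw)
    stop("synth_config: enhancer_length (", enhancer_length,
         ") shorter than the widest motif (", maxw, ")")
  structure(list(
    seed = as.integer(seed), n_enhancers_a = as.integer(n_enhancers_a),
    n_enhancers_b = as.integer(n_enhancers_b),
    enhancer_length = as.integer(enhancer_length), pwms = pwms,
    plant_prob_a = plant_prob_a, plant_prob_b = plant_prob_b,
    conservation_prob = conservation_prob, frac_unmapped = frac_unmapped,
    gc = gc, consensus_only = consensus_only,
    n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
    frac_upregulated = frac_upregulated, de_effect = de_effect),
    class = "synth_config")
}

.random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  DNA_BASES[sample.int(4, n, replace = TRUE, prob = p)]
}

.sample_instance <- function(pwm, consensus_only) {
  if (consensus_only) return(strsplit(pwm_consensus(pwm), "")[[1]])
  L <- pwm_width(pwm)
  vapply(seq_len(L), function(j)
    DNA_BASES[sample.int(4, 1, prob = pwm$probs[, j])], character(1))
}

# Plant motif instances into one set of background sequences.
# Returns list(seqs = character matrix rows, truth rows).
.plant_set <- function(cfg, n_enh, plant_prob, prefix) {
  len <- cfg$enhancer_length
  seqs <- vector("list", n_enh)
  truth <- list()
  for (i in seq_len(n_enh)) {
    s <- .random_dna(len, cfg$gc)
    occupied <- logical(len)
    for (mi in seq_along(cfg$pwms)) {
      if (stats::runif(1) >= plant_prob[mi]) next
      pwm <- cfg$pwms[[mi]]
      L <- pwm_width(pwm)
      inst <- .sample_instance(pwm, cfg$consensus_only)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-")
        inst <- rev(c(T = "A", G = "C", C = "G", A = "T")[inst])
      placed <- FALSE
      for (try in 1:100) {
        off <- sample.int(len - L + 1L, 1) - 1L  # 0-based
        if (!any(occupied[(off + 1):(off + L)])) { placed <- TRUE; break }
      }
      if (!placed) next
      s[(off + 1):(off + L)] <- inst
      occupied[(off + 1):(off + L)] <- TRUE
      truth[[length(truth) + 1]] <- data.frame(
        set = prefix, enhancer = sprintf("enh%s_%03d", prefix, i),
        motif_id = pwm$motif_id, offset = off, strand = strand,
        stringsAsFactors = FALSE)
    }
    seqs[[i]] <- paste(s, collapse = "")
  }
  names(seqs) <- sprintf("enh%s_%03d", prefix, seq_len(n_enh))
  list(seqs = unlist(seqs),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(set = character(), enhancer = character(),
                    motif_id = character(), offset = integer(),
                    strand = character(), stringsAsFactors = FALSE))
}

#' Generate two enhancer sets with planted motif instances
#'
#' Background bases are drawn independently at the configured GC content;
#' each enhancer independently receives one instance per motif with its
#' set's planting probability, at a uniform random non-overlapping offset
#' and strand. Each enhancer gets an ortholog copy identical to it except
#' that every planted instance is retained only with probability
#' `conservation_prob` (otherwise only the instance window is
#' rerandomised, keeping the flanks identical). The truth table records
#' every plant and whether it was conserved.
#'
#' @param config A [synth_config()].
#' @return List with elements bed_a, bed_b (interval data.frames), genome
#'   (two chromosomes, one per set), ortholog_seqs, ortholog_map, truth.
#' @export
generate_enhancer_sets <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  # offset from the library-generation stream so background bases do not
  # replay the consensus draws
  set.seed(config$seed + 7L)
  gap <- 100L
  len <- config$enhancer_length
  setA <- .plant_set(config, config$n_enhancers_a, config$plant_prob_a, "A")
  setB <- .plant_set(config, config$n_enhancers_b, config$plant_prob_b, "B")
  truth <- rbind(setA$truth, setB$truth)
  truth$conserved <- logical(nrow(truth))
  all_seqs <- c(setA$seqs, setB$seqs)
  ortho <- all_seqs
  names(ortho) <- paste0("orth_", names(all_seqs))
  if (nrow(truth)) {
    widths <- vapply(config$pwms[truth$motif_id], pwm_width, integer(1))
    truth$conserved <- stats::runif(nrow(truth)) < config$conservation_prob
    for (r in which(!truth$conserved)) {
      oid <- paste0("orth_", truth$enhancer[r])
      s <- strsplit(ortho[[oid]], "")[[1]]
      w <- widths[r]
      idx <- (truth$offset[r] + 1):(truth$offset[r] + w)
      s[idx] <- .random_dna(w, config$gc)
      ortho[oid] <- paste(s, collapse = "")
    }
  }
  map <- data.frame(enhancer = names(all_seqs),
                    ortholog = paste0("orth_", names(all_seqs)),
                    stringsAsFactors = FALSE)
  if (config$frac_unmapped > 0) {
    drop <- sample.int(nrow(map), round(config$frac_unmapped * nrow(map)))
    if (length(drop)) map <- map[-drop, , drop = FALSE]
  }
  make_bed <- function(seqs, chrom) {
    n <- length(seqs)
    starts <- (seq_len(n) - 1L) * (len + gap)
    data.frame(chrom = rep(chrom, n), start = starts, end = starts + len,
               name = if (n) names(seqs) else character(),
               strand = rep(".", n), stringsAsFactors = FALSE)
  }
  genome <- c(
    chrA = paste(vapply(setA$seqs, function(s)
      paste0(s, strrep("N", gap)), character(1)), collapse = ""),
    chrB = paste(vapply(setB$seqs, function(s)
      paste0(s, strrep("N", gap)), character(1)), collapse = ""))
  list(bed_a = make_bed(setA$seqs, "chrA"),
       bed_b = make_bed(setB$seqs, "chrB"),
       genome = genome,
       ortholog_seqs = ortho, ortholog_map = map, truth = truth)
}

#' Generate a two-condition expression table with planted truth
#'
#' Planted upregulated genes get fold >= 2.5, condition-B FPKM >= 12 and
#' q-value <= 0.01, all strictly separated from the default selection
#' thresholds (10 / 2 / 0.05); null genes get fold capped below 1.8 and
#' uniform q-values, so the default filter recovers exactly the planted
#' set. A random subset of genes is labelled as TFs.
#'
#' @param config A [synth_config()].
#' @return List with `table` (expression data.frame) and `truth`
#'   (gene_id, is_up, is_tf).
#' @export
generate_expression_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  gene_id <- sprintf("gene%04d", seq_len(n))
  is_up <- seq_len(n) %in% sample.int(n, round(config$frac_upregulated * n))
  is_tf <- seq_len(n) %in% sample.int(n, config$n_tfs)
  min_fold <- max(2.5, 2^config$de_effect)
  fold <- ifelse(is_up, stats::runif(n, min_fold, 60),
                 pmin(2^stats::rnorm(n, 0, 0.3), 1.8))
  fpkm_b <- ifelse(is_up, stats::runif(n, 12, 300),
                   stats::rlnorm(n, meanlog = 2, sdlog = 1.2))
  fpkm_a <- fpkm_b / fold
  q_value <- ifelse(is_up, stats::runif(n, 0, 0.01), stats::runif(n))
  list(table = data.frame(gene_id = gene_id, fpkm_a = fpkm_a,
                          fpkm_b = fpkm_b, fold = fold, q_value = q_value,
                          stringsAsFactors = FALSE),
       truth = data.frame(gene_id = gene_id, is_up = is_up, is_tf = is_tf,
                          stringsAsFactors = FALSE))
}

#' Generate a knockdown differential-expression table with planted overlap
#'
#' Builds a DE table (gene, log2fc, padj) over `universe` in which a
#' controlled fraction of `target_genes` is planted into the downregulated
#' set; the remaining down and up genes are drawn from the non-targets.
#' Down/up genes get |log2fc| >= log2(1.5) and padj <= 0.01; null genes
#' stay below the fold threshold with uniform padj.
#'
#' @param universe Character vector of genes tested.
#' @param target_genes Predicted target genes (subset of universe).
#' @param overlap_frac Fraction of targets planted as downregulated;
#'   `NULL` plants nothing (the down set is drawn uniformly from the
#'   universe, the null configuration for calibration checks).
#' @param n_down,n_up Total down- and up-regulated genes.
#' @param seed Integer seed.
#' @return List with `table` and `truth` (gene, is_down, is_up).
#' @export
generate_de_table <- function(universe, target_genes, overlap_frac = 0.5,
                              n_down = 200L, n_up = 200L, seed = 1L) {
  set.seed(seed)
  stopifnot(all(target_genes %in% universe))
  n <- length(universe)
  if (is.null(overlap_frac)) {
    down <- sample(universe, min(n_down, n))
    up <- sample(setdiff(universe, down),
                 min(n_up, n - length(down)))
  } else {
    stopifnot(overlap_frac >= 0, overlap_frac <= 1)
    planted <- sample(target_genes,
                      round(overlap_frac * length(target_genes)))
    pool <- setdiff(universe, target_genes)
    n_down_extra <- max(0L, n_down - length(planted))
    extra <- sample(pool, min(n_down_extra, length(pool)))
    down <- c(planted, extra)
    up <- sample(setdiff(pool, extra),
                 min(n_up, length(pool) - length(extra)))
  }
  is_down <- universe %in% down
  is_up <- universe %in% up
  lfc_min <- log2(1.5)
  log2fc <- ifelse(is_down, -stats::runif(n, lfc_min, 3),
                   ifelse(is_up, stats::runif(n, lfc_min, 3),
                          stats::runif(n, -0.5 * lfc_min, 0.5 * lfc_min)))
  padj <- ifelse(is_down | is_up, stats::runif(n, 0, 0.01), stats::runif(n))
  list(table = data.frame(gene = universe, log2fc = log2fc, padj = padj,
                          stringsAsFactors = FALSE),
       truth = data.frame(gene = universe, is_down = is_down, is_up = is_up,
                          stringsAsFactors = FALSE))
}

#' Select downregulated genes from a DE table
#'
#' Applies the conventional knockdown filter: linear fold decrease of at
#' least `fold_min` and adjusted p at most `p_max`.
#'
#' @param de_table data.frame with gene, log2fc, padj.
#' @param fold_min Minimum linear fold change (default 1.5).
#' @param p_max Maximum adjusted p (default 0.05).
#' @param direction `"down"` or `"up"`.
#' @return Character vector of gene ids.
#' @export
de_gene_set <- function(de_table, fold_min = 1.5, p_max = 0.05,
                        direction = c("down", "up")) {
  direction <- match.arg(direction)
  lfc <- de_table$log2fc
  keep <- !is.na(lfc) & !is.na(de_table$padj) & de_table$padj <= p_max &
    (if (direction == "down") lfc <= -log2(fold_min) else
      lfc >= log2(fold_min))
  de_table$gene[keep]
}

#' Generate a gene-set collection with one planted enriched term
#'
#' Null terms annotate every gene with probability `base_prob`; the planted
#' term annotates genes inside `gene_list` with the odds scaled by
#' `odds_ratio`. Used to calibrate over-representation ranking.
#'
#' @param universe Character vector of genes.
#' @param gene_list Genes of interest driving the planted enrichment.
#' @param n_null_terms Number of null terms (default 20).
#' @param base_prob Baseline annotation probability (default 0.05).
#' @param odds_ratio Gene-level odds ratio of the planted term
#'   (default 5).
#' @param seed Integer seed.
#' @return List with `sets` (GMT-style named list) and `planted_term`.
#' @export
generate_gene_sets <- function(universe, gene_list, n_null_terms = 20L,
                               base_prob = 0.05, odds_ratio = 5,
                               seed = 1L) {
  set.seed(seed)
  stopifnot(all(gene_list %in% universe))
  odds0 <- base_prob / (1 - base_prob)
  p1 <- odds_ratio * odds0 / (1 + odds_ratio * odds0)
  in_list <- universe %in% gene_list
  sets <- list()
  p_plant <- ifelse(in_list, p1, base_prob)
  sets[["planted_term"]] <-
    universe[stats::runif(length(universe)) < p_plant]
  for (i in seq_len(n_null_terms)) {
    sets[[sprintf("null_term_%02d", i)]] <-
      universe[stats::runif(length(universe)) < base_prob]
  }
  sets <- sets[lengths(sets) > 0]
  list(sets = sets, planted_term = "planted_term")
}
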