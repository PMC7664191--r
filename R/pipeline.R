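# Pipeline orchestration: upregulated-TF filter -> conserved motif scan of
# both enhancer sets -> redundancy collapsing -> differential enrichment ->
# nearest-gene association -> term enrichment -> target/DE overlap.

#' Default pipeline thresholds
#'
#' The defaults are the analysis' printed operating point: expression
#' FPKM >= 10, fold >= 2, q <= 0.05; motif IC >= 10 bits; site match >= 0.8
#' with p <= 0.05; motif similarity grouping at 0.8; enrichment fold >= 1.5
#' with Bonferroni p <= 0.05; term fold >= 2, FDR <= 0.05, >= 5 genes;
#' 1 Mb association cap.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(fpkm_min = 10, fold_min = 2, q_max = 0.05,
       ic_min = 10, match_min = 0.8, site_p_max = 0.05,
       sim_min = 0.8, enrich_fold_min = 1.5, enrich_p_max = 0.05,
       term_fold_min = 2, term_fdr_max = 0.05, term_min_genes = 5,
       max_distance = 1e6, max_extension = 1e6,
       conservation = TRUE, restrict_motifs = TRUE,
       de_fold_min = 1.5, de_p_max = 0.05,
       seed = 1L)
}

# input resolvers: accept an in-memory object or a file path
.res_bed <- function(x) if (is.character(x) && length(x) == 1) read_bed(x) else x
.res_fasta <- function(x) if (is.character(x) && length(x) == 1) read_fasta(x) else x
.res_expr <- function(x) if (is.character(x) && length(x) == 1) read_expression_table(x) else x
.res_de <- function(x) if (is.character(x) && length(x) == 1) read_de_table(x) else x
.res_tfs <- function(x) if (is.character(x) && length(x) == 1) read_tf_list(x) else x
.res_gmt <- function(x) if (is.character(x) && length(x) == 1) read_gmt(x) else x
.res_omap <- function(x) if (is.character(x) && length(x) == 1) read_ortholog_map(x) else x
.res_tss <- function(x) if (is.character(x) && length(x) == 1)
  utils::read.delim(x, stringsAsFactors = FALSE) else x
.res_motifs <- function(x, format) {
  if (is.character(x) && length(x) == 1) read_motif_library(x, format) else x
}

#' Core motif stages: scan, conserve, deduplicate, test enrichment
#'
#' Runs the motif half of the pipeline on in-memory inputs: scan both
#' enhancer sequence sets on both strands, flag conservation against the
#' ortholog map (identical filters on both sets), count per-enhancer
#' presence, collapse redundant motifs (occurrences counted on set B,
#' where predictions are primary), and compute the differential enrichment
#' table over the cluster representatives.
#'
#' @param pwms Motif library (list of `pwm`).
#' @param seqs_a,seqs_b Named character vectors of enhancer sequences.
#' @param ortholog_map,ortholog_seqs Conservation inputs (NULL disables the
#'   conservation filter together with `params$conservation = FALSE`).
#' @param params Parameter list (see [default_params()]); partial lists are
#'   completed with the defaults.
#' @param dists Optional precomputed score distributions (named by
#'   motif_id), reused across replicate runs.
#' @return List with sites_a, sites_b (conservation-filtered),
#'   occurrences_b, clusters, enrichment, selected.
#' @export
run_motif_stages <- function(pwms, seqs_a, seqs_b, ortholog_map = NULL,
                             ortholog_seqs = NULL, params = list(),
                             dists = NULL) {
  params <- utils::modifyList(default_params(), params)
  if (is.null(dists)) dists <- precompute_dists(pwms)
  sites_a <- scan_enhancers(pwms, seqs_a, match_min = params$match_min,
                            p_max = params$site_p_max, dists = dists)
  sites_b <- scan_enhancers(pwms, seqs_b, match_min = params$match_min,
                            p_max = params$site_p_max, dists = dists)
  if (isTRUE(params$conservation) && !is.null(ortholog_map)) {
    sites_a <- apply_conservation(sites_a, ortholog_map, ortholog_seqs,
                                  pwms, match_min = params$match_min)
    sites_b <- apply_conservation(sites_b, ortholog_map, ortholog_seqs,
                                  pwms, match_min = params$match_min)
    sites_a <- sites_a[sites_a$conserved, , drop = FALSE]
    sites_b <- sites_b[sites_b$conserved, , drop = FALSE]
  }
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  occ_b <- count_presence(sites_b, names(seqs_b), motif_ids = ids)
  clusters <- cluster_motifs(pwms, occ_b, sim_min = params$sim_min)
  reps <- clusters$representative
  occ_a <- count_presence(sites_a, names(seqs_a), motif_ids = ids)
  enrichment <- motif_enrichment(occ_a[reps], occ_b[reps],
                                 n_a = length(seqs_a), n_b = length(seqs_b),
                                 fold_min = params$enrich_fold_min,
                                 p_max = params$enrich_p_max)
  selected <- select_enriched(enrichment,
                              fold_min = params$enrich_fold_min,
                              p_max = params$enrich_p_max)
  list(sites_a = sites_a, sites_b = sites_b, occurrences_b = occ_b,
       clusters = clusters, enrichment = enrichment, selected = selected)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: expression filtering and TF restriction; motif
#' library information-content filtering (and restriction to motifs of
#' upregulated TFs when an expression table and TF catalog are supplied);
#' PWM scanning of both enhancer sets with conservation filtering; motif
#' redundancy collapsing; differential motif enrichment and selection;
#' nearest-gene association of the enhancers carrying the top enriched
#' motif; region-based term enrichment of those enhancers; and the overlap
#' test between predicted target genes and the knockdown-downregulated
#' set. Each input may be an in-memory object or a file path.
#'
#' @param config Named list (or path to a YAML file) with entries
#'   enhancers_a, enhancers_b, genome, motifs (+ optional motif_format),
#'   and optionally ortholog_map, ortholog_seqs, expression, tf_list, tss,
#'   gene_sets, de_table, params.
#' @param outdir Optional output directory; when given, every stage table,
#'   a summary, the resolved configuration and the run log are written
#'   there.
#' @return List of stage results plus `counts` (the stage-count ledger)
#'   and `params`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("run_pipeline: config file not found: ",
                                   config)
    config <- yaml::read_yaml(config)
  }
  params <- utils::modifyList(default_params(),
                              if (is.null(config$params)) list() else
                                config$params)
  set.seed(params$seed)
  logline <- character()
  note <- function(...) {
    msg <- paste0(...)
    logline <<- c(logline, msg)
    message(msg)
  }
  for (need in c("enhancers_a", "enhancers_b", "genome", "motifs")) {
    if (is.null(config[[need]]))
      stop("run_pipeline: required input '", need, "' is missing")
    if (is.character(config[[need]]) && length(config[[need]]) == 1 &&
        !file.exists(config[[need]]))
      stop("run_pipeline: input '", need, "' file not found: ",
           config[[need]])
  }

  # stage 1: expression filter and TF restriction
  expr_filtered <- NULL
  up_tfs <- NULL
  if (!is.null(config$expression)) {
    expr <- .res_expr(config$expression)
    expr_filtered <- filter_upregulated(expr, fpkm_min = params$fpkm_min,
                                        fold_min = params$fold_min,
                                        q_max = params$q_max)
    note("expression: ", nrow(expr), " genes in, ", nrow(expr_filtered),
         " upregulated past filters")
    if (!is.null(config$tf_list)) {
      tfs <- .res_tfs(config$tf_list)
      expr_filtered_tf <- restrict_to_tfs(expr_filtered, tfs)
      up_tfs <- expr_filtered_tf$gene_id
      note("expression: ", length(up_tfs), " upregulated TFs")
    }
  }

  # stage 2: motif library, IC filter, optional TF restriction
  pwms <- .res_motifs(config$motifs,
                      if (is.null(config$motif_format)) "meme-minimal" else
                        config$motif_format)
  n_lib <- length(pwms)
  ic <- vapply(pwms, information_content, numeric(1))
  pwms <- pwms[ic >= params$ic_min]
  note("motifs: ", n_lib, " in library, ", length(pwms),
       " with IC >= ", params$ic_min)
  if (!is.null(up_tfs) && isTRUE(params$restrict_motifs)) {
    keep <- vapply(pwms, function(p) {
      toupper(p$motif_id) %in% toupper(up_tfs) ||
        (!is.null(p$altname) && toupper(p$altname) %in% toupper(up_tfs))
    }, logical(1))
    pwms <- pwms[keep]
    note("motifs: ", length(pwms), " belong to upregulated TFs")
  }
  if (length(pwms) == 0) stop("run_pipeline: no motifs left to scan")

  # stage 3: sequences
  genome <- .res_fasta(config$genome)
  bed_a <- .res_bed(config$enhancers_a)
  bed_b <- .res_bed(config$enhancers_b)
  seqs_a <- extract_sequences(genome, bed_a)
  seqs_b <- extract_sequences(genome, bed_b)
  note("enhancers: ", length(seqs_a), " in set A, ", length(seqs_b),
       " in set B")

  # stages 4-6: scan, conserve, deduplicate, enrich
  omap <- if (!is.null(config$ortholog_map)) .res_omap(config$ortholog_map)
  oseq <- if (!is.null(config$ortholog_seqs)) .res_fasta(config$ortholog_seqs)
  ms <- run_motif_stages(pwms, seqs_a, seqs_b, omap, oseq, params)
  note("sites: ", nrow(ms$sites_a), " conserved in set A, ",
       nrow(ms$sites_b), " in set B")
  note("clusters: ", nrow(ms$clusters), " motif cluster(s) from ",
       length(pwms), " motifs")
  note("enrichment: ", nrow(ms$selected), " motif(s) pass fold >= ",
       params$enrich_fold_min, " and Bonferroni p <= ", params$enrich_p_max)

  # stages 7-9: association, term enrichment, target/DE overlap
  assignments <- NULL
  term_results <- NULL
  term_filtered <- NULL
  overlap <- NULL
  target_genes <- NULL
  if (nrow(ms$selected) > 0 && !is.null(config$tss)) {
    top <- ms$selected$motif_id[1]
    top_enh <- unique(ms$sites_b$enhancer_name[ms$sites_b$motif_id == top])
    top_bed <- bed_b[bed_b$name %in% top_enh, , drop = FALSE]
    tss <- .res_tss(config$tss)
    assignments <- assign_nearest_gene(top_bed, tss,
                                       max_distance = params$max_distance)
    target_genes <- sort(unique(assignments$gene_id[
      !is.na(assignments$gene_id)]), method = "radix")
    note("association: top motif ", top, " in ", nrow(top_bed),
         " set-B enhancers, ", length(target_genes), " target genes")
    if (!is.null(config$gene_sets)) {
      gmt <- .res_gmt(config$gene_sets)
      domains <- build_domains(tss, max_extension = params$max_extension)
      term_results <- region_term_enrichment(top_bed, domains, gmt)
      term_filtered <- apply_term_filters(term_results,
                                          fold_min = params$term_fold_min,
                                          fdr_max = params$term_fdr_max,
                                          min_genes = params$term_min_genes)
      note("terms: ", nrow(term_results), " tested, ",
           nrow(term_filtered), " pass term filters")
    }
    if (!is.null(config$de_table)) {
      de <- .res_de(config$de_table)
      down <- de_gene_set(de, fold_min = params$de_fold_min,
                          p_max = params$de_p_max, direction = "down")
      overlap <- target_de_overlap(target_genes, down, de$gene)
      note("overlap: ", overlap$overlap, " of ", overlap$target_set_size,
           " targets downregulated (p = ",
           format(overlap$hyper_p, digits = 3), ")")
    }
  }

  result <- list(expression_filtered = expr_filtered, upregulated_tfs = up_tfs,
                 motifs_kept = pwms, sites_a = ms$sites_a,
                 sites_b = ms$sites_b, clusters = ms$clusters,
                 enrichment = ms$enrichment, selected = ms$selected,
                 assignments = assignments, target_genes = target_genes,
                 term_enrichment = term_results,
                 term_filtered = term_filtered,
                 target_overlap = overlap, counts = logline, params = params)
  if (!is.null(outdir)) .write_bundle(result, config, outdir)
  result
}

.write_bundle <- function(result, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) if (!is.null(df))
    write_results(df, file.path(outdir, file))
  wr(result$expression_filtered, "filtered_expression.tsv")
  wr(result$sites_a, "sites_a.tsv")
  wr(result$sites_b, "sites_b.tsv")
  wr(result$clusters, "clusters.tsv")
  wr(result$enrichment, "motif_enrichment.tsv")
  wr(result$assignments, "region_assignments.tsv")
  wr(result$term_enrichment, "term_enrichment.tsv")
  wr(result$target_overlap, "target_overlap.tsv")
  provenance <- lapply(config[setdiff(names(config), "params")], function(x)
    if (is.character(x) && length(x) == 1) x else "<in-memory>")
  yaml::write_yaml(list(inputs = provenance, params = result$params),
                   file.path(outdir, "resolved_config.yaml"))
  writeLines(result$counts, file.path(outdir, "run.log"))
  summary_md <- c(
    "# Pipeline summary", "",
    paste0("- ", result$counts), "",
    if (nrow(result$selected) > 0)
      c("## Enriched motifs", "",
        paste0("- ", result$selected$motif_id, ": fold ",
               format(result$selected$fold, digits = 4), ", Bonferroni p ",
               format(result$selected$p_bonf, digits = 3)))
    else "No motif passed the enrichment thresholds.")
  writeLines(summary_md, file.path(outdir, "summary.md"))
  invisible(outdir)
}

#' Generate a complete synthetic pipeline fixture
#'
#' Builds every input the full pipeline consumes, wired together so the
#' planted structure propagates end to end: enhancer sets with a planted
#' motif, ortholog conservation, an expression table whose upregulated TFs
#' lend their names to the motif library (so the TF-restriction stage keeps
#' all motifs), one gene TSS per set-B enhancer, a gene-set collection with
#' one term enriched in the planted motif's target genes, and a DE table
#' with a planted fraction of those targets downregulated.
#'
#' @param config A [synth_config()].
#' @param overlap_frac Fraction of planted-motif target genes planted as
#'   knockdown-downregulated (default 0.5).
#' @return List with all `run_pipeline()` inputs plus `truth`.
#' @export
generate_pipeline_fixture <- function(config, overlap_frac = 0.5) {
  stopifnot(inherits(config, "synth_config"))
  ex <- generate_expression_table(config)
  up_tf <- sort(ex$truth$gene_id[ex$truth$is_up & ex$truth$is_tf],
                method = "radix")
  n_m <- length(config$pwms)
  if (length(up_tf) < n_m)
    stop("generate_pipeline_fixture: only ", length(up_tf),
         " upregulated TFs for ", n_m, " motifs; increase n_tfs")
  # name motifs after upregulated TFs so the restriction stage keeps them
  motif_tfs <- up_tf[seq_len(n_m)]
  pwms <- config$pwms
  for (i in seq_len(n_m)) pwms[[i]]$motif_id <- motif_tfs[i]
  names(pwms) <- motif_tfs
  config$pwms <- pwms
  enh <- generate_enhancer_sets(config)
  # one gene per set-B enhancer, TSS at the enhancer midpoint so each
  # enhancer's nearest gene is unambiguously its own
  n_b <- config$n_enhancers_b
  tss <- data.frame(gene_id = sprintf("rgene%03d", seq_len(n_b)),
                    chrom = "chrB",
                    tss = floor((enh$bed_b$start + enh$bed_b$end) / 2),
                    strand = "+", stringsAsFactors = FALSE)
  planted_enh <- enh$truth$enhancer[enh$truth$set == "B" &
                                      enh$truth$motif_id == motif_tfs[1]]
  target_genes <- tss$gene_id[match(planted_enh, enh$bed_b$name)]
  gs <- generate_gene_sets(tss$gene_id, target_genes,
                           seed = config$seed + 2L)
  de <- generate_de_table(tss$gene_id, target_genes,
                          overlap_frac = overlap_frac,
                          n_down = max(10L, round(0.15 * n_b)),
                          n_up = max(10L, round(0.15 * n_b)),
                          seed = config$seed + 3L)
  list(enhancers_a = enh$bed_a, enhancers_b = enh$bed_b,
       genome = enh$genome, motifs = pwms,
       ortholog_map = enh$ortholog_map, ortholog_seqs = enh$ortholog_seqs,
       expression = ex$table, tf_list = ex$truth$gene_id[ex$truth$is_tf],
       tss = tss, gene_sets = gs$sets, de_table = de$table,
       truth = list(enhancers = enh$truth, expression = ex$truth,
                    de = de$truth, planted_motif = motif_tfs[1],
                    planted_term = gs$planted_term,
                    target_genes = target_genes))
}
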