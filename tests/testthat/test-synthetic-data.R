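# Synthetic-data generators: determinism, planted structure, calibration.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 5, n_enhancers_a = 20, n_enhancers_b = 20,
                      enhancer_length = 120)
  e1 <- generate_enhancer_sets(cfg)
  e2 <- generate_enhancer_sets(cfg)
  expect_identical(e1, e2)
  x1 <- generate_expression_table(cfg)
  x2 <- generate_expression_table(cfg)
  expect_identical(x1, x2)
  d1 <- generate_de_table(x1$table$gene_id, x1$table$gene_id[1:20], seed = 3)
  d2 <- generate_de_table(x1$table$gene_id, x1$table$gene_id[1:20], seed = 3)
  expect_identical(d1, d2)
  # a different seed changes the sequences
  cfg2 <- synth_config(seed = 6, n_enhancers_a = 20, n_enhancers_b = 20,
                       enhancer_length = 120, pwms = cfg$pwms)
  expect_false(identical(generate_enhancer_sets(cfg2)$genome, e1$genome))
})

test_that("planted counts fall in the binomial range and zero plants zero", {
  withr::local_seed(23)
  pwms <- synth_pwm_library(n_motifs = 2, width = 10)
  counts <- vapply(1:5, function(r) {
    cfg <- synth_config(seed = 100 + r, pwms = pwms,
                        n_enhancers_a = 10, n_enhancers_b = 100,
                        plant_prob_a = 0, plant_prob_b = c(0.4, 0))
    tr <- generate_enhancer_sets(cfg)$truth
    sum(tr$set == "B" & tr$motif_id == pwms[[1]]$motif_id)
  }, numeric(1))
  lo <- qbinom(0.005, 100, 0.4)
  hi <- qbinom(0.995, 100, 0.4)
  expect_true(all(counts >= lo & counts <= hi))
  # nothing planted anywhere when all probabilities are zero
  cfg0 <- synth_config(seed = 1, pwms = pwms, n_enhancers_a = 10,
                       n_enhancers_b = 10, plant_prob_a = 0,
                       plant_prob_b = 0)
  expect_equal(nrow(generate_enhancer_sets(cfg0)$truth), 0)
})

test_that("conserved plants survive in the ortholog, failed ones are rewritten", {
  cfg <- synth_config(seed = 41, n_enhancers_a = 0, n_enhancers_b = 60,
                      plant_prob_a = 0,
                      plant_prob_b = c(1, rep(0, 9)),
                      conservation_prob = 0.5, consensus_only = TRUE)
  enh <- generate_enhancer_sets(cfg)
  cons_word <- pwm_consensus(cfg$pwms[[1]])
  for (r in seq_len(nrow(enh$truth))) {
    tr <- enh$truth[r, ]
    oid <- paste0("orth_", tr$enhancer)
    window <- substr(enh$ortholog_seqs[[oid]], tr$offset + 1,
                     tr$offset + nchar(cons_word))
    planted_word <- if (tr$strand == "+") cons_word else revcomp(cons_word)
    if (tr$conserved) {
      expect_equal(window, planted_word)
    } else {
      expect_false(window == planted_word)
    }
  }
  # conservation flags themselves are Bernoulli(conservation_prob)
  expect_gt(mean(enh$truth$conserved), 0.25)
  expect_lt(mean(enh$truth$conserved), 0.75)
})

test_that("expression generator separates planted genes from the thresholds", {
  cfg <- synth_config(seed = 77)
  ex <- generate_expression_table(cfg)
  up <- ex$truth$is_up
  expect_true(all(ex$table$fold[up] >= 2.5))
  expect_true(all(ex$table$fpkm_b[up] >= 12))
  expect_true(all(ex$table$q_value[up] <= 0.01))
  expect_true(all(ex$table$fold[!up] < 2))
  # with nothing planted the default filter recovers nothing
  cfg0 <- synth_config(seed = 78, frac_upregulated = 0)
  ex0 <- generate_expression_table(cfg0)
  expect_equal(nrow(filter_upregulated(ex0$table)), 0)
})

test_that("planted target overlap beats the null and the null p is calibrated", {
  universe <- sprintf("g%04d", 1:800)
  targets <- universe[1:40]
  de1 <- generate_de_table(universe, targets, overlap_frac = 1,
                           n_down = 160, seed = 11)
  de0 <- generate_de_table(universe, targets, overlap_frac = NULL,
                           n_down = 160, seed = 11)
  p1 <- target_de_overlap(targets, de_gene_set(de1$table), universe)$hyper_p
  p0 <- target_de_overlap(targets, de_gene_set(de0$table), universe)$hyper_p
  expect_lt(p1, p0)
  expect_lt(p1, 1e-6)
  # null calibration: the randomised PIT of the discrete hypergeometric
  # p-value is uniform when the down set is drawn independently
  withr::local_seed(91)
  u <- vapply(1:200, function(r) {
    de <- generate_de_table(universe, targets, overlap_frac = NULL,
                            n_down = 160, seed = 5000 + r)
    down <- de_gene_set(de$table)
    res <- target_de_overlap(targets, down, universe)
    p_ge <- res$hyper_p
    p_gt <- stats::phyper(res$overlap, res$de_set_size,
                          res$universe_size - res$de_set_size,
                          res$target_set_size, lower.tail = FALSE)
    p_gt + runif(1) * (p_ge - p_gt)
  }, numeric(1))
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("an enhancer shorter than the widest motif is rejected", {
  expect_error(synth_config(seed = 1, enhancer_length = 10),
               "shorter than the widest motif")
})
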