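# Term enrichment statistics: BH FDR, region binomial test, gene-list ORA,
# term filters and target/DE overlap.

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  withr::local_seed(4)
  p <- runif(30)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  perm <- sample(30)
  expect_equal(sort(bh_fdr(p[perm])), sort(adj))
  # direct step-up for a random vector
  m <- length(p)
  o <- order(p)
  manual <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(adj[o], pmin(1, manual))
})

# four genes with 250-bp domains on one chromosome; term coverage and
# region hits are then fully controlled
toy_domains <- function() {
  data.frame(gene_id = c("gA", "gB", "gC", "gD"), chrom = "chr1",
             start = c(0, 250, 500, 750), end = c(250, 500, 750, 1000),
             stringsAsFactors = FALSE)
}

toy_regions <- function(mids) {
  data.frame(chrom = "chr1", start = mids - 5, end = mids + 5,
             name = sprintf("r%02d", seq_along(mids)),
             stringsAsFactors = FALSE)
}

test_that("region binomial tail matches exact summation on a controlled case", {
  # term = gA: p_term = 250/1000 = 0.25; 4 of 6 region midpoints in gA
  regions <- toy_regions(c(10, 60, 110, 160, 510, 760))
  res <- region_term_enrichment(regions, toy_domains(),
                                list(hitA = "gA"))
  expect_equal(res$p_term, 0.25)
  expect_equal(res$k_regions, 4)
  expect_equal(res$binom_p, enum_binom_ge(4, 6, 0.25), tolerance = 1e-12)
  expect_equal(res$fold_enrich, 4 / (6 * 0.25))
  # gene route: universe 4, term 1, hit genes {gA,gC,gD} -> overlap 1
  expect_equal(res$gene_hits, 1)
  expect_equal(res$hyper_p, enum_hyper_ge(1, 1, 4, 3), tolerance = 1e-12)
})

test_that("degenerate region terms behave as stated", {
  regions <- toy_regions(c(10, 510, 760))
  # term covering the whole assignable genome: p_term = 1, tail = 1
  res <- suppressWarnings(region_term_enrichment(
    regions, toy_domains(),
    list(all = c("gA", "gB", "gC", "gD"), none = "gB", ghost = "gZ")))
  all_row <- res[res$term == "all", ]
  expect_equal(all_row$p_term, 1)
  expect_equal(all_row$binom_p, 1)
  expect_lte(all_row$fold_enrich, 1)
  # zero regions hitting a term -> binomial tail 1
  expect_equal(res[res$term == "none", "binom_p"], 1)
  # term annotating no domain gene is skipped with a warning
  expect_false("ghost" %in% res$term)
  expect_warning(region_term_enrichment(regions, toy_domains(),
                                        list(ghost = "gZ")), "ghost")
})

test_that("gene-list ORA matches the enumeration oracle and its edge cases", {
  universe <- sprintf("u%02d", 1:10)
  term <- list(t1 = universe[1:5])
  # universe 10, term 5, list 4, overlap 3 -> 55/210
  res <- gene_list_ora(universe[c(1, 2, 3, 6)], universe, term)
  expect_equal(res$p, 55 / 210, tolerance = 1e-12)
  expect_equal(res$gene_hits, 3)
  # list = universe: p = 1, fold = 1
  res <- gene_list_ora(universe, universe, term)
  expect_equal(res$p, 1)
  expect_equal(res$fold_enrich, 1)
  # disjoint list and term: p = 1
  res <- gene_list_ora(universe[6:9], universe, term)
  expect_equal(res$p, 1)
  # case-insensitive matching and dropped out-of-universe genes
  expect_message(res <- gene_list_ora(c("U01", "zz"), universe, term),
                 "dropped 1")
  expect_equal(res$gene_hits, 1)
})

test_that("term filters apply inclusive fold/FDR/gene-support cutoffs", {
  res <- data.frame(term = c("a", "b", "c", "d"),
                    gene_hits = c(6, 4, 10, 8),
                    fold_enrich = c(2.0, 5, 1.9, 3),
                    fdr = c(0.05, 0.001, 0.001, 0.2),
                    stringsAsFactors = FALSE)
  out <- apply_term_filters(res)
  # b has only 4 genes, c fails fold, d fails FDR; a passes exactly
  expect_equal(out$term, "a")
  expect_equal(nrow(apply_term_filters(res[0, ])), 0)
  expect_equal(nrow(apply_term_filters(res, top_n = 0)), 0)
})

test_that("target/DE overlap reproduces the enumeration oracle", {
  universe <- sprintf("u%02d", 1:10)
  res <- target_de_overlap(universe[1:4], universe[c(1:3, 7, 8)], universe)
  expect_equal(res$overlap, 3)
  expect_equal(res$hyper_p, 55 / 210, tolerance = 1e-12)
  res0 <- target_de_overlap(universe[9:10], universe[1:5], universe)
  expect_equal(res0$overlap, 0)
  expect_equal(res0$hyper_p, 1)
  expect_warning(res_e <- target_de_overlap(character(), universe[1:5],
                                            universe), "empty target")
  expect_equal(res_e$hyper_p, 1)
})

test_that("a planted enriched term ranks first by FDR in nearly all replicates", {
  withr::local_seed(55)
  universe <- sprintf("g%04d", 1:2000)
  top <- vapply(1:100, function(r) {
    gl <- sample(universe, 100)
    gs <- generate_gene_sets(universe, gl, seed = 9000 + r)
    res <- gene_list_ora(gl, universe, gs$sets)
    res$term[1] == gs$planted_term
  }, logical(1))
  expect_gte(mean(top), 0.95)
})
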