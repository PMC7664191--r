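# Format readers/writers: strict validation and round-trip stability.

test_that("read_bed parses, auto-names and validates intervals", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tE1", "chr2\t0\t50\tE2\t0\t-"), bed)
  iv <- read_bed(bed)
  expect_equal(iv$chrom, c("chr1", "chr2"))
  expect_equal(iv$start, c(100L, 0L))
  expect_equal(iv$end, c(200L, 50L))
  expect_equal(iv$name, c("E1", "E2"))
  expect_equal(iv$strand, c(".", "-"))

  writeLines(c("chr1\t10\t20", "chr1\t30\t40", "chr1\t50\t60"), bed)
  iv <- read_bed(bed)
  expect_equal(iv$name, c("region_1", "region_2", "region_3"))
  expect_equal(sum(iv$end - iv$start), 30)

  writeLines("chr1\t200\t100", bed)
  expect_error(read_bed(bed), "line 1.*end <= start")
  writeLines(c("chr1\t1\t2\tX", "chr1\t3\t4\tX"), bed)
  expect_error(read_bed(bed), "duplicate")
  writeLines("chr1\t100", bed)
  expect_error(read_bed(bed), "fewer than 3")
})

test_that("BED round-trip preserves coordinates and names", {
  bed <- withr::local_tempfile(fileext = ".bed")
  iv <- data.frame(chrom = "chrX", start = c(5L, 99L), end = c(25L, 200L),
                   name = c("a", "b"), strand = c("+", "."),
                   stringsAsFactors = FALSE)
  write_bed(iv, bed)
  expect_equal(read_bed(bed), iv)
})

test_that("JASPAR PFM counts become pseudocounted probabilities", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 TFX",
               "A [ 10  0 ]",
               "C [  0 10 ]",
               "G [  0  0 ]",
               "T [  0  0 ]"), f)
  lib <- read_motif_library(f, "jaspar-pfm")
  expect_length(lib, 1)
  p <- lib$M1
  expect_equal(p$altname, "TFX")
  # (count + 0.25) / (column total + 1)
  expect_equal(p$probs[, 1], c(A = 10.25, C = 0.25, G = 0.25, T = 0.25) / 11)
  expect_equal(colSums(p$probs), c(1, 1), tolerance = 1e-12)
  # IC uses the raw counts, i.e. deterministic columns: 2 bits each
  expect_equal(information_content(p), 4)

  writeLines(c(">M2", "A [ 0 ]", "C [ 0 ]", "G [ 0 ]", "T [ 0 ]"), f)
  expect_error(read_motif_library(f, "jaspar-pfm"), "zero-total")
  writeLines(c(">M3", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]"), f)
  expect_error(read_motif_library(f, "jaspar-pfm"), "4 matrix rows")
  writeLines(character(), f)
  expect_warning(lib <- read_motif_library(f, "jaspar-pfm"), "no motifs")
  expect_length(lib, 0)
})

test_that("MEME minimal motifs round-trip through write and read", {
  withr::local_seed(7)
  pwms <- list(random_pwm(6, "alpha"), random_pwm(9, "beta"))
  f <- withr::local_tempfile(fileext = ".meme")
  write_motif_meme(pwms, f)
  lib <- read_motif_library(f, "meme-minimal")
  expect_equal(names(lib), c("alpha", "beta"))
  for (i in 1:2) {
    expect_equal(unname(lib[[i]]$probs), unname(pwms[[i]]$probs),
                 tolerance = 1e-5)
  }
})

test_that("expression table parsing validates schema and recomputes fold", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tfpkm_a\tfpkm_b\tfold\tq_value",
               "Plagl1\t0.99\t45.26\t46.93\t0.001"), f)
  df <- read_expression_table(f)
  expect_equal(df$gene_id, "Plagl1")
  expect_equal(df$fold, 46.93)
  expect_equal(df$fpkm_b, 45.26)

  # fold recomputed when absent, with the 0-denominator convention
  writeLines(c("gene_id\tfpkm_a\tfpkm_b\tq_value",
               "g1\t2\t10\t0.01", "g2\t0\t5\t0.01", "g3\t0\t0\t0.5"), f)
  df <- read_expression_table(f)
  expect_equal(df$fold, c(5, Inf, NA))

  writeLines(c("gene_id\tfpkm_a\tfpkm_b\tfold\tq_value",
               "g1\t-1\t10\t2\t0.01"), f)
  expect_error(read_expression_table(f), "negative FPKM")
  writeLines(c("gene_id\tfpkm_a\tfpkm_b\tfold\tq_value",
               "g1\t1\t10\t10\t0.01", "g1\t1\t10\t10\t0.01"), f)
  expect_error(read_expression_table(f), "duplicate gene_id.*g1")
  writeLines(c("gene_id\tfpkm_b", "g1\t10"), f)
  expect_error(read_expression_table(f), "missing column.*found")
})

test_that("GMT parsing dedups genes and keeps terms independent", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tA\tB\ta", "T2\tdesc\tB\tC"), f)
  sets <- read_gmt(f)
  expect_equal(sets$T1, c("A", "B"))
  expect_equal(sets$T2, c("B", "C"))
  writeLines("T1\tdesc", f)
  expect_error(read_gmt(f), "fewer than 3")
  writeLines(character(), f)
  expect_length(read_gmt(f), 0)
})

test_that("FASTA round-trip uppercases and preserves sequences", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(s1 = "ACGTACGTNNACGT", s2 = strrep("ACGT", 40))
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)
})

test_that("result tables serialize deterministically without underflow", {
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  df <- data.frame(motif_id = c("m1", "m2"), fold = c(1 / 3, Inf),
                   p = c(1e-300, 0.05), stringsAsFactors = FALSE)
  write_results(df, f1)
  write_results(df, f2)
  expect_identical(readLines(f1), readLines(f2))
  txt <- readLines(f1)
  expect_match(txt[2], "1e-300")
  expect_match(txt[2], "0.333333")
  # empty result set -> header-only file
  write_results(df[0, ], f1)
  expect_equal(length(readLines(f1)), 1)
})

test_that("ortholog map reader enforces schema and uniqueness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("enhancer\tortholog", "e1\to1", "e2\to2"), f)
  m <- read_ortholog_map(f)
  expect_equal(m$ortholog, c("o1", "o2"))
  writeLines(c("enhancer\tortholog", "e1\to1", "e1\to2"), f)
  expect_error(read_ortholog_map(f), "duplicate enhancer")
  writeLines(c("a\tb", "e1\to1"), f)
  expect_error(read_ortholog_map(f), "missing column")
})
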