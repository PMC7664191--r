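# PWM information content, site scanning, exact score p-values and the
# ortholog conservation filter.

test_that("information content spans 0 (uniform) to 2 bits per column", {
  unif <- new_pwm("u", matrix(0.25, 4, 6))
  expect_equal(information_content(unif), 0)
  # deterministic columns via raw counts: 2 bits per column
  counts <- matrix(0, 4, 5)
  counts[1, ] <- 12
  det <- pwm_from_counts("d", counts)
  expect_equal(information_content(det), 10)
  half <- new_pwm("h", matrix(c(0.5, 0.5, 0, 0), 4, 1))
  expect_equal(information_content(half), 1)
})

test_that("scanning finds the consensus at maximal relative score on both strands", {
  p <- indicator_pwm("ACGTA")
  hits <- scan_sequence(p, paste0("TTTT", "ACGTA", "GGGG"),
                        match_min = 0.9, p_max = 1)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$offset, 4)
  expect_equal(plus$rel_score, 1)
  # reverse complement of the consensus is found on the minus strand with
  # the same relative score
  hits_rc <- scan_sequence(p, paste0("TTTT", revcomp("ACGTA"), "GGGG"),
                           match_min = 0.9, p_max = 1)
  minus <- hits_rc[hits_rc$strand == "-", ]
  expect_equal(minus$offset, 4)
  expect_equal(minus$rel_score, 1)
})

test_that("site sets of a sequence and its reverse complement mirror each other", {
  withr::local_seed(11)
  p <- random_pwm(6, "r")
  s <- random_dna_str(120)
  fwd <- scan_sequence(p, s, match_min = 0.6, p_max = 1)
  bwd <- scan_sequence(p, revcomp(s), match_min = 0.6, p_max = 1)
  # a site at offset o on strand st maps to offset n - L - o on the other
  # strand of the reverse complement
  key <- function(df, n, L) {
    refl <- data.frame(offset = n - L - df$offset,
                       strand = ifelse(df$strand == "+", "-", "+"),
                       score = round(df$score, 6))
    refl[order(refl$offset, refl$strand), ]
  }
  got <- bwd[order(bwd$offset, bwd$strand),
             c("offset", "strand", "score")]
  got$score <- round(got$score, 6)
  rownames(got) <- NULL
  want <- key(fwd, nchar(s), pwm_width(p))
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("windows containing N are skipped", {
  p <- indicator_pwm("ACGTA")
  expect_equal(nrow(scan_sequence(p, strrep("N", 50), match_min = 0.5,
                                  p_max = 1)), 0)
  # an N inside the only match window suppresses it
  hits <- scan_sequence(p, "TTACGNATT", match_min = 0.5, p_max = 1)
  expect_false(any(hits$offset == 2 & hits$strand == "+"))
})

test_that("site p-values match brute-force enumeration and are monotone", {
  withr::local_seed(3)
  for (L in c(3, 5, 7)) {
    p <- random_pwm(L)
    d <- score_distribution(p)
    expect_equal(d$survival[1], 1, tolerance = 1e-12)  # smin -> all words
    sc <- word_scores(p)
    qs <- sc[round(seq(1, length(sc), length.out = 25))]
    dp <- site_pvalue(p, qs, d)
    expect_true(all(diff(dp) <= 1e-12))  # monotone non-increasing
    expect_equal(dp, enum_pvalue(p, qs), tolerance = 1e-6)
  }
  # an indicator PWM at its maximum score: only the consensus word
  ind <- indicator_pwm("ACGTAC")
  d <- score_distribution(ind)
  expect_equal(site_pvalue(ind, d$smax, d), (1 / 4)^6, tolerance = 1e-12)
  expect_warning(site_pvalue(ind, d$smax + 1, d), "clamped")
})

test_that("relative score is invariant to shifting a column of log-odds", {
  withr::local_seed(5)
  p <- random_pwm(5)
  lo <- pwm_logodds(p)
  x <- enhancerMotifs:::encode_dna(random_dna_str(60))
  sw <- enhancerMotifs:::.score_windows
  rng <- enhancerMotifs:::.lo_range
  rel <- function(m) {
    r <- rng(m)
    (sw(m, x) - r["smin"]) / (r["smax"] - r["smin"])
  }
  lo2 <- lo
  lo2[, 3] <- lo2[, 3] + 1.7  # affine shift of one column
  expect_equal(rel(lo), rel(lo2), tolerance = 1e-9)
})

test_that("conservation requires a motif match in the mapped ortholog", {
  p <- indicator_pwm("ACGTACGT")
  seqs <- c(e1 = paste0("TT", "ACGTACGT", "TTTT"),
            e2 = paste0("GG", "ACGTACGT", "GGGG"),
            e3 = paste0("CC", "ACGTACGT", "CCCC"))
  sites <- scan_enhancers(p, seqs, match_min = 0.8, p_max = 1)
  omap <- data.frame(enhancer = c("e1", "e2"),
                     ortholog = c("o1", "o2"), stringsAsFactors = FALSE)
  oseqs <- c(o1 = paste0("AAAA", revcomp("ACGTACGT"), "AA"),  # minus-strand ok
             o2 = strrep("N", 20))
  out <- apply_conservation(sites, omap, oseqs, list(p))
  expect_true(all(out$conserved[out$enhancer_name == "e1"]))
  expect_false(any(out$conserved[out$enhancer_name == "e2"]))  # all-N ortholog
  expect_false(any(out$conserved[out$enhancer_name == "e3"]))  # unmapped
  expect_equal(attr(out, "no_ortholog"), 1L)
  # ortholog id missing from the FASTA is an error naming the id
  expect_error(apply_conservation(sites, omap, oseqs["o2"], list(p)), "o1")
})

test_that("planted consensus sites are fully recalled, all-N yields nothing", {
  withr::local_seed(21)
  p <- indicator_pwm("TGACGTCA", id = "planted")
  n <- 30
  seqs <- vapply(seq_len(n), function(i) {
    s <- random_dna_str(80)
    off <- sample(1:(80 - 8), 1)
    paste0(substr(s, 1, off - 1), "TGACGTCA", substr(s, off + 8, 80))
  }, character(1))
  names(seqs) <- sprintf("e%02d", seq_len(n))
  sites <- scan_enhancers(p, seqs, match_min = 0.8, p_max = 0.05)
  expect_equal(sort(unique(sites$enhancer_name)), sort(names(seqs)))
})
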