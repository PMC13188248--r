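# Genome scanning (seeding, strand handling, translated mode) and read
# rescue (clustering, consensus accuracy, coverage monotonicity).

test_that("a planted query is found with exact boundaries and identity 1", {
  set.seed(61)
  q <- random_dna_string(300L)
  contig <- paste0(random_dna_string(500L), q, random_dna_string(400L))
  hits <- scan_genome(c(q1 = q), c(c1 = contig))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$s_start, 500L)
  expect_equal(hits$s_end, 800L)
  expect_equal(hits$identity, 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$q_start, 0L)
  expect_equal(hits$q_end, 300L)
})

test_that("reverse-strand plantings score the same with strand minus", {
  set.seed(62)
  q <- random_dna_string(250L)
  fwd <- paste0(random_dna_string(300L), q, random_dna_string(300L))
  rev <- paste0(random_dna_string(300L), r2scout:::revcomp(q),
                random_dna_string(300L))
  h_f <- scan_genome(c(q = q), c(c = fwd))
  h_r <- scan_genome(c(q = q), c(c = rev))
  expect_equal(h_r$strand, "-")
  expect_equal(h_f$score, h_r$score)
  expect_equal(h_r$s_end - h_r$s_start, 250L)
  expect_equal(h_r$s_start, 300L)
})

test_that("translated mode finds protein queries in any frame", {
  el <- make_element(element_spec("D", orf_len_aa = 950L), seed = 63)
  prot_q <- substr(el$protein, 101L, 400L)
  contig <- paste0(strrep("AC", 100L), el$element_nt, strrep("GT", 100L))
  hits <- scan_genome(c(p1 = prot_q), c(c1 = contig), mode = "translated")
  expect_gte(nrow(hits), 1L)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$strand, "+")
  # the nucleotide interval covers the query's position in the element
  orf_start <- 200L + el$spec$utr5_len
  expect_lte(abs(best$s_start - (orf_start + 100L * 3L)), 3L)
})

test_that("scan preconditions are enforced", {
  expect_error(scan_genome(character(0), c(c = "ACGT")), "named character")
  expect_error(scan_genome(c(q = "ACGTACGT"), c(c = "ACGTACGT"), k = 3L),
               "k must be >= 4")
})

test_that("error-free tiling reads collapse to the exact element", {
  set.seed(64)
  el <- random_dna_string(1500L)
  src <- c(s = paste0(random_dna_string(200L), el, random_dna_string(200L)))
  reads <- simulate_reads(src, n = 20L, mean_len = 600L, seed = 65)
  cand <- rescue_from_reads(substr(el, 400L, 900L), reads,
                            polish_rounds = 1L)
  expect_equal(length(cand), 1L)
  al <- local_align(el, cand[[1]]$seq)
  expect_equal(al$identity, 1)
  expect_equal(al$q_end - al$q_start, 1500L)
})

test_that("reads covering disjoint halves yield two partial candidates", {
  set.seed(66)
  el <- random_dna_string(2000L)
  reads <- data.frame(id = c("r1", "r2"),
                      seq = c(substr(el, 1L, 800L),
                              substr(el, 1201L, 2000L)),
                      qual = strrep("I", 800L), stringsAsFactors = FALSE)
  cand <- rescue_from_reads(el, reads)
  expect_equal(length(cand), 2L)
  for (cc in cand) expect_lt(nchar(cc$seq), 1000L)
})

test_that("no read hitting the query yields an empty list", {
  set.seed(67)
  reads <- data.frame(id = "r1", seq = random_dna_string(500L),
                      qual = strrep("I", 500L), stringsAsFactors = FALSE)
  cand <- rescue_from_reads(random_dna_string(800L), reads)
  expect_equal(length(cand), 0L)
  expect_error(rescue_from_reads("ACGT", data.frame(id = character(),
                                                    seq = character())),
               "at least one")
})

test_that("consensus accuracy does not degrade with deeper coverage", {
  el <- make_element(element_spec("D", orf_len_aa = 950L), seed = 68)
  src <- c(s = paste0(r2scout:::with_seed(1, r2scout:::random_dna(300L)),
                      el$element_nt,
                      r2scout:::with_seed(2, r2scout:::random_dna(300L))))
  query <- substr(el$element_nt, 1L, 1000L)
  depth_n <- c(5L, 15L, 30L)
  ident <- vapply(depth_n, function(n) {
    reads <- simulate_reads(src, n = n, mean_len = 1800L, sub_rate = 0.04,
                            indel_rate = 0.04, seed = 69L)
    cand <- rescue_from_reads(query, reads, polish_rounds = 2L)
    if (!length(cand)) return(0)
    max(vapply(cand, function(cc)
      local_align(el$element_nt, cc$seq)$identity, 0))
  }, 0)
  expect_true(all(diff(ident) >= -0.002))
  expect_gt(ident[3], 0.99)
})
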