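# The synthetic-data generator: determinism, parameter validation, ground
# truth bookkeeping, read simulation error rates, and the tree evolver's
# closed-form behaviour.

test_that("rDNA reference generation is deterministic and validated", {
  r1 <- make_reference_rdna(seed = 1)
  r2 <- make_reference_rdna(seed = 1)
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$unit_seq, r2$unit_seq)

  r3 <- make_reference_rdna(seed = 2)
  expect_gt(sum(strsplit(r1$seq, "")[[1]] != strsplit(r3$seq, "")[[1]]), 0)

  layout <- c("18S-like" = 100L, "28S-like" = 2000L)
  expect_error(make_reference_rdna(1, layout, nick_pos = 2010L),
               "nick_pos")
  expect_error(make_reference_rdna(1, c("18S-like" = 100L), 50L), "28S")
  expect_error(make_reference_rdna(1, c("28S-like" = 0L), 50L), "> 0")
})

test_that("generated elements satisfy their own domain annotators", {
  el <- make_element(element_spec("D", orf_len_aa = 1000L), seed = 5)
  expect_equal(nchar(el$protein), 1000L)
  ar <- annotate_protein(el$protein)
  expect_equal(nrow(ar$znfs), 1L)
  expect_equal(nrow(ar$mybs), 1L)

  no_myb <- make_element(element_spec("no-Myb"), seed = 5)
  expect_equal(nrow(annotate_protein(no_myb$protein)$mybs), 0L)

  dup <- make_element(element_spec("D+Myb2"), seed = 5)
  mybs <- annotate_protein(dup$protein)$mybs
  expect_equal(nrow(mybs), 2L)
  expect_true(mybs$start[2] >= mybs$end[1])

  expect_error(make_element(element_spec("D", orf_len_aa = 100L), seed = 1),
               "smaller than the sum")
})

test_that("element ORFs avoid stops and need no initiator methionine", {
  el <- make_element(element_spec("A"), seed = 8)
  orfs <- extract_orfs(el$element_nt)
  expect_equal(nrow(orfs$full), 1L)
  expect_equal(orfs$full$aa_seq[1], el$protein)
  expect_false(startsWith(el$protein, "M"))
})

test_that("genome truth table records coordinates, strand and truncation", {
  g <- small_genome()
  tr <- g$truth
  expect_equal(sum(tr$class == "R2-site-specific"), 4L)
  expect_true(all(tr$strand == "+"))
  expect_equal(anyDuplicated(tr$element_id), 0L)

  # round trip: the recorded interval reproduces the planted sequence
  for (i in seq_len(nrow(tr))) {
    ext <- substr(g$contigs[[tr$contig_id[i]]], tr$start[i] + 1L, tr$end[i])
    expect_identical(ext, unname(g$elements[[tr$element_id[i]]]))
  }

  # truncation shortens the recorded interval by exactly truncate5_nt
  t4 <- tr[tr$element_id == "elem_04", ]
  full_len <- nchar(make_element(element_spec("D+Myb2", truncate5_nt = 500L),
                                 seed = r2scout:::derive_seed(3, 4))$element_nt)
  expect_equal(t4$end - t4$start, full_len - 500L)

  # the -11 insertion sits 11 nt upstream of the canonical nick in its unit
  t2 <- tr[tr$element_id == "elem_02", ]
  rd <- g$rdna
  up <- substr(g$contigs[[t2$contig_id]], t2$start - 40L + 1L, t2$start)
  want <- substr(rd$seq, rd$nick_pos - 11L - 40L + 1L, rd$nick_pos - 11L)
  expect_identical(up, want)
})

test_that("insertions leave the rDNA flanks untouched", {
  g <- small_genome()
  rd <- g$rdna
  tr <- g$truth[g$truth$class == "R2-site-specific" &
                  g$truth$truncate5_nt == 0L, ]
  for (i in seq_len(nrow(tr))) {
    contig <- g$contigs[[tr$contig_id[i]]]
    off <- tr$insertion_offset[i]
    p <- rd$nick_pos + off
    up <- substr(contig, tr$start[i] - 60L + 1L, tr$start[i])
    down <- substr(contig, tr$end[i] + 1L, tr$end[i] + 60L)
    expect_identical(up, substr(rd$seq, p - 60L + 1L, p))
    expect_identical(down, substr(rd$seq, p + 1L, p + 60L))
  }
})

test_that("more site-specific elements than units is an error", {
  specs <- list(element_spec("D"), element_spec("D"))
  expect_error(build_genome_and_truth(specs, n_rdna_units = 1, seed = 1),
               "more site-specific")
})

test_that("misassembly mode splits one element across two contigs", {
  specs <- list(element_spec("D"), element_spec("A"))
  g <- build_genome_and_truth(specs, n_rdna_units = 3, seed = 6,
                              misassemble = TRUE)
  expect_length(g$contigs, 2L)
  split_rows <- g$truth[g$truth$split, ]
  expect_equal(nrow(split_rows), 2L)
  expect_setequal(split_rows$contig_id, c("contig_1", "contig_2"))
  # the two halves concatenate to the planted element
  h1 <- split_rows[split_rows$contig_id == "contig_1", ]
  h2 <- split_rows[split_rows$contig_id == "contig_2", ]
  joined <- paste0(substr(g$contigs[["contig_1"]], h1$start + 1L, h1$end),
                   substr(g$contigs[["contig_2"]], h2$start + 1L, h2$end))
  expect_identical(joined, unname(g$elements[[h1$element_id]]))
})

test_that("simulated reads honour counts, error-free mode and rates", {
  g <- small_genome()
  reads <- simulate_reads(g$contigs, n = 100L, mean_len = 400L,
                          seed = 4)
  expect_equal(nrow(reads), 100L)
  # error-free reads are exact substrings of a contig or its complement
  for (i in sample.int(100L, 20L)) {
    r <- reads[i, ]
    frag <- substr(g$contigs[[r$contig]], r$start + 1L, r$end)
    if (r$strand == "-") frag <- r2scout:::revcomp(frag)
    expect_identical(r$seq, frag)
  }

  # FASTQ round trip
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(nrow(back), 100L)
  expect_identical(back$seq, reads$seq)

  # substitution rate recovered within a conservative binomial window
  noisy <- simulate_reads(g$contigs, n = 25L, mean_len = 400L,
                          sub_rate = 0.05, seed = 9)
  mism <- 0L; tot <- 0L
  for (i in seq_len(nrow(noisy))) {
    r <- noisy[i, ]
    frag <- substr(g$contigs[[r$contig]], r$start + 1L, r$end)
    if (r$strand == "-") frag <- r2scout:::revcomp(frag)
    a <- strsplit(r$seq, "")[[1]]; b <- strsplit(frag, "")[[1]]
    mism <- mism + sum(a != b); tot <- tot + length(a)
  }
  expect_gt(tot, 9000L)
  expect_lt(abs(mism / tot - 0.05), 0.01)

  expect_error(simulate_reads(character(0), n = 1), "empty contigs")
  expect_error(simulate_reads(g$contigs, sub_rate = 0.5), "rates")
})

test_that("tree evolution follows the equal-rates closed form", {
  root <- strrep("ACDEFGHIKLMNPQRSTVWY", 500L)  # 10,000 sites
  lv <- evolve_on_tree(root, "(a:0.25,b:0.25);", seed = 5)
  pd <- mean(strsplit(lv[["a"]], "")[[1]] != strsplit(lv[["b"]], "")[[1]])
  t_tot <- 0.5
  expected <- (19 / 20) * (1 - exp(-(20 / 19) * t_tot))
  se <- sqrt(expected * (1 - expected) / nchar(root))
  expect_lt(abs(pd - expected), 3 * se)

  # zero branch lengths copy the root everywhere
  lv0 <- evolve_on_tree("ACDEFGHIKL", "((a:0,b:0):0,c:0);", seed = 1)
  expect_true(all(lv0 == "ACDEFGHIKL"))

  # rate-zero sites never change
  rates <- rep(c(0, 2), each = 50L)
  lv2 <- evolve_on_tree(strrep("AR", 50L), "(a:1,b:1);",
                        site_rates = rates, seed = 2)
  a <- strsplit(lv2[["a"]], "")[[1]]; b <- strsplit(lv2[["b"]], "")[[1]]
  r0 <- strsplit(strrep("AR", 50L), "")[[1]]
  expect_true(all(a[rates == 0] == r0[rates == 0]))
  expect_true(all(b[rates == 0] == r0[rates == 0]))

  expect_error(evolve_on_tree("ACD", "((a:1,b:1;"), "malformed")
})

test_that("generator operations are bit-reproducible for a fixed seed", {
  e1 <- make_element(element_spec("A"), seed = 33)
  e2 <- make_element(element_spec("A"), seed = 33)
  expect_identical(e1$element_nt, e2$element_nt)
  r1 <- simulate_reads(c(c1 = strrep("ACGT", 500L)), n = 10L,
                       mean_len = 200L, sub_rate = 0.1, indel_rate = 0.05,
                       seed = 7)
  r2 <- simulate_reads(c(c1 = strrep("ACGT", 500L)), n = 10L,
                       mean_len = 200L, sub_rate = 0.1, indel_rate = 0.05,
                       seed = 7)
  expect_identical(r1$seq, r2$seq)
  g1 <- build_genome_and_truth(list(element_spec("D")), 2, seed = 12)
  g2 <- build_genome_and_truth(list(element_spec("D")), 2, seed = 12)
  expect_identical(g1$contigs, g2$contigs)
})
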