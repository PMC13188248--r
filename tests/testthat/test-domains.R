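# ORF extraction, the zinc-finger grammar against its enumeration oracle,
# profile detectors with a permutation null, architecture classification on
# the full synthetic panel, and the N-terminal trim.

test_that("ORF length gate keeps 900 and drops 899", {
  # random residues: their codons carry stops into the shifted frames, so
  # the planted frame-0 stretch is the only long ORF
  mk <- function(n_aa) {
    nt <- r2scout:::with_seed(1, {
      aa <- random_aa_string(n_aa)
      r2scout:::reverse_translate(aa)
    })
    paste0("TAA", nt, "TAA")
  }
  o899 <- extract_orfs(mk(899L))
  expect_equal(nrow(o899$full), 0L)
  expect_true(899L %in% o899$partial$length_aa)
  o900 <- extract_orfs(mk(900L))
  expect_true(900L %in% o900$full$length_aa)

  # a lone stop codon yields nothing in any frame
  o <- extract_orfs("TAA")
  expect_equal(nrow(o$full), 0L)
  expect_equal(nrow(o$partial), 0L)
  expect_error(extract_orfs("AC"), "codon")
  expect_error(extract_orfs("ACGU"), "invalid nucleotide")
})

test_that("ORF coordinates map back to the element nucleotides", {
  el <- make_element(element_spec("D", orf_len_aa = 950L), seed = 3)
  o <- extract_orfs(el$element_nt)
  rec <- o$full[1L, ]
  nt <- substr(el$element_nt, rec$nt_start + 1L, rec$nt_end)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  expect_identical(aa, rec$aa_seq)
})

test_that("zinc-finger grammar matches planted motifs", {
  pad <- strrep("A", 10L)
  hit <- annotate_znf(paste0(pad, "CAAC", strrep("K", 12L), "H",
                             strrep("K", 4L), "H", pad))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$pair_type, "CCHH")
  expect_equal(hit$first_pair_variant, "CxxC")
  expect_equal(hit$start, 10L)

  chc <- annotate_znf(paste0(pad, "CAAC", strrep("K", 12L), "H",
                             strrep("K", 4L), "C", pad))
  expect_equal(chc$pair_type, "CCHC")

  none <- annotate_znf(strrep("KARNDE", 40L))
  expect_equal(nrow(none), 0L)
})

test_that("zinc-finger annotation agrees with the enumeration oracle", {
  set.seed(21)
  for (rep in 1:300) {
    s <- paste(sample(c("C", "H", "P", "A"), sample(16:30, 1L),
                      replace = TRUE), collapse = "")
    got <- annotate_znf(s)
    want <- oracle_znf(s)
    expect_equal(nrow(got), nrow(want), info = s)
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = s)
      expect_equal(got$end, want$end, info = s)
    }
  }
})

test_that("profile detectors find their templates and reject shuffles", {
  tpl <- r2scout:::motif_templates()
  aa <- make_element(element_spec("D"), seed = 14)$protein
  aux <- annotate_myb_and_aux(aa)
  expect_equal(nrow(aux$mybs), 1L)
  expect_false(is.null(aux$rle))
  expect_false(is.null(aux$knuckle))

  # permutation null: shuffling the protein kills the hits
  set.seed(22)
  clean <- 0L
  for (i in 1:100) {
    shuf <- paste(sample(strsplit(aa, "")[[1L]]), collapse = "")
    h <- annotate_myb_and_aux(shuf)
    if (nrow(h$mybs) == 0L && is.null(h$rle) && is.null(h$knuckle))
      clean <- clean + 1L
  }
  expect_gte(clean, 95L)
})

test_that("RT motifs are checked for presence and order", {
  aa <- make_element(element_spec("D"), seed = 15)$protein
  rt <- annotate_rt_motifs(aa)
  expect_true(rt$intact)
  expect_equal(rt$motifs$motif, 0:7)

  tpl <- r2scout:::motif_templates()
  # delete motif 5's template from the protein
  no5 <- sub(tpl[["RT5"]], "", aa, fixed = TRUE)
  rt5 <- annotate_rt_motifs(no5)
  expect_false(rt5$intact)
  expect_false(5L %in% rt5$motifs$motif)

  # swap motifs 3 and 4 in sequence: order violated
  swapped <- sub(tpl[["RT3"]], "@@@", aa, fixed = TRUE)
  swapped <- sub(tpl[["RT4"]], tpl[["RT3"]], swapped, fixed = TRUE)
  swapped <- sub("@@@", tpl[["RT4"]], swapped, fixed = TRUE)
  rts <- annotate_rt_motifs(swapped)
  expect_false(rts$intact)
})

test_that("the architecture panel is classified without error", {
  panel <- arch_panel_specs()
  expect_length(panel, 50L)
  mistakes <- 0L
  for (i in seq_along(panel)) {
    p <- panel[[i]]
    el <- make_element(p$spec, seed = 100L + i)
    ar <- annotate_protein(el$protein)
    ok <- ar$label == p$label
    if (ok && !is.na(p$check_number) && p$label != "no-Myb") {
      zn <- ar$znfs[!is.na(ar$znfs$assigned_number) &
                      ar$znfs$assigned_number == p$check_number, ]
      ok <- nrow(zn) == 1L &&
        if (p$variant == "CPCC") zn$cpcc_flag else
          (zn$first_pair_variant == p$variant && !zn$cpcc_flag)
    }
    if (!ok) mistakes <- mistakes + 1L
  }
  expect_equal(mistakes, 0L)
})

test_that("two-finger architectures split into B and C by pair type", {
  b <- annotate_protein(make_element(element_spec("B"), seed = 31)$protein)
  expect_equal(b$label, "B")
  nt_b <- b$znfs[which.min(b$znfs$start), ]
  expect_equal(nt_b$pair_type, "CCHC")

  c_ <- annotate_protein(make_element(element_spec("C"), seed = 31)$protein)
  expect_equal(c_$label, "C")
  nt_c <- c_$znfs[which.min(c_$znfs$start), ]
  expect_equal(nt_c$pair_type, "CCHH")
})

test_that("the co-fold heuristic tracks the ZnF3-ZnF2 linker length", {
  tight <- annotate_protein(make_element(element_spec("A"), seed = 41,
                                         cofold_linker_aa = 6L)$protein)
  expect_true(tight$cofold_znf32_plausible)
  loose <- annotate_protein(make_element(element_spec("A"), seed = 41,
                                         cofold_linker_aa = 18L)$protein)
  expect_false(loose$cofold_znf32_plausible)
  d <- annotate_protein(make_element(element_spec("D"), seed = 41)$protein)
  expect_true(is.na(d$cofold_znf32_plausible))
})

test_that("N-terminal trim starts 10 residues before the first finger", {
  aa <- paste0(strrep("K", 50L), "CAAC", strrep("K", 12L), "H",
               strrep("K", 4L), "H", strrep("K", 30L))
  znfs <- annotate_znf(aa)
  expect_equal(znfs$start, 50L)
  tr <- trim_n_terminus(aa, znfs)
  expect_equal(tr$offset, 40L)
  expect_identical(tr$aa, substring(aa, 41L))

  near <- paste0(strrep("K", 4L), "CAAC", strrep("K", 12L), "H",
                 strrep("K", 4L), "H")
  tr2 <- trim_n_terminus(near, annotate_znf(near))
  expect_equal(tr2$offset, 0L)
  expect_identical(tr2$aa, near)

  tr3 <- trim_n_terminus("KKKK", annotate_znf("KKKK"))
  expect_false(tr3$trimmed)
  expect_identical(tr3$aa, "KKKK")

  # property: the trim is always a suffix no longer than the input
  set.seed(23)
  for (i in 1:20) {
    s <- random_aa_string(200L)
    t <- trim_n_terminus(s, annotate_znf(s))
    expect_true(endsWith(s, t$aa))
  }
})
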