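# Progressive alignment, trimming, distance corrections, neighbor joining
# (with the additive-matrix consistency oracle and an independent NJ
# cross-check), bootstrap reproducibility, and Robinson-Foulds distances.

tree_distance_matrix <- function(phy) {
  D <- ape::cophenetic.phylo(phy)
  D[phy$tip.label, phy$tip.label]
}

test_that("progressive alignment preserves residues and pairwise optima", {
  two <- align_progressive(c(x = "MKVLIT", y = "MKVLIT"))
  expect_identical(unname(two), c("MKVLIT", "MKVLIT"))

  set.seed(51)
  seqs <- setNames(vapply(1:5, function(i) random_aa_string(60L), ""),
                   paste0("s", 1:5))
  msa <- align_progressive(seqs)
  expect_equal(length(unique(nchar(msa))), 1L)
  for (nm in names(seqs))
    expect_identical(gsub("-", "", msa[[nm]]), seqs[[nm]])

  # two sequences: the merge score equals the pairwise global optimum
  sc <- scoring_scheme("protein", gap_open = 11, gap_extend = 1)
  a <- random_aa_string(40L); b <- random_aa_string(45L)
  pair <- align_progressive(c(p = a, q = b), scoring = sc)
  ref <- local_align(a, b, sc, type = "global")
  expect_identical(unname(pair[["p"]]), ref$q_aln)
  expect_identical(unname(pair[["q"]]), ref$s_aln)

  expect_error(align_progressive(c(a = "MK", a = "MK")), "duplicate")
})

test_that("gap-fraction trimming drops exactly the over-gapped columns", {
  # an all-gap column is dropped at any threshold below 1
  allgap <- c(a = "MKV-", b = "MKV-", c = "M-V-", d = "M-V-")
  expect_equal(as.character(trim_alignment(allgap, 0.9)),
               c("MKV", "MKV", "M-V", "M-V"), ignore_attr = TRUE)
  msa <- c(a = "MKV-", b = "MKV-", c = "M-VD", d = "M-VD")
  # half-gapped columns survive a 0.9 threshold
  expect_equal(as.character(trim_alignment(msa, 0.9)), unname(msa),
               ignore_attr = TRUE)
  tr <- trim_alignment(msa, 0.4)
  expect_equal(as.character(tr), c("MV", "MV", "MV", "MV"),
               ignore_attr = TRUE)
  expect_equal(attr(tr, "dropped_cols"), c(1L, 3L))
  gapfree <- c(a = "MKVD", b = "MKVD")
  expect_equal(as.character(trim_alignment(gapfree)), unname(gapfree),
               ignore_attr = TRUE)
  expect_error(trim_alignment(c(a = "--", b = "--"), 0.4), "all columns")
})

test_that("distance corrections match their closed forms", {
  # two 10-residue rows differing at exactly one position: p = 0.1
  msa <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAR")
  expect_equal(distance_matrix(msa, "p")["a", "b"], 0.1)
  expect_equal(distance_matrix(msa, "poisson")["a", "b"], -log(0.9),
               tolerance = 1e-9)
  expect_equal(distance_matrix(msa, "kimura-protein")["a", "b"],
               -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-9)
  same <- c(a = "MKVD", b = "MKVD")
  for (corr in c("p", "poisson", "kimura-protein"))
    expect_equal(distance_matrix(same, corr)["a", "b"], 0)
  expect_error(distance_matrix(c(a = "A---", b = "-RRR")), "comparable")
})

test_that("identity matrix counts pairwise matches over occupied columns", {
  msa <- c(a = "ACGT", b = "ACGA")
  im <- identity_matrix(msa)
  expect_equal(im["a", "b"], 75)
  expect_equal(diag(im), c(a = 100, b = 100))
  set.seed(52)
  seqs <- setNames(vapply(1:4, function(i) random_aa_string(30L), ""),
                   paste0("t", 1:4))
  im2 <- identity_matrix(seqs)
  expect_equal(im2, t(im2))
})

test_that("NJ recovers additive four- and five-taxon trees exactly", {
  phy <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  D <- tree_distance_matrix(phy)
  est <- nj_tree(D)
  expect_equal(rf_distance(est, phy), 0L)
  # branch lengths recovered: compare patristic distances
  expect_equal(tree_distance_matrix(est)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  # a 12-topology sample of labelled 5-taxon trees (the acceptance suite
  # enumerates the full set)
  tips <- c("a", "b", "c", "d", "e")
  count <- 0L
  for (rest in list(c("b","c"), c("b","d"), c("b","e"), c("c","d"),
                    c("c","e"), c("d","e"))) {
    others <- setdiff(tips[-1], rest)
    for (swap in 0:1) {
      pair2 <- if (swap) rev(others) else others
      nw <- sprintf("((a:1,%s:2):1,((%s:1,%s:3):1,%s:2):1);",
                    rest[1], rest[2], pair2[1], pair2[2])
      phy5 <- ape::read.tree(text = nw)
      D5 <- tree_distance_matrix(phy5)
      expect_equal(rf_distance(nj_tree(D5), phy5), 0L, info = nw)
      count <- count + 1L
    }
  }
  expect_equal(count, 12L)
})

test_that("NJ agrees topologically with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(53)
  for (rep in 1:5) {
    phy <- ape::rtree(8L)
    phy$edge.length <- pmax(phy$edge.length, 0.05)
    D <- tree_distance_matrix(phy)
    mine <- nj_tree(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
    # and the package's own RF agrees with phangorn's
    expect_equal(rf_distance(mine, phy),
                 phangorn::RF.dist(ape::unroot(mine), ape::unroot(phy)))
  }
})

test_that("three-taxon NJ uses the three-point formulas", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3L, 3L,
              dimnames = list(c("a","b","c"), c("a","b","c")))
  phy <- nj_tree(D)
  expect_equal(sort(phy$tip.label), c("a", "b", "c"))
  pd <- tree_distance_matrix(phy)
  expect_equal(pd[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("bootstrap supports are high on clean signal and reproducible", {
  set.seed(54)
  phy <- ape::rtree(8L)
  phy$edge.length <- pmin(pmax(phy$edge.length, 0.15), 0.5)
  msa <- evolve_on_tree(strrep("ACDEFGHIKLMNPQRSTWYV", 50L), phy, seed = 6)
  D <- distance_matrix(msa, "poisson")
  t1 <- neighbor_joining(D, bootstrap = list(msa = msa, B = 200L, seed = 9L))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 95))

  t2 <- neighbor_joining(D, bootstrap = list(msa = msa, B = 200L, seed = 9L))
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(t1$node.label, t2$node.label)
})

test_that("outgroup rooting places the root on the outgroup edge", {
  phy <- ape::read.tree(text = "((a:1,b:1):1,(c:1,og:1):1);")
  D <- tree_distance_matrix(phy)
  rooted <- neighbor_joining(D, outgroup = "og")
  expect_true(ape::is.rooted(rooted))
  first_split <- ape::extract.clade(rooted,
                                    length(rooted$tip.label) + 1L)
  expect_true("og" %in% rooted$tip.label)
  expect_error(neighbor_joining(D, outgroup = "zz"), "outgroup")
})

test_that("RF distance counts bipartition differences", {
  t1 <- "((a:1,b:1):1,(c:1,d:1):1);"
  expect_equal(rf_distance(t1, t1), 0L)
  t2 <- "((a:1,c:1):1,(b:1,d:1):1);"
  expect_equal(rf_distance(t1, t2), 2L)

  cat6 <- "(((((a:1,b:1):1,c:1):1,d:1):1,e:1):1,f:1);"
  bal6 <- "(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):1);"
  # brute-force bipartition enumeration oracle
  bips <- function(nw) {
    phy <- ape::read.tree(text = nw)
    pp <- ape::prop.part(phy)
    tips <- sort(phy$tip.label)
    keys <- vapply(pp, function(idx) {
      side <- sort(phy$tip.label[idx])
      if (tips[1] %in% side) side <- setdiff(tips, side)
      if (length(side) < 2L || length(side) > length(tips) - 2L)
        return(NA_character_)
      paste(side, collapse = "|")
    }, "")
    unique(keys[!is.na(keys)])
  }
  want <- length(setdiff(bips(cat6), bips(bal6))) +
    length(setdiff(bips(bal6), bips(cat6)))
  expect_equal(rf_distance(cat6, bal6), want)
  expect_error(rf_distance(t1, "(a:1,(b:1,x:1):1);"), "fewer than four")
})

test_that("NJ recovers simulated topologies from finite alignments", {
  set.seed(55)
  hits <- 0L
  for (rep in 1:10) {
    phy <- ape::rtree(8L)
    phy$edge.length <- pmin(pmax(phy$edge.length, 0.05), 0.3)
    msa <- evolve_on_tree(strrep("ACDEFGHIKLMNPQRSTWYV", 25L), phy,
                          seed = 60L + rep)
    est <- nj_tree(distance_matrix(msa, "poisson"))
    if (rf_distance(est, phy) == 0L) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
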