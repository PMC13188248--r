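# Likelihood machinery: discrete-gamma categories against an independent
# implementation, pruning against brute-force state enumeration, the
# two-leaf closed form, and posterior-mean rate behaviour.

test_that("discrete-gamma category rates match phangorn and average one", {
  skip_if_not_installed("phangorn")
  for (alpha in c(0.3, 0.5, 1, 3)) {
    mine <- discrete_gamma(alpha, 4L)
    ref <- phangorn::discrete.gamma(alpha, 4L)
    expect_equal(mine, ref, tolerance = 1e-8)
    expect_equal(mean(mine), 1, tolerance = 1e-9)
  }
  expect_error(discrete_gamma(0), "positive")
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(41)
  trees <- c("((a:0.3,b:0.1):0.2,c:0.4);",
             "((a:0.2,b:0.2):0.1,(c:0.3,d:0.1):0.2);",
             "(((a:0.1,b:0.2):0.1,c:0.3):0.2,(d:0.2,e:0.4):0.1);")
  for (nw in trees) {
    phy <- ape::read.tree(text = nw)
    ntip <- length(phy$tip.label)
    aln <- matrix(sample.int(20L, ntip * 6L, replace = TRUE), nrow = ntip,
                  dimnames = list(phy$tip.label, NULL))
    for (rate in c(0.5, 1, 2)) {
      mine <- r2scout:::lik_sites(phy, aln, rate)
      want <- oracle_tree_lik(phy, aln, rate)
      expect_equal(log(mine), log(want), tolerance = 1e-10)
    }
  }
})

test_that("two-leaf site likelihoods equal the closed form", {
  phy <- ape::read.tree(text = "(a:0.3,b:0.2);")
  aln <- matrix(c(1L, 1L, 1L, 5L), nrow = 2L,
                dimnames = list(c("a", "b"), NULL))
  lik <- r2scout:::lik_sites(phy, aln, 1)
  t_tot <- 0.5
  p_same <- 1 / 20 + (19 / 20) * exp(-20 * t_tot / 19)
  p_diff <- (1 - p_same) / 19
  expect_equal(lik[1], p_same / 20, tolerance = 1e-12)
  expect_equal(lik[2], p_diff / 20, tolerance = 1e-12)
})

test_that("invariant sites land in the most conserved bin", {
  set.seed(42)
  phy <- ape::rtree(8L)
  phy$edge.length <- pmax(phy$edge.length, 0.2)
  root <- strrep("AR", 100L)
  msa <- evolve_on_tree(root, phy, alpha = 0.5, seed = 3)
  # force the first 10 sites invariant across all leaves
  msa[] <- vapply(msa, function(s) {
    substr(s, 1L, 10L) <- strrep("W", 10L); s
  }, "")
  sr <- site_rates(msa, phy)
  expect_true(all(sr$bins[1:10] == 1L))
  expect_true(all(sr$posterior_mean[1:10] <
                    quantile(sr$posterior_mean, 0.2, na.rm = TRUE)))
})

test_that("posterior-mean rates average close to the prior mean", {
  set.seed(43)
  phy <- ape::rtree(12L)
  phy$edge.length <- pmin(pmax(phy$edge.length, 0.05), 0.5)
  msa <- evolve_on_tree(strrep("ACDEFGHIKLMNPQRSTVWY", 25L), phy,
                        alpha = 1, seed = 4)
  sr <- site_rates(msa, phy)
  expect_lt(abs(mean(sr$posterior_mean) - 1), 0.05)
})

test_that("all-gap columns are excluded and reported missing", {
  phy <- ape::read.tree(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);")
  msa <- c(a = "AR-D", b = "AR-D", c = "AK-D", d = "AK-D")
  sr <- site_rates(msa, phy)
  expect_true(is.na(sr$posterior_mean[3]))
  expect_true(is.na(sr$bins[3]))
  expect_false(anyNA(sr$posterior_mean[-3]))
})

test_that("deeper alignments concentrate the posterior-mean rates", {
  set.seed(44)
  root <- strrep("ACDEFGHIKLMNPQRSTVWY", 20L)
  # all sites truly evolve at rate 1; under a fixed prior shape the spread
  # of the per-site posterior means is estimation noise, which must shrink
  # as taxa are added
  vars <- vapply(c(4L, 16L), function(ntaxa) {
    phy <- ape::rtree(ntaxa)
    phy$edge.length <- pmin(pmax(phy$edge.length, 0.1), 0.4)
    msa <- evolve_on_tree(root, phy, seed = ntaxa)
    sr <- site_rates(msa, phy, alpha = 1)
    var(sr$posterior_mean)
  }, 0)
  expect_lt(vars[2], vars[1])
})
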