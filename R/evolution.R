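# Likelihood machinery under the 20-state equal-rates amino-acid model and
# discrete-gamma per-site evolutionary rates.  The equal-rates model has a
# closed-form transition probability,
#   P(same)(t)  = 1/20 + (19/20) exp(-20 t / 19),
#   P(other)(t) = 1/20 - (1/20) exp(-20 t / 19)   (for each of 19 states),
# with branch lengths in expected substitutions per site, which gives the
# test suite exact oracles.

# 20x20 transition probability matrix at distance t (t = bl * rate)
pmat_poisson <- function(t) {
  e <- exp(-20 * t / 19)
  off <- (1 - e) / 20
  m <- matrix(off, 20L, 20L)
  diag(m) <- 1 / 20 + 19 * e / 20
  m
}

#' Discrete-gamma category rates
#'
#' Mean rate of each of `K` equal-probability categories of a gamma(alpha,
#' alpha) distribution (mean 1), computed from the incomplete-gamma identity
#' for the mean within quantile bins.
#'
#' @param alpha gamma shape (> 0).
#' @param K number of categories.
#' @return numeric vector of K category rates with mean 1.
#' @export
discrete_gamma <- function(alpha, K = 4L) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  b <- stats::qgamma(seq(0, 1, length.out = K + 1L), shape = alpha,
                     rate = alpha)
  K * (pgamma(b[-1L], shape = alpha + 1, rate = alpha) -
         pgamma(b[-(K + 1L)], shape = alpha + 1, rate = alpha))
}

# encode an alignment (named character vector) as taxa x sites integer
# matrix; gaps and X become 0 (treated as missing data in the likelihood)
aln_int_matrix <- function(msa) {
  rows <- lapply(msa, function(s) {
    v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], .AA)
    v[is.na(v)] <- 0L
    v
  })
  do.call(rbind, rows)
}

# Felsenstein pruning: per-site likelihood of the alignment on 'phy' with a
# single rate multiplier applied to every site.  aln is taxa x sites integer
# (0 = missing).  Uniform 1/20 root frequencies.
lik_sites <- function(phy, aln, rate) {
  ntip <- length(phy$tip.label)
  S <- ncol(aln)
  phy <- stats::reorder(phy, "postorder")
  tipidx <- match(phy$tip.label, rownames(aln))
  L <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) {
    M <- matrix(0, 20L, S)
    v <- aln[tipidx[i], ]
    obs <- v > 0L
    M[cbind(v[obs], which(obs))] <- 1
    M[, !obs] <- 1
    L[[i]] <- M
  }
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
    P <- pmat_poisson(phy$edge.length[e] * rate)
    contrib <- P %*% L[[child]]
    L[[par]] <- if (is.null(L[[par]])) contrib else L[[par]] * contrib
  }
  root <- ntip + 1L
  colSums(L[[root]]) / 20
}

# golden-section maximisation of f on [lo, hi]
golden_max <- function(f, lo, hi, tol = 1e-3) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Per-site evolutionary rates by discrete-gamma posterior means
#'
#' Fits the gamma shape by maximising the whole-alignment likelihood under
#' `K` equal-probability discrete-gamma categories (golden-section search
#' over log alpha in \[0.05, 20\]), then reports each column's posterior-mean
#' rate and an equal-frequency 1-6 bin (1 = most conserved; ties broken by
#' column index).  All-gap columns are excluded from the quantiles and
#' reported as `NA`.
#'
#' @param msa named character vector of aligned protein sequences.
#' @param tree newick string or `phylo` with branch lengths; its leaves must
#'   be a subset of the alignment taxa.
#' @param K number of gamma categories.
#' @param alpha_range search interval for the shape parameter.
#' @param alpha optional fixed gamma shape; when given the search is skipped
#'   and posterior means are computed under this shape.
#' @return an object of class `r2_site_rates`: list with `alpha_hat`,
#'   `loglik`, `posterior_mean` (per column, `NA` for all-gap columns),
#'   `bins` (integer 1-6), `category_rates`, `K`.
#' @export
site_rates <- function(msa, tree, K = 4L, alpha_range = c(0.05, 20),
                       alpha = NULL) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length) || all(phy$edge.length <= 0))
    stop("tree must have positive branch length somewhere", call. = FALSE)
  if (!all(phy$tip.label %in% names(msa)))
    stop("tree leaves must be a subset of the alignment taxa", call. = FALSE)
  aln <- aln_int_matrix(msa[phy$tip.label])
  rownames(aln) <- phy$tip.label
  usable <- colSums(aln > 0L) > 0L
  sub <- aln[, usable, drop = FALSE]

  lik_by_cat <- function(alpha) {
    rk <- discrete_gamma(alpha, K)
    vapply(rk, function(r) lik_sites(phy, sub, r), numeric(ncol(sub)))
  }
  ll <- function(log_alpha) {
    Lk <- lik_by_cat(exp(log_alpha))
    sum(log(rowMeans(Lk)))
  }
  alpha_hat <- if (is.null(alpha))
    exp(golden_max(ll, log(alpha_range[1L]), log(alpha_range[2L])))
  else alpha
  rk <- discrete_gamma(alpha_hat, K)
  Lk <- lik_by_cat(alpha_hat)
  post <- as.vector((Lk %*% rk) / rowSums(Lk))

  pm <- rep(NA_real_, ncol(aln))
  pm[usable] <- post
  bins <- rep(NA_integer_, ncol(aln))
  bins[usable] <- as.integer(ceiling(
    6 * rank(post, ties.method = "first") / length(post)))
  structure(list(alpha_hat = alpha_hat, loglik = sum(log(rowMeans(Lk))),
                 posterior_mean = pm, bins = bins, category_rates = rk,
                 K = K),
            class = "r2_site_rates")
}
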