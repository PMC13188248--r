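# Neighbor joining with bootstrap supports, outgroup rooting, bipartition
# machinery and Robinson-Foulds distances.  Trees are ape "phylo" objects
# throughout; newick I/O goes through ape.

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration on the Q criterion; ties are broken by the
#' lowest taxon-index pair.  Negative branch lengths are clamped to zero
#' with the deficit moved to the sister edge.  The three remaining clusters
#' are resolved by the three-point formulas, so the result is an unrooted
#' binary tree with a basal trifurcation.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @param labels optional taxon labels (defaults to `rownames(D)`).
#' @return an unrooted `phylo`.
#' @export
nj_tree <- function(D, labels = NULL) {
  if (is.null(labels)) labels <- rownames(D)
  n <- nrow(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (n < 3L) stop("need at least three taxa", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-8)) stop("distance matrix must be symmetric",
                                      call. = FALSE)
  nodes <- as.list(labels)         # newick fragments
  d <- D
  active <- seq_len(n)
  fix_pair <- function(vi, vj) {
    # clamp a negative branch, moving the deficit to the sister edge
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    c(max(vi, 0), max(vj, 0))
  }
  while (length(active) > 3L) {
    m <- length(active)
    dm <- d[active, active, drop = FALSE]
    r <- rowSums(dm)
    Q <- (m - 2) * dm - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index pair among ties
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    vi <- 0.5 * dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dm[i, j] - vi
    v <- fix_pair(vi, vj)
    ai <- active[i]; aj <- active[j]
    frag <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[ai]], v[1L],
                    nodes[[aj]], v[2L])
    # distances to the new node
    rest <- active[-c(i, j)]
    dnew <- 0.5 * (d[ai, rest] + d[aj, rest] - d[ai, aj])
    d <- rbind(cbind(d, 0), 0)
    new_idx <- nrow(d)
    d[new_idx, rest] <- dnew
    d[rest, new_idx] <- dnew
    nodes[[new_idx]] <- frag
    active <- c(rest, new_idx)
  }
  a <- active[1L]; b <- active[2L]; c0 <- active[3L]
  va <- (d[a, b] + d[a, c0] - d[b, c0]) / 2
  vb <- (d[a, b] + d[b, c0] - d[a, c0]) / 2
  vc <- (d[a, c0] + d[b, c0] - d[a, b]) / 2
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nodes[[a]], max(va, 0),
                 nodes[[b]], max(vb, 0), nodes[[c0]], max(vc, 0))
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree with optional bootstrap supports and rooting
#'
#' Builds the NJ tree from `dist`; when `bootstrap` is given, alignment
#' columns are resampled with replacement `B` times, the tree is rebuilt per
#' replicate, and each internal bipartition's support is the percentage of
#' replicates containing it.  When `outgroup` is given the tree is rooted on
#' its pendant edge.  Supports are stored as internal node labels; the
#' conventional display threshold (80) is recorded in the
#' `"support_threshold"` attribute.
#'
#' @param dist symmetric distance matrix with taxon dimnames.
#' @param outgroup optional outgroup taxon name.
#' @param bootstrap optional list with `msa` (named aligned sequences), `B`
#'   (replicates, default 1000), `seed` (default 1), and `correction`
#'   (distance correction, default `"poisson"`).
#' @return a `phylo`; internal node labels carry bootstrap percentages when
#'   bootstrapping was requested.
#' @export
neighbor_joining <- function(dist, outgroup = NULL, bootstrap = NULL) {
  if (nrow(dist) < 3L) stop("need at least three taxa", call. = FALSE)
  phy <- nj_tree(dist)
  supp <- NULL
  if (!is.null(bootstrap)) {
    msa <- bootstrap$msa
    if (is.null(msa)) stop("bootstrap needs an 'msa'", call. = FALSE)
    B <- bootstrap$B %||% 1000L
    seed <- bootstrap$seed %||% 1L
    correction <- bootstrap$correction %||% "poisson"
    aln <- aln_int_matrix(msa)
    rownames(aln) <- names(msa)
    counts <- new.env(parent = emptyenv())
    with_seed(seed, {
      for (b in seq_len(B)) {
        cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
        res <- cpp_pdist(aln[, cols, drop = FALSE])
        p <- res$p
        db <- switch(correction,
                     "p" = p,
                     "poisson" = -log(1 - p),
                     "kimura-protein" = -log(1 - p - 0.2 * p^2))
        diag(db) <- 0
        dimnames(db) <- list(rownames(aln), rownames(aln))
        tb <- nj_tree(db)
        for (key in bip_keys(tb))
          assign(key, (counts[[key]] %||% 0L) + 1L, envir = counts)
      }
    })
    supp <- function(key) round(100 * (counts[[key]] %||% 0L) / B, 1)
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% phy$tip.label)
      stop("outgroup '", outgroup, "' not among the taxa", call. = FALSE)
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  if (!is.null(supp)) {
    ntip <- length(phy$tip.label)
    labs <- character(phy$Nnode)
    for (nd in seq_len(phy$Nnode)) {
      key <- clade_key(phy, ntip + nd)
      labs[nd] <- if (is.na(key)) "" else as.character(supp(key))
    }
    phy$node.label <- labs
  }
  attr(phy, "support_threshold") <- 80
  attr(phy, "method") <- "neighbor-joining"
  phy
}

# canonical bipartition key for the clade under internal node 'nd':
# the side not containing the alphabetically first taxon, sorted and joined
clade_key <- function(phy, nd) {
  tips <- sort(phy$tip.label)
  n <- length(tips)
  clade <- ape::extract.clade(phy, nd)$tip.label
  side <- if (tips[1L] %in% clade) setdiff(tips, clade) else clade
  if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
  paste(sort(side), collapse = "|")
}

# all non-trivial bipartition keys of a tree
bip_keys <- function(phy) {
  ntip <- length(phy$tip.label)
  keys <- vapply(seq_len(phy$Nnode), function(nd)
    clade_key(phy, ntip + nd), "")
  unique(keys[!is.na(keys)])
}

#' Internal nodes with bootstrap support below a display threshold
#'
#' @param phy a tree from [neighbor_joining()] with node labels.
#' @param threshold support display threshold (default 80, the conventional
#'   cutoff below which supports are shown at the nodes).
#' @return integer vector of internal node numbers with support below the
#'   threshold.
#' @export
low_support_nodes <- function(phy, threshold = 80) {
  if (is.null(phy$node.label)) return(integer(0))
  sup <- suppressWarnings(as.numeric(phy$node.label))
  which(!is.na(sup) & sup < threshold) + length(phy$tip.label)
}

#' Robinson-Foulds distance between two trees
#'
#' Both trees are pruned to their shared leaf set (at least four leaves
#' required) and the symmetric difference of internal bipartitions is
#' counted.
#'
#' @param t1,t2 `phylo` objects or newick strings.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  t1 <- as_phylo(t1); t2 <- as_phylo(t2)
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L)
    stop("trees share fewer than four leaves", call. = FALSE)
  t1 <- ape::keep.tip(t1, shared)
  t2 <- ape::keep.tip(t2, shared)
  k1 <- bip_keys(t1); k2 <- bip_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}
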