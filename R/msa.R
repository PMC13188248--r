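# Progressive multiple alignment (k-mer guide tree + profile-profile
# affine-gap merges), gap-fraction trimming, pairwise distances with
# standard corrections, and percentage identity matrices.

#' Progressive multiple sequence alignment
#'
#' A guide tree is built by neighbor joining on shared-k-mer distances and
#' the sequences are merged postorder by profile-profile alignment with
#' affine gaps (column scores are frequency-weighted substitution scores).
#' Gaps are only ever inserted: ungapping any row reproduces the input.
#'
#' @param seqs named character vector of protein sequences (unique names).
#' @param scoring protein [scoring_scheme()] (BLOSUM62 half-bits by
#'   default).
#' @param k k-mer size for the guide-tree distance.
#' @return named character vector of equal-length aligned sequences, in
#'   input order.
#' @export
align_progressive <- function(seqs, scoring = scoring_scheme(
                                "protein", gap_open = 11, gap_extend = 1),
                              k = 3L) {
  if (length(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids", call. = FALSE)
  n <- length(seqs)
  if (n == 2L) {
    al <- local_align(seqs[[1L]], seqs[[2L]], scoring, type = "global")
    out <- setNames(c(al$q_aln, al$s_aln), names(seqs))
    return(out)
  }
  # guide tree from shared-k-mer distances
  ksets <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) character(0) else unique(substring(s, 1:(L - k + 1L), k:L))
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    denom <- max(1L, min(length(ksets[[i]]), length(ksets[[j]])))
    d <- 1 - length(intersect(ksets[[i]], ksets[[j]])) / denom
    D[i, j] <- D[j, i] <- d
  }
  guide <- nj_tree(D)
  merges <- guide_merge_order(guide)

  # profiles held as character matrices (rows = sequences)
  profs <- lapply(seqs, function(s)
    matrix(strsplit(s, "", fixed = TRUE)[[1L]], nrow = 1L))
  names(profs) <- names(seqs)
  active <- as.list(names(seqs))
  names(active) <- names(seqs)
  groups <- stats::setNames(as.list(names(seqs)), names(seqs))

  S <- scoring$submat[1:20, 1:20]
  freq_of <- function(mat) {
    # 20 x L residue frequencies over non-gap residues
    L <- ncol(mat)
    f <- matrix(0, 20L, L)
    for (j in seq_len(L)) {
      col <- mat[, j]
      col <- col[col %in% .AA]
      if (length(col))
        f[, j] <- tabulate(match(col, .AA), nbins = 20L) / nrow(mat)
    }
    f
  }
  merge_two <- function(A, B) {
    fa <- freq_of(A); fb <- freq_of(B)
    C <- crossprod(fa, S %*% fb)
    path <- cpp_global_path(C, scoring$gap_open, scoring$gap_extend)$path
    out <- matrix("-", nrow = nrow(A) + nrow(B), ncol = length(path))
    ia <- 0L; ib <- 0L
    for (col in seq_along(path)) {
      if (path[col] != 3L) { ia <- ia + 1L; out[seq_len(nrow(A)), col] <- A[, ia] }
      if (path[col] != 2L) { ib <- ib + 1L
        out[nrow(A) + seq_len(nrow(B)), col] <- B[, ib] }
    }
    out
  }

  for (m in merges) {
    A <- profs[[m$left]]; B <- profs[[m$right]]
    merged <- merge_two(A, B)
    profs[[m$id]] <- merged
    groups[[m$id]] <- c(groups[[m$left]], groups[[m$right]])
    profs[[m$left]] <- NULL; profs[[m$right]] <- NULL
  }
  final_id <- merges[[length(merges)]]$id
  mat <- profs[[final_id]]
  rows <- apply(mat, 1L, paste, collapse = "")
  out <- setNames(rows, groups[[final_id]])
  out[names(seqs)]
}

# postorder merge schedule from a guide tree (phylo): list of
# (left, right, id) where left/right are tip names or prior merge ids
guide_merge_order <- function(phy) {
  ntip <- length(phy$tip.label)
  phy <- stats::reorder(phy, "postorder")
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  node_name <- character(ntip + phy$Nnode)
  node_name[seq_len(ntip)] <- phy$tip.label
  merges <- list()
  # postorder edge order lists children before parents
  nodes <- unique(phy$edge[, 1L])
  for (nd in nodes) {
    ch <- kids[[as.character(nd)]]
    nm <- node_name[ch]
    # fold multifurcations left to right
    cur <- nm[1L]
    for (x in nm[-1L]) {
      id <- sprintf("node_%d_%d", nd, length(merges) + 1L)
      merges[[length(merges) + 1L]] <- list(left = cur, right = x, id = id)
      cur <- id
    }
    node_name[nd] <- cur
  }
  merges
}

#' Trim alignment columns by gap fraction
#'
#' Columns whose gap fraction exceeds `max_gap_fraction` are dropped, in
#' order; the dropped 0-based column indices are recorded in the
#' `"dropped_cols"` attribute.
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param max_gap_fraction columns with a gap fraction above this are
#'   removed.
#' @return the trimmed alignment (same names), with attribute
#'   `dropped_cols`.
#' @export
trim_alignment <- function(msa, max_gap_fraction = 0.9) {
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) stop("all columns dropped by the gap-fraction trim",
                       call. = FALSE)
  out <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  structure(setNames(out, names(msa)),
            dropped_cols = which(!keep) - 1L)
}

#' Pairwise distance matrix from an alignment
#'
#' p-distance over columns where both rows are ungapped, with optional
#' Poisson (`d = -ln(1 - p)`) or Kimura protein
#' (`d = -ln(1 - p - 0.2 p^2)`) correction.
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param correction `"p"`, `"poisson"` or `"kimura-protein"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, correction = c("p", "poisson",
                                                "kimura-protein")) {
  correction <- match.arg(correction)
  if (length(msa) < 2L) stop("need at least two sequences", call. = FALSE)
  aln <- aln_int_matrix(msa)
  res <- cpp_pdist(aln)
  p <- res$p
  if (any(res$comparable[upper.tri(res$comparable)] == 0L)) {
    bad <- which(res$comparable == 0L & upper.tri(res$comparable),
                 arr.ind = TRUE)[1L, ]
    stop("no comparable columns between '", names(msa)[bad[1L]], "' and '",
         names(msa)[bad[2L]], "'", call. = FALSE)
  }
  d <- switch(correction,
              "p" = p,
              "poisson" = -log(1 - p),
              "kimura-protein" = -log(1 - p - 0.2 * p^2))
  diag(d) <- 0
  dimnames(d) <- list(names(msa), names(msa))
  d
}

#' Percentage identity matrix
#'
#' Identity is `100 * matches / columns with at least one residue` for each
#' pair; unaligned input is aligned first.  The diagonal is 100.
#'
#' @param seqs named character vector (aligned or unaligned).
#' @param ... passed to [align_progressive()] when alignment is needed.
#' @return symmetric percentage matrix.
#' @export
identity_matrix <- function(seqs, ...) {
  if (length(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    seqs <- align_progressive(seqs, ...)
  aln <- aln_int_matrix(seqs)
  n <- nrow(aln)
  out <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- aln[i, ]; b <- aln[j, ]
    cols <- a > 0L | b > 0L
    denom <- sum(cols)
    pct <- if (denom == 0L) NA_real_ else
      100 * sum(a[cols] == b[cols] & a[cols] > 0L) / denom
    out[i, j] <- out[j, i] <- pct
  }
  out
}
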