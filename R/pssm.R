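# Position-specific scoring matrices: construction from an alignment with
# pseudocounts, gapped profile scoring, and the two-reference lineage
# placement of candidate RT families.

round_half_bits <- function(x) round(2 * x) / 2

#' Build a position-specific scoring matrix from aligned sequences
#'
#' Columns with more than `max_gap_frac` gaps are dropped (and recorded).
#' Column frequencies are `(counts + pseudocount * background) /
#' (n + pseudocount)` and scores are `2 * log2(freq / background)` half-bit
#' log-odds, rounded to half-bits.  The ambiguous residue X receives a fixed
#' penalty in every column so it can never satisfy a motif position.
#'
#' @param aligned_seqs character vector of equal-length (gapped) sequences;
#'   a single ungapped sequence is allowed.
#' @param pseudocount positive pseudocount mass.
#' @param background length-20 background frequency vector (sums to 1).
#' @param max_gap_frac columns with a gap fraction above this are dropped.
#' @param x_score score assigned to X in every column.
#' @return an object of class `r2_pssm`: list with `length`, `scores`
#'   (length x 21 matrix over the 20 residues plus X), `background`,
#'   `pseudocount`, `dropped_cols` (0-based indices), `max_score`.
#' @export
build_pssm <- function(aligned_seqs, pseudocount = 1, background = NULL,
                       max_gap_frac = 0.5, x_score = -4) {
  if (length(aligned_seqs) == 0L || all(!nzchar(aligned_seqs)))
    stop("empty alignment", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-6)
    stop("background must be a length-20 frequency vector", call. = FALSE)
  lens <- nchar(aligned_seqs)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(aligned_seqs), "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac <= max_gap_frac)
  if (!length(keep)) stop("all columns exceed the gap fraction", call. = FALSE)
  L <- length(keep)
  scores <- matrix(0, nrow = L, ncol = 21L,
                   dimnames = list(NULL, .AAX))
  for (i in seq_len(L)) {
    col <- mat[, keep[i]]
    col <- col[col %in% .AA]
    n <- length(col)
    counts <- tabulate(match(col, .AA), nbins = 20L)
    freq <- (counts + pseudocount * background) / (n + pseudocount)
    scores[i, 1:20] <- round_half_bits(2 * log2(freq / background))
    scores[i, 21L] <- x_score
  }
  structure(list(length = L, scores = scores, background = background,
                 pseudocount = pseudocount, dropped_cols = setdiff(
                   seq_len(ncol(mat)), keep) - 1L,
                 max_score = sum(apply(scores[, 1:20, drop = FALSE], 1, max))),
            class = "r2_pssm")
}

#' Score a query against a PSSM by gapped local alignment
#'
#' Affine-gap dynamic programming of the query over the profile columns;
#' the result is the optimal local score in half-bits (floored at zero).
#'
#' @param query_aa query protein sequence.
#' @param pssm an `r2_pssm`.
#' @param gap_open,gap_extend gap penalties (half-bits); a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @return list with `score`, `q_start`, `q_end`, `col_start`, `col_end`
#'   (0-based half-open).
#' @export
score_against_pssm <- function(query_aa, pssm, gap_open = 11, gap_extend = 1) {
  if (!nzchar(query_aa)) stop("query must be non-empty", call. = FALSE)
  v <- enc_aa(query_aa)
  cpp_profile_align(v, pssm$scores, gap_open, gap_extend)
}

#' Place a candidate RT family relative to the two lineage references
#'
#' A PSSM is built from the candidate family (the family forms the profile;
#' the references are the queries, mirroring a PSI-BLAST-style database
#' search) and both lineage reference RTs are scored against it.  The call
#' is the larger score unless the margin is within `tie_epsilon` half-bits.
#'
#' @param family character vector of family member sequences (aligned or
#'   unaligned; unaligned families of more than one sequence are aligned
#'   first).
#' @param ref_A,ref_D lineage reference RT sequences (defaults: the shipped
#'   synthetic references).
#' @param pseudocount PSSM pseudocount.
#' @param tie_epsilon half-bit margin below which the call is ambiguous.
#' @param gap_open,gap_extend profile alignment gap penalties.
#' @return an object of class `r2_lineage_placement`: list with
#'   `score_vs_A`, `score_vs_D`, `call` (`"A"`, `"D"`, `"ambiguous"`) and
#'   `margin` (signed, positive toward A).
#' @export
lineage_placement <- function(family, ref_A = NULL, ref_D = NULL,
                              pseudocount = 1, tie_epsilon = 2,
                              gap_open = 11, gap_extend = 1) {
  if (length(family) < 1L) stop("family must contain a sequence", call. = FALSE)
  if (is.null(ref_A) || is.null(ref_D)) {
    refs <- lineage_reference_rts()
    if (is.null(ref_A)) ref_A <- refs[["A"]]
    if (is.null(ref_D)) ref_D <- refs[["D"]]
  }
  aligned <- family
  if (length(family) > 1L && length(unique(nchar(family))) != 1L) {
    if (is.null(names(aligned)))
      names(aligned) <- sprintf("fam_%03d", seq_along(aligned))
    aligned <- align_progressive(aligned)
  }
  pssm <- build_pssm(aligned, pseudocount = pseudocount)
  sA <- score_against_pssm(ref_A, pssm, gap_open, gap_extend)$score
  sD <- score_against_pssm(ref_D, pssm, gap_open, gap_extend)$score
  margin <- sA - sD
  call <- if (abs(margin) < tie_epsilon) "ambiguous"
          else if (margin > 0) "A" else "D"
  structure(list(score_vs_A = sA, score_vs_D = sD, call = call,
                 margin = margin),
            class = "r2_lineage_placement")
}
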