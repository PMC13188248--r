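# Element discovery: affine-gap local alignment (the package's stand-in for
# a BLAST-like search), exact k-mer seeding with diagonal chaining, and
# merging of fragmented hits into loci.

#' Scoring scheme for pairwise alignment
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param match,mismatch nucleotide match/mismatch scores (`N` scores as a
#'   mismatch against everything).
#' @param gap_open,gap_extend non-negative gap penalties; a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @param submat optional substitution matrix for protein mode (defaults to
#'   BLOSUM62 in half-bits, with ambiguous X scoring -4 everywhere).
#' @return an object of class `r2_scoring`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"), match = 2,
                           mismatch = -3, gap_open = 5, gap_extend = 2,
                           submat = NULL) {
  mode <- match.arg(mode)
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0", call. = FALSE)
  S <- if (mode == "nucleotide") nt_submat(match, mismatch)
       else if (is.null(submat)) aa_submat() else submat
  structure(list(mode = mode, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend, submat = S),
            class = "r2_scoring")
}

encode_for <- function(x, scoring) {
  if (scoring$mode == "nucleotide") enc_nt(x) else enc_aa(x)
}

alphabet_for <- function(scoring) {
  if (scoring$mode == "nucleotide") .NT else .AAX
}

#' Optimal local (or global) pairwise alignment with affine gaps
#'
#' Smith-Waterman (or Needleman-Wunsch for `type = "global"`) with Gotoh
#' affine gaps.  `a` is the query, `b` the subject; coordinates are 0-based
#' half-open.
#'
#' @param a,b sequences (single strings).
#' @param scoring a [scoring_scheme()].
#' @param type `"local"` (default) or `"global"`.
#' @return list with `score`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   aligned strings `q_aln`/`s_aln` (gap = `-`), and `identity` (matching
#'   columns over aligned columns, double gaps excluded).
#' @export
local_align <- function(a, b, scoring = scoring_scheme(),
                        type = c("local", "global")) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  va <- encode_for(a, scoring)
  vb <- encode_for(b, scoring)
  res <- cpp_pair_align(va, vb, scoring$submat, scoring$gap_open,
                        scoring$gap_extend, type == "global")
  al <- alphabet_for(scoring)
  qa <- dec_seq(res$a_aln, al)
  sa <- dec_seq(res$s_aln %||% res$b_aln, al)
  ident <- alignment_identity(res$a_aln, res$b_aln)
  list(score = res$score,
       q_start = res$a_start, q_end = res$a_end,
       s_start = res$b_start, s_end = res$b_end,
       q_aln = qa, s_aln = sa, identity = ident)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

alignment_identity <- function(va, vb) {
  keep <- !(va == 0L & vb == 0L)
  if (!any(keep)) return(NA_real_)
  sum(va[keep] == vb[keep] & va[keep] > 0L) / sum(keep)
}

# k-mer index of one sequence: named list kmer -> start positions (1-based),
# k-mers containing N/X are skipped, as are k-mers above max_occ occurrences.
kmer_index <- function(seq, k, max_occ = Inf, bad = "N") {
  L <- nchar(seq)
  if (L < k) return(list())
  km <- substring(seq, 1:(L - k + 1L), k:L)
  ok <- !grepl(paste0("[", bad, "*]"), km)
  idx <- split(which(ok), km[ok])
  if (is.finite(max_occ)) idx <- idx[lengths(idx) <= max_occ]
  idx
}

# chain seeds (qpos, spos 1-based) into diagonal clusters; a chain breaks on
# diagonal drift beyond diag_tol, a subject gap beyond max_chain_gap, or a
# backwards subject jump (seeds in one chain must be co-linear)
chain_seeds <- function(qpos, spos, diag_tol, max_chain_gap) {
  d <- spos - qpos
  o <- order(d, spos)
  d <- d[o]; qpos <- qpos[o]; spos <- spos[o]
  ds <- diff(spos)
  brk <- c(TRUE, diff(d) > diag_tol | ds > max_chain_gap | ds < 0L)
  grp <- cumsum(brk)
  lapply(split(seq_along(grp), grp), function(i)
    list(q = qpos[i], s = spos[i], n = length(i)))
}

#' Scan contigs for matches to query sequences
#'
#' Exact k-mer seeds are located on both strands, seeds on nearby diagonals
#' are chained, and each chain is extended by local alignment of the query
#' against the spanned contig segment.  Translated mode scans all six frames
#' of the contig against protein queries and reports nucleotide coordinates.
#'
#' @param queries,contigs named character vectors or FASTA paths.
#' @param mode `"nucleotide"` or `"translated"`.
#' @param k seed length; defaults to 7 in nucleotide mode (sensitive
#'   BLASTN-like word size) and 3 in translated mode. Must be >= 4
#'   (nucleotide) or >= 2 (translated).
#' @param scoring a [scoring_scheme()] (defaults fit the mode).
#' @param min_score minimum alignment score to report.
#' @param min_seeds minimum seeds per chain before extension (4 by default; exact matches of a >= 50 nt query always exceed this).
#' @param diag_tol diagonal drift tolerated within one chain (nt).
#' @param max_chain_gap maximum subject gap between chained seeds (nt).
#' @param max_occ contig k-mers occurring more often than this are masked.
#' @return data frame of hits: `contig_id`, `query_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end` (0-based half-open, subject coordinates always on the
#'   forward strand of the contig), `strand`, `score`, `identity`.
#' @export
scan_genome <- function(queries, contigs, mode = c("nucleotide", "translated"),
                        k = NULL, scoring = NULL, min_score = 60,
                        min_seeds = 4L, diag_tol = 30L, max_chain_gap = 300L,
                        max_occ = 64L) {
  mode <- match.arg(mode)
  queries <- as_seqset(queries, if (mode == "nucleotide") "dna" else "aa")
  contigs <- as_seqset(contigs, "dna")
  if (length(queries) == 0L) stop("no query sequences", call. = FALSE)
  if (is.null(k)) k <- if (mode == "nucleotide") 7L else 3L
  if (mode == "nucleotide" && k < 4L) stop("k must be >= 4", call. = FALSE)
  if (mode == "translated" && k < 2L) stop("k must be >= 2", call. = FALSE)
  if (is.null(scoring))
    scoring <- if (mode == "nucleotide") scoring_scheme("nucleotide")
               else scoring_scheme("protein", gap_open = 11, gap_extend = 1)

  hits <- list()
  for (cname in names(contigs)) {
    contig <- contigs[[cname]]
    if (mode == "nucleotide") {
      cidx <- kmer_index(contig, k, max_occ = max_occ)
      for (qname in names(queries)) {
        for (strand in c("+", "-")) {
          q <- if (strand == "+") queries[[qname]] else revcomp(queries[[qname]])
          h <- scan_one(q, contig, cidx, k, scoring, min_score, min_seeds,
                        diag_tol, max_chain_gap)
          if (is.null(h)) next
          if (strand == "-") {
            qlen <- nchar(q)
            tmp <- h$q_start
            h$q_start <- qlen - h$q_end
            h$q_end <- qlen - tmp
          }
          h$strand <- strand; h$query_id <- qname; h$contig_id <- cname
          hits[[length(hits) + 1L]] <- h
        }
      }
    } else {
      frames <- six_frames(contig)
      for (fr in frames) {
        fidx <- kmer_index(fr$aa, k, max_occ = max_occ, bad = "X")
        for (qname in names(queries)) {
          h <- scan_one(queries[[qname]], fr$aa, fidx, k, scoring, min_score,
                        min_seeds, diag_tol, max_chain_gap)
          if (is.null(h)) next
          nt <- aa_to_nt_coords(h$s_start, h$s_end, fr, nchar(contig))
          h$s_start <- nt[1]; h$s_end <- nt[2]
          h$strand <- fr$strand; h$query_id <- qname; h$contig_id <- cname
          hits[[length(hits) + 1L]] <- h
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(contig_id = character(), query_id = character(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), score = numeric(),
                      identity = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[out$score >= min_score, , drop = FALSE]
  out <- dedupe_hits(out)
  rownames(out) <- NULL
  out[, c("contig_id", "query_id", "q_start", "q_end", "s_start", "s_end",
          "strand", "score", "identity")]
}

# seed, chain and extend one (query, subject) pair; returns hit rows or NULL
scan_one <- function(q, s, sidx, k, scoring, min_score, min_seeds, diag_tol,
                     max_chain_gap) {
  qlen <- nchar(q); slen <- nchar(s)
  if (qlen < k) return(NULL)
  bad <- if (scoring$mode == "nucleotide") "N" else "X"
  qk <- substring(q, 1:(qlen - k + 1L), k:qlen)
  ok <- which(!grepl(paste0("[", bad, "*]"), qk))
  if (!length(ok)) return(NULL)
  present <- ok[qk[ok] %in% names(sidx)]
  if (!length(present)) return(NULL)
  slist <- sidx[qk[present]]
  qpos <- rep(present, lengths(slist))
  spos <- unlist(slist, use.names = FALSE)
  chains <- chain_seeds(qpos, spos, diag_tol, max_chain_gap)
  chains <- chains[vapply(chains, `[[`, 0L, "n") >= min_seeds]
  if (!length(chains)) return(NULL)
  # cheap ungapped extension along the chain diagonal weeds out chance
  # repeats before any gapped DP is spent on them
  vq <- enc_for_scan(q, scoring)
  vs <- enc_for_scan(s, scoring)
  pre_min <- min(min_score, 40)
  keep <- vapply(chains, function(ch)
    ungapped_diag_score(vq, vs, ch, k, scoring) >= pre_min, TRUE)
  chains <- chains[keep]
  if (!length(chains)) return(NULL)
  # strongest chains first; weaker chains already covered by a hit are
  # skipped so fragmentary seed clusters do not trigger redundant DP
  chains <- chains[order(-vapply(chains, `[[`, 0L, "n"))]
  extend_cap <- 1500L
  rows <- list()
  for (ch in chains) {
    mid <- (min(ch$s) + max(ch$s) + k) / 2
    covered <- FALSE
    for (r in rows)
      if (mid >= r$s_start && mid <= r$s_end) { covered <- TRUE; break }
    if (covered) next
    pad <- 50L
    lo <- max(1L, min(ch$s) - min(extend_cap, min(ch$q) - 1L) - pad)
    hi <- min(slen, max(ch$s) + k - 1L +
                min(extend_cap, qlen - max(ch$q) - k + 1L) + pad)
    seg <- substr(s, lo, hi)
    al <- local_align(q, seg, scoring)
    if (al$score < min_score) next
    rows[[length(rows) + 1L]] <- data.frame(
      q_start = al$q_start, q_end = al$q_end,
      s_start = lo - 1L + al$s_start, s_end = lo - 1L + al$s_end,
      score = al$score, identity = al$identity, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

enc_for_scan <- function(x, scoring) {
  if (scoring$mode == "nucleotide") enc_nt(x) else enc_aa(x)
}

# best contiguous ungapped score (Kadane) along the chain's median diagonal,
# within a window around the chain span
ungapped_diag_score <- function(vq, vs, ch, k, scoring, window = 400L) {
  diag <- as.integer(stats::median(ch$s - ch$q))
  q0 <- max(1L, min(ch$q) - window)
  q1 <- min(length(vq), max(ch$q) + k - 1L + window)
  s0 <- q0 + diag; s1 <- q1 + diag
  if (s1 < 1L || s0 > length(vs)) return(0)
  if (s0 < 1L) { q0 <- q0 + (1L - s0); s0 <- 1L }
  if (s1 > length(vs)) { q1 <- q1 - (s1 - length(vs)); s1 <- length(vs) }
  if (q1 <= q0) return(0)
  a <- vq[q0:q1]; b <- vs[s0:s1]
  sc <- ifelse(a == b & a > 0L &
                 (scoring$mode != "nucleotide" | a != 5L),
               if (scoring$mode == "nucleotide") scoring$match else 4,
               if (scoring$mode == "nucleotide") scoring$mismatch else -1)
  cs <- cumsum(sc)
  max(0, cs - cummin(c(0, cs[-length(cs)])))
}

# keep the best-scoring hit among near-identical duplicates produced by
# multiple chains of the same (contig, query, strand)
dedupe_hits <- function(h) {
  if (nrow(h) < 2L) return(h)
  key <- paste(h$contig_id, h$query_id, h$strand)
  keep <- logical(nrow(h))
  for (kk in unique(key)) {
    i <- which(key == kk)
    i <- i[order(-h$score[i])]
    chosen <- integer()
    for (j in i) {
      dup <- FALSE
      for (c0 in chosen) {
        ov <- min(h$s_end[j], h$s_end[c0]) - max(h$s_start[j], h$s_start[c0])
        if (ov > 0.5 * (h$s_end[j] - h$s_start[j])) { dup <- TRUE; break }
      }
      if (!dup) chosen <- c(chosen, j)
    }
    keep[chosen] <- TRUE
  }
  h[keep, , drop = FALSE]
}

# translations of all six frames with coordinate bookkeeping
six_frames <- function(contig) {
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    for (f in 0:2) {
      L <- nchar(s) - f
      L <- L - (L %% 3L)
      if (L < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f + 1L, f + L)),
        if.fuzzy.codon = "X"))
      # stops become X: they can neither seed nor match, but keep coordinates
      aa <- gsub("*", "X", aa, fixed = TRUE)
      out[[length(out) + 1L]] <- list(aa = aa, frame = f, strand = strand)
    }
  }
  out
}

# map 0-based half-open aa coordinates in a frame back to forward-strand nt
aa_to_nt_coords <- function(aa_start, aa_end, fr, contig_len) {
  nt_start <- fr$frame + 3L * aa_start
  nt_end <- fr$frame + 3L * aa_end
  if (fr$strand == "+") c(nt_start, nt_end)
  else c(contig_len - nt_end, contig_len - nt_start)
}

#' Merge fragmented hits into loci
#'
#' Hits on the same contig and strand separated by at most `max_gap` are
#' merged into one locus spanning their union; each locus keeps its best
#' score and query.  Merging is idempotent: loci are pairwise separated by
#' more than `max_gap`.
#'
#' @param hits data frame from [scan_genome()].
#' @param max_gap maximum separation (nt) between merged hits.
#' @return data frame of loci: `contig_id`, `start`, `end`, `strand`,
#'   `n_hits`, `score`, `query_id`, `identity`.
#' @export
merge_loci <- function(hits, max_gap = 100L) {
  if (nrow(hits) == 0L)
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_hits = integer(), score = numeric(),
                      query_id = character(), identity = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(hits$contig_id, hits$strand)
  out <- list()
  for (kk in unique(key)) {
    h <- hits[key == kk, , drop = FALSE]
    h <- h[order(h$s_start, h$s_end), , drop = FALSE]
    cur <- h[1, , drop = FALSE]
    cur_end <- cur$s_end; cur_start <- cur$s_start
    members <- 1L
    flush <- function(cur, cur_start, cur_end, members, block) {
      best <- block[which.max(block$score), , drop = FALSE]
      data.frame(contig_id = cur$contig_id, start = cur_start, end = cur_end,
                 strand = cur$strand, n_hits = members, score = best$score,
                 query_id = best$query_id, identity = best$identity,
                 stringsAsFactors = FALSE)
    }
    block_rows <- 1L
    for (i in seq_len(nrow(h))[-1]) {
      if (h$s_start[i] - cur_end <= max_gap) {
        cur_end <- max(cur_end, h$s_end[i])
        members <- members + 1L
        block_rows <- c(block_rows, i)
      } else {
        out[[length(out) + 1L]] <- flush(cur, cur_start, cur_end, members,
                                         h[block_rows, , drop = FALSE])
        cur <- h[i, , drop = FALSE]
        cur_start <- h$s_start[i]; cur_end <- h$s_end[i]
        members <- 1L; block_rows <- i
      }
    }
    out[[length(out) + 1L]] <- flush(cur, cur_start, cur_end, members,
                                     h[block_rows, , drop = FALSE])
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
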