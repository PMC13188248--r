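# Read rescue: recover full-length elements from long reads when the
# assembly is truncated or chimeric.  Reads hitting the query are clustered
# by mutual overlap (shared k-mers) and each cluster is collapsed to a
# majority-vote consensus that is iteratively polished against the reads.
# This is a deliberately simplified consensus/polish stage: correction
# quality is asserted on synthetic data only.

#' Recover element candidates from long reads
#'
#' @param query query sequence (single string) used to fish reads.
#' @param long_reads data frame from [simulate_reads()], FASTQ path, or named
#'   character vector.
#' @param short_reads optional short reads (same forms); when given they are
#'   added to the voting pool for the polish rounds.
#' @param polish_rounds consensus/polish iterations per cluster.
#' @param min_hit_score minimum local-alignment score for a read to count as
#'   hitting the query.
#' @param k_overlap k-mer size for read-read overlap detection.
#' @param min_shared minimum shared k-mers to link two reads in a cluster.
#' @param scoring nucleotide [scoring_scheme()].
#' @return list of candidates, each a list with `id`, `seq`,
#'   `supporting_read_count`, `read_ids`, `source = "read-rescue"`.  Empty
#'   list when no read hits the query.
#' @export
rescue_from_reads <- function(query, long_reads, short_reads = NULL,
                              polish_rounds = 2L, min_hit_score = 80,
                              k_overlap = 13L, min_shared = 3L,
                              scoring = scoring_scheme()) {
  reads <- as_read_seqs(long_reads)
  if (length(reads) < 1L) stop("need at least one long read", call. = FALSE)

  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < k_overlap) character(0) else
      unique(substring(s, 1:(L - k_overlap + 1L), k_overlap:L))
  }

  # seed the clusters with reads hitting the query, oriented to its strand
  oriented <- character(0)
  for (id in names(reads)) {
    fw <- local_align(reads[[id]], query, scoring)
    rv <- local_align(revcomp(reads[[id]]), query, scoring)
    if (max(fw$score, rv$score) < min_hit_score) next
    oriented[id] <- if (fw$score >= rv$score) reads[[id]] else
      revcomp(reads[[id]])
  }
  if (!length(oriented)) return(list())

  # recruit the remaining reads by k-mer overlap with the growing pool, so a
  # cluster extends past the query into the element's full span
  pool_kmers <- unique(unlist(lapply(oriented, kmers_of), use.names = FALSE))
  unassigned <- setdiff(names(reads), names(oriented))
  repeat {
    added <- FALSE
    for (id in unassigned) {
      fw <- reads[[id]]; rv <- revcomp(fw)
      nf <- length(intersect(kmers_of(fw), pool_kmers))
      nr <- length(intersect(kmers_of(rv), pool_kmers))
      if (max(nf, nr) >= min_shared) {
        oriented[id] <- if (nf >= nr) fw else rv
        pool_kmers <- unique(c(pool_kmers, kmers_of(oriented[id])))
        added <- TRUE
      }
    }
    unassigned <- setdiff(names(reads), names(oriented))
    if (!added || !length(unassigned)) break
  }

  # split the pool into clusters of mutually overlapping reads
  ksets <- lapply(oriented, kmers_of)
  n <- length(oriented)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (length(intersect(ksets[[i]], ksets[[j]])) >= min_shared) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  clusters <- split(seq_len(n), roots)

  out <- list()
  for (ci in seq_along(clusters)) {
    members <- clusters[[ci]]
    rs <- oriented[members]
    draft <- rs[[which.max(nchar(rs))]]
    quiet_rounds <- 0L
    for (round in seq_len(25L)) {
      pool <- rs
      if (!is.null(short_reads)) {
        sr <- as_read_seqs(short_reads)
        pool <- c(pool, orient_to(sr, draft, scoring, min_hit_score / 2))
      }
      res <- consensus_round(draft, pool, scoring)
      draft <- res$draft
      quiet_rounds <- if (res$extended) 0L else quiet_rounds + 1L
      # keep polishing a few rounds after the draft stops growing
      if (quiet_rounds >= max(1L, polish_rounds)) break
    }
    out[[length(out) + 1L]] <- list(
      id = sprintf("rescue_%02d", length(out) + 1L),
      seq = draft,
      supporting_read_count = length(members),
      read_ids = names(rs),
      source = "read-rescue")
  }
  out
}

as_read_seqs <- function(x) {
  if (is.data.frame(x)) return(setNames(x$seq, x$id))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    r <- read_fastq(x)
    return(setNames(r$seq, r$id))
  }
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("reads must be a data frame, FASTQ path, or named character vector",
       call. = FALSE)
}

orient_to <- function(reads, target, scoring, min_score) {
  out <- character(0)
  for (id in names(reads)) {
    fw <- local_align(reads[[id]], target, scoring)
    rv <- local_align(revcomp(reads[[id]]), target, scoring)
    if (max(fw$score, rv$score) < min_score) next
    out[id] <- if (fw$score >= rv$score) reads[[id]] else revcomp(reads[[id]])
  }
  out
}

# One consensus round: align every read to the draft, collect per-position
# replacement strings (substitution, "" = deletion, base+insertion), take the
# per-position majority among covering reads, and extend the draft with the
# longest read overhang hanging off either end (assembly-style extension;
# later rounds polish the newly added, initially single-read, sequence).
consensus_round <- function(draft, reads, scoring, min_overhang = 20L) {
  L <- nchar(draft)
  votes <- vector("list", L)
  dchars <- strsplit(draft, "", fixed = TRUE)[[1L]]
  left_ext <- ""; right_ext <- ""
  for (rd in reads) {
    al <- local_align(rd, draft, scoring)
    if (al$score <= 0) next
    if (al$s_start == 0L && al$q_start >= min_overhang &&
        al$q_start > nchar(left_ext))
      left_ext <- substr(rd, 1L, al$q_start)
    if (al$s_end == L && nchar(rd) - al$q_end >= min_overhang &&
        nchar(rd) - al$q_end > nchar(right_ext))
      right_ext <- substring(rd, al$q_end + 1L)
    q <- strsplit(al$q_aln, "", fixed = TRUE)[[1L]]
    s <- strsplit(al$s_aln, "", fixed = TRUE)[[1L]]
    pos <- al$s_start   # 0-based position of next draft char
    repl <- character(L)
    covered <- logical(L)
    for (col in seq_along(q)) {
      if (s[col] == "-") {
        # insertion relative to draft: attach to the preceding draft position
        if (pos >= 1L && covered[pos])
          repl[pos] <- paste0(repl[pos], q[col])
      } else {
        pos <- pos + 1L              # draft position 'pos' (1-based)
        repl[pos] <- if (q[col] == "-") "" else q[col]
        covered[pos] <- TRUE
      }
    }
    for (p in which(covered))
      votes[[p]] <- c(votes[[p]], repl[p])
  }
  pieces <- dchars
  for (p in seq_len(L)) {
    v <- votes[[p]]
    if (length(v) < 2L) next          # keep draft where coverage is thin
    tab <- sort(table(v), decreasing = TRUE)
    # plurality rule: alignment ambiguity around indels splits the majority
    # across equivalent edits, so the top vote wins when strictly ahead;
    # ties keep the draft
    if (length(tab) == 1L || tab[[1L]] > tab[[2L]]) pieces[p] <- names(tab)[1L]
  }
  list(draft = paste0(left_ext, paste(pieces, collapse = ""), right_ext),
       extended = nzchar(left_ext) || nzchar(right_ext))
}
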