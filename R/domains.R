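# ORF extraction and N-terminal domain annotation: the zinc-finger grammar,
# profile-based Myb/RLE/knuckle and RT motif detectors, architecture
# classification, and the N-terminal trim used before tree building.

#' Extract non-canonically translated ORFs
#'
#' R2 ORFs need not begin with a methionine, so ORFs are maximal stop-free
#' stretches in each of the three frames on the element strand (standard
#' genetic code).  Records at least `min_len_aa` residues long go to `full`
#' (the "less than 900 amino acids" filter excludes 899 and keeps 900);
#' shorter ones go to `partial`.  Codons containing N translate to X, and X
#' never satisfies a motif position downstream.
#'
#' @param element_nt element nucleotide sequence (strand-fixed).
#' @param min_len_aa full-length threshold in amino acids.
#' @return list with `full` and `partial`, each a data frame of ORF records:
#'   `aa_seq`, `frame` (0..2), `nt_start`, `nt_end` (0-based half-open on the
#'   element), `length_aa`.
#' @export
extract_orfs <- function(element_nt, min_len_aa = 900L) {
  if (nchar(element_nt) < 3L)
    stop("element sequence shorter than one codon", call. = FALSE)
  enc_nt(element_nt)   # validates the alphabet
  recs <- list()
  for (f in 0:2) {
    L <- nchar(element_nt) - f
    L <- L - (L %% 3L)
    if (L < 3L) next
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(element_nt, f + 1L, f + L)),
      if.fuzzy.codon = "X"))
    # maximal stop-free stretches
    stops <- gregexpr("*", aa, fixed = TRUE)[[1L]]
    bounds <- c(0L, if (stops[1L] != -1L) stops else NULL,
                nchar(aa) + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      a0 <- bounds[b]          # aa index before the stretch (1-based stops)
      a1 <- bounds[b + 1L]     # aa index of the next stop
      len <- a1 - a0 - 1L
      if (len < 1L) next
      seq_aa <- substr(aa, a0 + 1L, a1 - 1L)
      recs[[length(recs) + 1L]] <- data.frame(
        aa_seq = seq_aa, frame = f,
        nt_start = f + 3L * a0, nt_end = f + 3L * (a1 - 1L),
        length_aa = len, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    empty <- data.frame(aa_seq = character(), frame = integer(),
                        nt_start = integer(), nt_end = integer(),
                        length_aa = integer(), stringsAsFactors = FALSE)
    return(list(full = empty, partial = empty))
  }
  all_orfs <- do.call(rbind, recs)
  all_orfs <- all_orfs[order(-all_orfs$length_aa), , drop = FALSE]
  rownames(all_orfs) <- NULL
  list(full = all_orfs[all_orfs$length_aa >= min_len_aa, , drop = FALSE],
       partial = all_orfs[all_orfs$length_aa < min_len_aa, , drop = FALSE])
}

# Enumerate every match of the zinc-finger grammar
#   C x(s) C x(8-14) H x(3-5) [H|C],  s in {1,2,3}
# Returns one row per raw match (1-based start of the first C).
znf_enumerate <- function(aa) {
  ch <- strsplit(aa, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cpos <- which(ch == "C")
  out <- list()
  for (c1 in cpos) {
    for (s in 1:3) {
      c2 <- c1 + s + 1L
      if (c2 > n || ch[c2] != "C") next
      for (g1 in 8:14) {
        hp <- c2 + g1 + 1L
        if (hp > n || ch[hp] != "H") next
        for (g2 in 3:5) {
          lp <- hp + g2 + 1L
          if (lp > n || !(ch[lp] %in% c("H", "C"))) next
          out[[length(out) + 1L]] <- data.frame(
            start1 = c1, end1 = lp, s = s,
            pair_type = if (ch[lp] == "H") "CCHH" else "CCHC",
            cpcc = (c1 + 3L <= n &&
                      substr(aa, c1, c1 + 3L) == "CPCC"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Deterministic selection among raw grammar matches: order by start, then
# prefer the CxxC parse when the literal first-pair region is C,P,C,C, then
# shorter first-pair spacing, then shorter total span; accept greedily
# left-to-right without overlaps.
znf_select <- function(raw) {
  o <- order(raw$start1, !(raw$cpcc & raw$s == 2L), raw$s, raw$end1)
  raw <- raw[o, , drop = FALSE]
  chosen <- integer(0)
  last_end <- 0L
  for (i in seq_len(nrow(raw))) {
    if (raw$start1[i] > last_end) {
      chosen <- c(chosen, i)
      last_end <- raw$end1[i]
    }
  }
  raw[chosen, , drop = FALSE]
}

#' Annotate zinc fingers by motif grammar
#'
#' Scans with the grammar `C x(s) C x(8-14) H x(3-5) [H|C]`, `s` in
#' \{1,2,3\}: the final coordinating residue gives the pair type (CCHH vs
#' CCHC, the ZnF2 signature), the first-pair spacing gives the variant
#' (CxC/CxxC/CxxxC), and a literal C,P,C,C first-pair region raises
#' `cpcc_flag`.  Overlapping matches are resolved greedily left-to-right.
#' Finger numbers are assigned later by [classify_architecture()].
#'
#' @param aa protein sequence.
#' @return data frame of hits (possibly empty): `start`, `end` (0-based
#'   half-open), `pair_type`, `first_pair_variant`, `cpcc_flag`,
#'   `assigned_number` (`NA` until numbered).
#' @export
annotate_znf <- function(aa) {
  empty <- data.frame(start = integer(), end = integer(),
                      pair_type = character(),
                      first_pair_variant = character(),
                      cpcc_flag = logical(), assigned_number = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(aa)) return(empty)
  raw <- znf_enumerate(aa)
  if (is.null(raw)) return(empty)
  sel <- znf_select(raw)
  data.frame(start = sel$start1 - 1L, end = sel$end1,
             pair_type = sel$pair_type,
             first_pair_variant = c("CxC", "CxxC", "CxxxC")[sel$s],
             cpcc_flag = sel$cpcc,
             assigned_number = NA_integer_,
             stringsAsFactors = FALSE)
}

# Ungapped sliding-window profile scan; returns all window scores.
slide_pssm <- function(aa, pssm) {
  v <- enc_aa(aa)
  L <- pssm$length
  n <- length(v)
  if (n < L) return(numeric(0))
  offs <- 0:(n - L)
  cols <- seq_len(L)
  vapply(offs, function(o) sum(pssm$scores[cbind(cols, v[o + cols])]), 0)
}

# best non-overlapping windows scoring >= thr, greedy by score
profile_hits <- function(aa, pssm, thr) {
  sc <- slide_pssm(aa, pssm)
  idx <- which(sc >= thr)
  if (!length(idx))
    return(data.frame(start = integer(), end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  idx <- idx[order(-sc[idx])]
  L <- pssm$length
  chosen <- integer(0)
  for (i in idx) {
    if (!any(abs(chosen - i) < L)) chosen <- c(chosen, i)
  }
  chosen <- sort(chosen)
  data.frame(start = chosen - 1L, end = chosen - 1L + L,
             score = sc[chosen], stringsAsFactors = FALSE)
}

#' Annotate Myb, RLE and thumb-zinc-knuckle domains
#'
#' Each shipped log-odds profile is slid over the protein; windows scoring at
#' least `threshold_frac` of the profile's maximum are reported.  Two or more
#' non-overlapping Myb hits flag a Myb duplication (Myb2) candidate.
#'
#' @param aa protein sequence.
#' @param profiles named list of profiles (defaults to the shipped synthetic
#'   consensi; must contain `MYB`, `RLE`, `KNUCKLE`).
#' @param threshold_frac score threshold as a fraction of each profile's
#'   maximum attainable score.
#' @return list with `mybs` (data frame of hits), `rle` and `knuckle`
#'   (single-row data frame or `NULL`).
#' @export
annotate_myb_and_aux <- function(aa, profiles = default_profiles(),
                                 threshold_frac = 0.55) {
  need <- c("MYB", "RLE", "KNUCKLE")
  if (!all(need %in% names(profiles)))
    stop("profiles must contain MYB, RLE and KNUCKLE", call. = FALSE)
  mybs <- profile_hits(aa, profiles$MYB,
                       threshold_frac * profiles$MYB$max_score)
  one_best <- function(p) {
    h <- profile_hits(aa, p, threshold_frac * p$max_score)
    if (nrow(h) == 0L) NULL else h[which.max(h$score), , drop = FALSE]
  }
  list(mybs = mybs, rle = one_best(profiles$RLE),
       knuckle = one_best(profiles$KNUCKLE))
}

#' Annotate reverse-transcriptase motifs 0-7
#'
#' Motifs are located independently by profile scan; the RT is `intact` when
#' all eight are found in increasing coordinate order with scores at
#' threshold ("apparently intact RT motifs").
#'
#' @param aa protein sequence.
#' @param profiles named list containing profiles `RT0`..`RT7`.
#' @param threshold_frac score threshold as a fraction of each profile's
#'   maximum.
#' @return list with `motifs` (data frame: `motif` 0..7, `start`, `end`,
#'   `score`; missing motifs absent) and `intact` (logical).
#' @export
annotate_rt_motifs <- function(aa, profiles = default_profiles(),
                               threshold_frac = 0.55) {
  rows <- list()
  for (m in 0:7) {
    p <- profiles[[paste0("RT", m)]]
    if (is.null(p)) stop("missing profile RT", m, call. = FALSE)
    h <- profile_hits(aa, p, threshold_frac * p$max_score)
    if (nrow(h) == 0L) next
    best <- h[which.max(h$score), , drop = FALSE]
    rows[[length(rows) + 1L]] <- cbind(data.frame(motif = m), best)
  }
  motifs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = integer(), start = integer(), end = integer(),
               score = numeric(), stringsAsFactors = FALSE)
  rownames(motifs) <- NULL
  intact <- nrow(motifs) == 8L && !is.unsorted(motifs$start, strictly = TRUE)
  list(motifs = motifs, intact = intact)
}

#' Classify the N-terminal domain architecture
#'
#' Only fingers N-terminal to the first Myb are numbered, starting at the
#' finger nearest the Myb (ZnF1) and increasing toward the N terminus.  The
#' label follows the clade definitions: 3 fingers = A, 1 = D (D+Myb2 with a
#' duplicated Myb), 4 = 4ZnF, no Myb = no-Myb.  For exactly two fingers the
#' more N-terminal finger's pair type disambiguates: CCHC means ZnF2 is
#' retained (label B), CCHH means ZnF3 (label C) -- a sequence-evidence
#' convention, since clade B/C labels are historically phylogenetic.
#' `cofold_znf32_plausible` is a linker-length heuristic for the
#' interdependently folded ZnF3:2 pair of lineage-A proteins: true when both
#' fingers are present and separated by at most `max_linker` residues (it is
#' never a structural result).
#'
#' @param znfs data frame from [annotate_znf()].
#' @param mybs data frame of Myb hits from [annotate_myb_and_aux()].
#' @param rt_motifs optional result of [annotate_rt_motifs()].
#' @param rle,knuckle optional single-row hit data frames.
#' @param max_linker maximum ZnF3-ZnF2 linker (aa) for the co-fold heuristic.
#' @return an object of class `r2_architecture`: list with `znfs` (numbered),
#'   `mybs`, `rt_motifs`, `rle`, `knuckle`, `label`,
#'   `cofold_znf32_plausible`.
#' @export
classify_architecture <- function(znfs, mybs, rt_motifs = NULL, rle = NULL,
                                  knuckle = NULL, max_linker = 10L) {
  label <- "other"
  cofold <- NA
  if (is.null(mybs) || nrow(mybs) == 0L) {
    label <- "no-Myb"
  } else {
    first_myb <- min(mybs$start)
    nterm <- znfs[znfs$end <= first_myb, , drop = FALSE]
    if (nrow(nterm) > 0L) {
      # number from the finger nearest the Myb toward the N terminus
      o <- order(-nterm$start)
      nterm$assigned_number[o] <- seq_len(nrow(nterm))
      znfs[match(rownames(nterm), rownames(znfs)), "assigned_number"] <-
        nterm$assigned_number
    }
    nz <- nrow(nterm)
    label <- if (nz == 3L) "A"
      else if (nz == 4L) "4ZnF"
      else if (nz == 1L) { if (nrow(mybs) >= 2L) "D+Myb2" else "D" }
      else if (nz == 2L) {
        nt_finger <- nterm[which.min(nterm$start), , drop = FALSE]
        if (nt_finger$pair_type == "CCHC") "B" else "C"
      } else "other"
    z3 <- znfs[!is.na(znfs$assigned_number) & znfs$assigned_number == 3L, ,
               drop = FALSE]
    z2 <- znfs[!is.na(znfs$assigned_number) & znfs$assigned_number == 2L, ,
               drop = FALSE]
    if (nrow(z3) == 1L && nrow(z2) == 1L)
      cofold <- (z2$start - z3$end) <= max_linker
  }
  structure(list(znfs = znfs, mybs = mybs, rt_motifs = rt_motifs, rle = rle,
                 knuckle = knuckle, label = label,
                 cofold_znf32_plausible = cofold),
            class = "r2_architecture")
}

#' Annotate a protein end-to-end
#'
#' Convenience wrapper running the zinc-finger grammar, the Myb/RLE/knuckle
#' and RT-motif profile scans, and the architecture classifier.
#'
#' @param aa protein sequence.
#' @param profiles profile list (shipped defaults).
#' @param threshold_frac profile score threshold fraction.
#' @param max_linker co-fold heuristic linker cap (aa).
#' @return an `r2_architecture` (see [classify_architecture()]) whose
#'   `rt_motifs` field carries the RT scan including `intact`.
#' @export
annotate_protein <- function(aa, profiles = default_profiles(),
                             threshold_frac = 0.55, max_linker = 10L) {
  znfs <- annotate_znf(aa)
  aux <- annotate_myb_and_aux(aa, profiles, threshold_frac)
  rt <- annotate_rt_motifs(aa, profiles, threshold_frac)
  classify_architecture(znfs, aux$mybs, rt_motifs = rt, rle = aux$rle,
                        knuckle = aux$knuckle, max_linker = max_linker)
}

#' Trim an ORF 10 residues N-terminal of the most N-terminal zinc finger
#'
#' Returns the suffix of the protein beginning 10 amino acids before the most
#' N-terminal ZnF (clamped at the sequence start); without any ZnF the input
#' is returned unchanged with a warning flag.
#'
#' @param aa protein sequence (or an ORF record's `aa_seq`).
#' @param znfs data frame from [annotate_znf()].
#' @param margin_aa residues kept N-terminal of the first finger.
#' @return list with `aa` (trimmed sequence), `offset` (0-based start of the
#'   trim in the input) and `trimmed` (`FALSE` when no ZnF was present).
#' @export
trim_n_terminus <- function(aa, znfs, margin_aa = 10L) {
  if (is.null(znfs) || nrow(znfs) == 0L)
    return(list(aa = aa, offset = 0L, trimmed = FALSE))
  from <- max(0L, min(znfs$start) - margin_aa)
  list(aa = substring(aa, from + 1L), offset = from, trimmed = TRUE)
}
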