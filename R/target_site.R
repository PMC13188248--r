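# Target-site junction analysis: align the flanks of a candidate element to
# the 28S reference, locate the junction coordinates, measure the offset from
# the canonical nick site, and classify the element.

#' Classify the 28S junctions of a candidate element
#'
#' The `window` nucleotides upstream and downstream of the candidate interval
#' are locally aligned to the 28S reference.  A flank matches when its
#' identity is at least `min_identity` over at least `min_span` aligned
#' nucleotides and the alignment reaches the junction side of the flank
#' (within `junction_slack` nt, extrapolated).  Completeness follows R2
#' biology: both flanks matching = full-length; only the downstream (3')
#' flank = 5'-truncated; otherwise no rDNA flanks.
#'
#' @param start,end candidate interval, 0-based half-open on the contig.
#' @param contig contig sequence (single string).
#' @param rdna an [make_reference_rdna()] object (or any list with `seq` and
#'   `nick_pos`).
#' @param strand candidate strand; for `-` the element's 5' flank is the
#'   downstream contig flank (reverse-complemented before alignment is not
#'   needed because offsets are measured on the rDNA forward strand).
#' @param window flank length examined (nt).
#' @param min_identity minimum flank identity.
#' @param min_span minimum aligned span (nt).
#' @param junction_slack how far from the flank's junction end the alignment
#'   may stop and still be extrapolated to a junction coordinate.
#' @param scoring nucleotide [scoring_scheme()].
#' @return an object of class `r2_target_site`: list with
#'   `up_flank_identity`, `down_flank_identity`, `up_junction_pos`,
#'   `down_junction_pos` (0-based 28S coordinates or `NA`), `nick_offset`
#'   (signed nt or `NA`; negative = upstream of the canonical nick) and
#'   `completeness` (`"full-length"`, `"5prime-truncated"`,
#'   `"no-rdna-flanks"`).
#' @export
classify_junctions <- function(start, end, contig, rdna, strand = "+",
                               window = 200L, min_identity = 0.80,
                               min_span = 50L, junction_slack = 5L,
                               scoring = scoring_scheme()) {
  if (!(window >= min_span && min_span >= 20L))
    stop("need window >= min_span >= 20", call. = FALSE)
  L <- nchar(contig)
  stopifnot(start >= 0, end <= L, start < end)

  up_seq <- if (start > 0) substr(contig, max(0L, start - window) + 1L, start)
            else ""
  down_seq <- if (end < L) substr(contig, end + 1L, min(L, end + window))
              else ""

  eval_flank <- function(fl, side) {
    if (nchar(fl) < min_span)
      return(list(identity = NA_real_, junction = NA_integer_))
    al <- local_align(fl, rdna$seq, scoring)
    span <- al$q_end - al$q_start
    if (span < min_span || is.na(al$identity) || al$identity < min_identity)
      return(list(identity = al$identity, junction = NA_integer_))
    if (side == "up") {
      # junction = 28S coordinate abutting the element start
      tail_gap <- nchar(fl) - al$q_end
      if (tail_gap > junction_slack)
        return(list(identity = al$identity, junction = NA_integer_))
      list(identity = al$identity, junction = al$s_end + tail_gap)
    } else {
      head_gap <- al$q_start
      if (head_gap > junction_slack)
        return(list(identity = al$identity, junction = NA_integer_))
      list(identity = al$identity, junction = al$s_start - head_gap)
    }
  }

  # the element's 5' side is upstream on '+' and downstream on '-'
  if (strand == "+") {
    up <- eval_flank(up_seq, "up")
    down <- eval_flank(down_seq, "down")
  } else {
    up <- eval_flank(up_seq, "up")
    down <- eval_flank(down_seq, "down")
    # offsets stay on the rDNA forward strand; the 5'/3' roles swap
    tmp <- up; up <- down; down <- tmp
    # after swapping, "up" holds the element-5'-side junction info, but the
    # junction coordinates above were computed on the contig forward strand,
    # which is what the completeness rule needs: the element 5' flank is the
    # downstream contig flank on '-'
  }

  completeness <- if (!is.na(up$junction) && !is.na(down$junction))
    "full-length"
  else if (is.na(up$junction) && !is.na(down$junction))
    "5prime-truncated"
  else "no-rdna-flanks"

  call <- structure(list(up_flank_identity = up$identity,
                         down_flank_identity = down$identity,
                         up_junction_pos = up$junction,
                         down_junction_pos = down$junction,
                         nick_offset = NA_integer_,
                         completeness = completeness),
                    class = "r2_target_site")
  call$nick_offset <- nick_offset(call, rdna)
  call
}

#' Offset of an element's junction from the canonical nick site
#'
#' Measured on the rDNA forward strand; negative offsets place the element
#' upstream of the canonical nick.  Uses the 5' junction when located, else
#' the 3' junction (the typical situation for 5'-truncated copies).
#'
#' @param call an `r2_target_site` from [classify_junctions()].
#' @param rdna the rDNA reference.
#' @return signed integer offset in nt, or `NA` when no junction was located.
#' @export
nick_offset <- function(call, rdna) {
  if (!is.na(call$up_junction_pos))
    return(as.integer(call$up_junction_pos - rdna$nick_pos))
  if (!is.na(call$down_junction_pos))
    return(as.integer(call$down_junction_pos - rdna$nick_pos))
  NA_integer_
}

#' Classify an element from its target site and domain architecture
#'
#' A Myb-bearing element with rDNA flanks is a site-specific R2; Myb without
#' rDNA flanks marks the non-site-specific R2 homologs; absence of the
#' hallmark R2 Myb domain marks Utopia-like elements; candidates without a
#' usable ORF stay unclassified.
#'
#' @param call an `r2_target_site` from [classify_junctions()].
#' @param arch a `DomainArchitecture` from [classify_architecture()] (or
#'   [annotate_protein()]).
#' @param orf_ok logical; `FALSE` when no ORF could be extracted.
#' @return one of `"R2-site-specific"`, `"R2-homolog-non-site-specific"`,
#'   `"Utopia-like"`, `"unclassified"`.
#' @export
classify_element <- function(call, arch, orf_ok = TRUE) {
  if (!isTRUE(orf_ok)) return("unclassified")
  has_myb <- !is.null(arch$mybs) && nrow(arch$mybs) >= 1L
  if (!has_myb) return("Utopia-like")
  if (call$completeness != "no-rdna-flanks") "R2-site-specific"
  else "R2-homolog-non-site-specific"
}
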