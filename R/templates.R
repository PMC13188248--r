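# Motif templates and the derived single-sequence log-odds profiles used by
# the domain detectors.  Templates ship as an editable plain-text file under
# inst/extdata; the generator and the detectors share them, so clean synthetic
# elements are detectable by construction.

motif_templates <- function(path = NULL) {
  key <- if (is.null(path)) "templates_default" else paste0("templates_", path)
  if (!is.null(.r2_cache[[key]])) return(.r2_cache[[key]])
  if (is.null(path))
    path <- system.file("extdata", "motif_templates.tsv", package = "r2scout")
  if (!file.exists(path))
    stop("motif template file not found: ", path, call. = FALSE)
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    col.names = c("motif", "seq"), stringsAsFactors = FALSE)
  out <- setNames(toupper(tab$seq), tab$motif)
  .r2_cache[[key]] <- out
  out
}

# Assemble one zinc-finger template from the grammar
#   C x(s) C x(8-14) H x(3-5) [H|C]
# `variant` fixes the first cysteine-pair spacing; `pair_type` the final
# coordinating residue (CCHH or CCHC).
znf_template <- function(pair_type = c("CCHH", "CCHC"),
                         variant = c("CxxC", "CxC", "CxxxC", "CPCC")) {
  pair_type <- match.arg(pair_type)
  variant <- match.arg(variant)
  tpl <- motif_templates()
  spacer <- switch(variant, CxC = "P", CxxC = "PI", CxxxC = "PIE", CPCC = "PC")
  last <- if (pair_type == "CCHH") "H" else "C"
  paste0("C", spacer, "C", tpl[["ZNF_MID"]], "H", tpl[["ZNF_TAIL"]], last)
}

# Single-sequence half-bit profiles for the sliding-window detectors.
default_profiles <- function() {
  if (!is.null(.r2_cache$profiles)) return(.r2_cache$profiles)
  tpl <- motif_templates()
  want <- c("MYB", "RLE", "KNUCKLE", paste0("RT", 0:7))
  missing <- setdiff(want, names(tpl))
  if (length(missing))
    stop("profile templates missing from template file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  prof <- lapply(tpl[want], function(s) build_pssm(s))
  .r2_cache$profiles <- prof
  prof
}

# Deterministic construction of the two synthetic lineage reference RT
# domains: shared motif templates, lineage-specific linkers drawn from fixed
# lineage seeds.  The shipped FASTA is generated by exactly this routine;
# make_element() reuses the linkers so elements carry their lineage's RT
# signature.
.LINEAGE_RT_SEED <- c(A = 1011L, D = 2022L)

synthetic_rt_reference <- function(lineage = c("A", "D")) {
  lineage <- match.arg(lineage)
  key <- paste0("rtref_", lineage)
  if (!is.null(.r2_cache[[key]])) return(.r2_cache[[key]])
  tpl <- motif_templates()
  out <- with_seed(.LINEAGE_RT_SEED[[lineage]], {
    lead <- random_linker(12L)
    linkers <- character(8L)
    parts <- lead
    for (m in 0:7) {
      linkers[m + 1L] <- random_linker(22L)
      parts <- c(parts, tpl[[paste0("RT", m)]], linkers[m + 1L])
    }
    list(seq = paste(parts, collapse = ""), lead = lead, linkers = linkers)
  })
  .r2_cache[[key]] <- out
  out
}

#' Shipped synthetic lineage reference RT sequences
#'
#' Returns the two reference reverse-transcriptase domain sequences used as
#' the lineage-A and lineage-D anchors of the PSSM placement.  These are
#' synthetic stand-ins built from the package's own RT motif templates with
#' lineage-specific linkers (the biologically characterised anchor proteins
#' are external data); users with curated references can pass their own
#' sequences to [lineage_placement()].
#'
#' @return named character vector with elements `A` and `D`.
#' @export
lineage_reference_rts <- function() {
  path <- system.file("extdata", "synthetic_rt_refs.fasta", package = "r2scout")
  set <- as_seqset(path, "aa")
  stopifnot(all(c("lineageA_synthetic", "lineageD_synthetic") %in% names(set)))
  c(A = unname(set[["lineageA_synthetic"]]),
    D = unname(set[["lineageD_synthetic"]]))
}
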