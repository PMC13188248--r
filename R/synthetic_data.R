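# Synthetic-data generator: rDNA references, R2-like elements with known
# domain architecture, genomes with ground-truth insertion tables, sequencing
# reads, and tree-evolved protein families.  Every stochastic operation takes
# its own integer seed and is bit-reproducible.

.ARCH_LABELS <- c("A", "B", "C", "D", "D+Myb2", "4ZnF", "no-Myb")
.ZNF_VARIANTS <- c("CxC", "CxxC", "CxxxC", "CPCC")

arch_fingers <- function(arch_label) {
  switch(arch_label,
         "A" = c(3L, 2L, 1L),
         "B" = c(2L, 1L),
         "C" = c(3L, 1L),
         "D" = 1L,
         "D+Myb2" = 1L,
         "4ZnF" = c(4L, 3L, 2L, 1L),
         "no-Myb" = 1L,
         stop("unknown architecture label: ", arch_label, call. = FALSE))
}

#' Specify one synthetic element
#'
#' An element specification fixes the N-terminal domain architecture
#' (which zinc fingers and how many Myb domains the protein carries), the
#' first-cysteine-pair spacing variant of each finger, the reverse-
#' transcriptase lineage the element descends from, and how it is planted in
#' the genome (offset from the canonical 28S nick site, 5' truncation,
#' site specificity).
#'
#' @param arch_label one of `"A"`, `"B"`, `"C"`, `"D"`, `"D+Myb2"`, `"4ZnF"`,
#'   `"no-Myb"` (clade A = ZnF3+ZnF2+ZnF1, D = ZnF1 only, and so on; `no-Myb`
#'   emulates Utopia-like elements).
#' @param znf_variants named character vector mapping finger number
#'   (`"1"`..`"4"`) to a first-pair spacing variant (`"CxC"`, `"CxxC"`,
#'   `"CxxxC"`, `"CPCC"`). Fingers not named use `"CxxC"`.
#' @param lineage `"A"` or `"D"`: which lineage reference the RT linkers are
#'   drawn from.
#' @param orf_len_aa total ORF length in amino acids (templates plus random
#'   linkers).
#' @param utr5_len,utr3_len untranslated flank lengths in nucleotides.
#' @param insertion_offset signed offset (nt) of the element 5' junction from
#'   the canonical nick position; negative = upstream.
#' @param truncate5_nt how many nucleotides to remove from the element 5' end
#'   when planting (emulating 5'-truncated TPRT copies).
#' @param site_specific logical; `FALSE` plants the element in random
#'   non-rDNA sequence (non-site-specific homolog). `no-Myb` elements are
#'   always planted at the U2-like locus.
#' @return an object of class `r2_element_spec`.
#' @export
element_spec <- function(arch_label = "D", znf_variants = NULL, lineage = "D",
                         orf_len_aa = 1100L, utr5_len = 250L, utr3_len = 150L,
                         insertion_offset = 0L, truncate5_nt = 0L,
                         site_specific = TRUE) {
  arch_label <- match.arg(arch_label, .ARCH_LABELS)
  lineage <- match.arg(lineage, c("A", "D"))
  fingers <- arch_fingers(arch_label)
  if (!is.null(znf_variants)) {
    if (is.null(names(znf_variants)) ||
        !all(names(znf_variants) %in% as.character(fingers)))
      stop("znf_variants names must be finger numbers present in '",
           arch_label, "' (", paste(fingers, collapse = ","), ")",
           call. = FALSE)
    if (!all(znf_variants %in% .ZNF_VARIANTS))
      stop("znf_variants values must be one of: ",
           paste(.ZNF_VARIANTS, collapse = ", "), call. = FALSE)
  }
  if (orf_len_aa < 0) stop("orf_len_aa must be >= 0", call. = FALSE)
  if (truncate5_nt < 0) stop("truncate5_nt must be >= 0", call. = FALSE)
  structure(list(arch_label = arch_label,
                 znf_variants = znf_variants,
                 lineage = lineage,
                 orf_len_aa = as.integer(orf_len_aa),
                 utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len),
                 insertion_offset = as.integer(insertion_offset),
                 truncate5_nt = as.integer(truncate5_nt),
                 site_specific = isTRUE(site_specific)),
            class = "r2_element_spec")
}

#' Generate a synthetic 28S rDNA reference with an annotated nick position
#'
#' The reference stands in for the conserved 28S target locus: one rDNA unit
#' is laid out from `unit_layout`, and `nick_pos` marks the canonical
#' first-strand nick offset within the 28S-like segment (the position all
#' insertion offsets are measured from).
#'
#' @param seed integer seed.
#' @param unit_layout named integer vector of segment lengths for one rDNA
#'   unit; exactly one name must contain `"28S"`.
#' @param nick_pos 0-based offset of the canonical nick within the 28S-like
#'   segment.
#' @return an object of class `r2_rdna_ref` with fields `seq` (the 28S-like
#'   sequence), `nick_pos`, `unit_layout`, `segments`, `unit_seq` and
#'   `nick_unit_pos` (nick offset within the whole unit).
#' @export
make_reference_rdna <- function(seed = 1L,
                                unit_layout = c("18S-like" = 1800L,
                                                "ITS-like" = 700L,
                                                "28S-like" = 3800L),
                                nick_pos = 1900L) {
  if (any(unit_layout <= 0)) stop("all unit_layout lengths must be > 0",
                                  call. = FALSE)
  i28 <- grep("28S", names(unit_layout))
  if (length(i28) != 1L)
    stop("unit_layout must contain exactly one segment named like '28S'",
         call. = FALSE)
  len28 <- unit_layout[[i28]]
  if (!(nick_pos > 0 && nick_pos < len28))
    stop("nick_pos must lie strictly inside the 28S-like segment (0 < nick_pos < ",
         len28, ")", call. = FALSE)
  segments <- with_seed(seed, lapply(unit_layout, random_dna))
  unit_seq <- paste(unlist(segments), collapse = "")
  off28 <- if (i28 > 1) sum(unit_layout[seq_len(i28 - 1L)]) else 0L
  structure(list(seq = segments[[i28]],
                 nick_pos = as.integer(nick_pos),
                 unit_layout = unit_layout,
                 segments = segments,
                 unit_seq = unit_seq,
                 nick_unit_pos = as.integer(off28 + nick_pos)),
            class = "r2_rdna_ref")
}

# deterministic per-item seed derivation from a single top-level seed
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 69069 + i * 7919) %% 2147483647)
}

.LINKER_AA <- setdiff(.AA, c("C", "H"))

random_linker <- function(n) {
  if (n <= 0) return("")
  paste(sample(.LINKER_AA, n, replace = TRUE), collapse = "")
}

# mutate a protein stretch under the equal-rates jump process at distance t,
# restricted to an alphabet (linkers stay C/H-free so the zinc-finger
# grammar cannot fire inside them); uses the caller's RNG stream
mutate_aa <- function(aa, t, alphabet = .LINKER_AA) {
  if (t <= 0 || !nzchar(aa)) return(aa)
  ch <- strsplit(aa, "", fixed = TRUE)[[1L]]
  hit <- rpois(length(ch), t) > 0L
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(alphabet, a), 1L), "")
  paste(ch, collapse = "")
}

codon_table <- function() {
  if (!is.null(.r2_cache$codons)) return(.r2_cache$codons)
  gc <- Biostrings::GENETIC_CODE
  syn <- split(names(gc), gc)
  syn[["*"]] <- NULL
  .r2_cache$codons <- syn
  syn
}

reverse_translate <- function(aa) {
  syn <- codon_table()
  res <- strsplit(aa, "", fixed = TRUE)[[1L]]
  paste(vapply(res, function(a) {
    cc <- syn[[a]]
    if (is.null(cc)) stop("cannot reverse-translate residue: ", a, call. = FALSE)
    cc[sample.int(length(cc), 1L)]
  }, ""), collapse = "")
}

#' Build one synthetic element (protein and nucleotide sequence)
#'
#' The protein concatenates the motif templates the architecture calls for
#' (zinc fingers N-to-C by decreasing number, Myb -- duplicated for
#' `D+Myb2` -- then RT motifs 0..7 in order, the RLE endonuclease and the
#' thumb-zinc-knuckle) joined by random linkers that pad the ORF to
#' `orf_len_aa`.  The nucleotide sequence is a randomised synonymous-codon
#' reverse translation flanked by UTRs; the reading frame is bracketed by
#' in-frame stops so the ORF is a maximal stop-free stretch, and it does not
#' start with a methionine (R2 ORFs are non-canonically translated).
#'
#' @param spec an [element_spec()].
#' @param seed integer seed.
#' @param cofold_linker_aa linker length between ZnF3 and ZnF2 (short by
#'   default so the co-folding heuristic calls lineage-A style fingers
#'   plausible).
#' @param znf_linker_aa linker length between other consecutive fingers.
#' @param rt_linker_divergence expected substitutions per site applied to the
#'   lineage reference's RT inter-motif linkers (the element's lineage
#'   signature; motif residues stay exact).
#' @return list with `protein`, `element_nt`, `domains` (ground-truth domain
#'   coordinate table, 0-based half-open on the protein) and `spec`.
#' @export
make_element <- function(spec, seed = 1L, cofold_linker_aa = 6L,
                         znf_linker_aa = 12L, rt_linker_divergence = 0.2) {
  stopifnot(inherits(spec, "r2_element_spec"))
  tpl <- motif_templates()
  fingers <- arch_fingers(spec$arch_label)
  variant_of <- function(f) {
    v <- spec$znf_variants[as.character(f)]
    if (length(v) == 0L || is.na(v)) "CxxC" else unname(v)
  }
  with_seed(seed, {
    parts <- list()   # list of c(name, seq, is_domain)
    add <- function(name, s, domain = TRUE)
      parts[[length(parts) + 1L]] <<- list(name = name, seq = s,
                                           domain = domain)
    add("linker", random_linker(15L), domain = FALSE)
    for (idx in seq_along(fingers)) {
      f <- fingers[idx]
      pair <- if (f == 2L) "CCHC" else "CCHH"
      add(paste0("ZnF", f), znf_template(pair, variant_of(f)))
      gap <- if (f == 3L && idx < length(fingers) && fingers[idx + 1L] == 2L)
        cofold_linker_aa else znf_linker_aa
      add("linker", random_linker(gap), domain = FALSE)
    }
    if (spec$arch_label != "no-Myb") {
      add("Myb", tpl[["MYB"]])
      if (spec$arch_label == "D+Myb2") {
        add("linker", random_linker(8L), domain = FALSE)
        add("Myb2", tpl[["MYB"]])
      }
    }
    add("linker", random_linker(20L), domain = FALSE)
    # RT inter-motif linkers descend from the element's lineage reference
    # (lightly diverged), so the PSSM placement has a recoverable signal
    rtref <- synthetic_rt_reference(spec$lineage)
    for (m in 0:7) {
      add(paste0("RT", m), tpl[[paste0("RT", m)]])
      add("linker", mutate_aa(rtref$linkers[m + 1L], rt_linker_divergence),
          domain = FALSE)
    }
    add("RLE", tpl[["RLE"]])
    add("linker", random_linker(10L), domain = FALSE)
    add("KNUCKLE", tpl[["KNUCKLE"]])

    base_len <- sum(vapply(parts, function(p) nchar(p$seq), 0L))
    filler <- spec$orf_len_aa - base_len
    if (filler < 0)
      stop("orf_len_aa (", spec$orf_len_aa,
           ") smaller than the sum of template lengths (", base_len, ")",
           call. = FALSE)
    # split the padding between a mid-protein spacer (after the Myb block,
    # before RT0) and a C-terminal tail
    mid <- sample.int(filler + 1L, 1L) - 1L
    insert_at <- which(vapply(parts, function(p) p$name == "RT0", TRUE))[1L]
    parts <- append(parts, list(list(name = "linker",
                                     seq = random_linker(mid),
                                     domain = FALSE)),
                    after = insert_at - 1L)
    add("linker", random_linker(filler - mid), domain = FALSE)

    protein <- paste(vapply(parts, `[[`, "", "seq"), collapse = "")
    pos <- 0L
    dom <- list()
    for (p in parts) {
      w <- nchar(p$seq)
      if (p$domain && w > 0L)
        dom[[length(dom) + 1L]] <- data.frame(domain = p$name, start = pos,
                                              end = pos + w,
                                              stringsAsFactors = FALSE)
      pos <- pos + w
    }
    domains <- do.call(rbind, dom)

    orf_nt <- reverse_translate(protein)
    utr5 <- if (spec$utr5_len > 0) random_dna(spec$utr5_len) else ""
    utr3 <- if (spec$utr3_len > 0) random_dna(spec$utr3_len) else ""
    if (spec$utr5_len >= 3L)
      substr(utr5, spec$utr5_len - 2L, spec$utr5_len) <- "TAA"
    if (spec$utr3_len >= 3L)
      substr(utr3, 1L, 3L) <- "TAA"
    list(protein = protein,
         element_nt = paste0(utr5, orf_nt, utr3),
         domains = domains,
         spec = spec)
  })
}

#' Build a synthetic genome with a ground-truth element table
#'
#' Lays out a tandem rDNA array of `n_rdna_units` identical units and plants
#' each site-specific element at `nick_pos + insertion_offset` of a distinct
#' unit.  5'-truncated elements lose their first `truncate5_nt` nucleotides
#' and receive a random junk spacer upstream (the spacer's terminal base is
#' drawn to differ from the removed element base, so the truncation
#' breakpoint is sequence-unambiguous).  `no-Myb` (Utopia-like) elements are
#' planted at a separate U2-like repeat locus, and non-site-specific
#' homologs in random downstream sequence.  An optional misassembly mode
#' splits the last site-specific element across two contigs with chimeric
#' junction sequence.
#'
#' @param specs list of [element_spec()] objects.
#' @param n_rdna_units number of tandem rDNA units.
#' @param seed integer seed.
#' @param rdna an [make_reference_rdna()] object (a default is generated from
#'   `seed` if omitted).
#' @param misassemble logical; split one element across two contigs.
#' @param junk_len length of the junk spacer upstream of truncated elements.
#' @return list with `contigs` (named character vector), `truth` (data frame:
#'   `contig_id`, `start`, `end` 0-based half-open, `strand`, `element_id`,
#'   `class`, `arch_label`, `lineage`, `insertion_offset`, `truncate5_nt`,
#'   `split`), `elements` (planted sequences by element id), `proteins`,
#'   and `rdna`.
#' @export
build_genome_and_truth <- function(specs, n_rdna_units, seed = 1L,
                                   rdna = NULL, misassemble = FALSE,
                                   junk_len = 150L) {
  if (inherits(specs, "r2_element_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "r2_element_spec")))
  if (is.null(rdna)) rdna <- make_reference_rdna(seed = derive_seed(seed, 0L))
  kind <- vapply(specs, function(s) {
    if (s$arch_label == "no-Myb") "utopia"
    else if (s$site_specific) "rdna" else "random"
  }, "")
  n_site <- sum(kind == "rdna")
  if (n_site > n_rdna_units)
    stop("more site-specific elements (", n_site, ") than rDNA units (",
         n_rdna_units, ")", call. = FALSE)

  built <- lapply(seq_along(specs), function(i)
    make_element(specs[[i]], seed = derive_seed(seed, i)))
  ids <- sprintf("elem_%02d", seq_along(specs))
  class_of <- c(rdna = "R2-site-specific", utopia = "Utopia-like",
                random = "R2-homolog-non-site-specific")

  with_seed(derive_seed(seed, 999999L), {
    units <- rep(rdna$unit_seq, n_rdna_units)
    unit_pick <- sort(sample.int(n_rdna_units, n_site))
    site_idx <- which(kind == "rdna")

    truth <- list()
    planted <- character(length(specs))
    # place site-specific elements within their units; record offsets within
    # the unit, convert to contig coordinates when concatenating
    unit_ins <- vector("list", n_rdna_units)
    for (j in seq_along(site_idx)) {
      i <- site_idx[j]
      sp <- specs[[i]]
      el <- built[[i]]$element_nt
      p <- rdna$nick_unit_pos + sp$insertion_offset
      if (p <= 0 || p >= nchar(rdna$unit_seq))
        stop("insertion_offset places element outside the rDNA unit",
             call. = FALSE)
      body <- el
      junk <- ""
      if (sp$truncate5_nt > 0L) {
        if (sp$truncate5_nt >= nchar(el))
          stop("truncate5_nt removes the whole element", call. = FALSE)
        removed_last <- substr(el, sp$truncate5_nt, sp$truncate5_nt)
        body <- substring(el, sp$truncate5_nt + 1L)
        junk <- random_dna(junk_len)
        # keep the breakpoint unambiguous under local alignment
        alt <- setdiff(c("A", "C", "G", "T"), removed_last)
        substr(junk, junk_len, junk_len) <- sample(alt, 1L)
      }
      unit_ins[[unit_pick[j]]] <- list(i = i, p = p, junk = junk, body = body)
      planted[i] <- body
    }

    pad5 <- random_dna(500L)
    contig <- pad5
    for (u in seq_len(n_rdna_units)) {
      ins <- unit_ins[[u]]
      if (is.null(ins)) {
        contig <- paste0(contig, units[u])
      } else {
        start0 <- nchar(contig) + ins$p + nchar(ins$junk)
        truth[[length(truth) + 1L]] <- data.frame(
          contig_id = "contig_1", start = start0,
          end = start0 + nchar(ins$body), strand = "+",
          element_id = ids[ins$i], class = class_of[["rdna"]],
          arch_label = specs[[ins$i]]$arch_label,
          lineage = specs[[ins$i]]$lineage,
          insertion_offset = specs[[ins$i]]$insertion_offset,
          truncate5_nt = specs[[ins$i]]$truncate5_nt,
          split = FALSE, stringsAsFactors = FALSE)
        contig <- paste0(contig, substr(units[u], 1L, ins$p), ins$junk,
                         ins$body,
                         substring(units[u], ins$p + 1L))
      }
    }

    # U2-like locus hosting Utopia-like (Myb-less) elements
    u2_repeat <- random_dna(190L)
    contig <- paste0(contig, random_dna(800L), u2_repeat)
    for (i in which(kind == "utopia")) {
      body <- built[[i]]$element_nt
      start0 <- nchar(contig)
      truth[[length(truth) + 1L]] <- data.frame(
        contig_id = "contig_1", start = start0, end = start0 + nchar(body),
        strand = "+", element_id = ids[i], class = class_of[["utopia"]],
        arch_label = specs[[i]]$arch_label, lineage = specs[[i]]$lineage,
        insertion_offset = NA_integer_, truncate5_nt = specs[[i]]$truncate5_nt,
        split = FALSE, stringsAsFactors = FALSE)
      planted[i] <- body
      contig <- paste0(contig, body, u2_repeat)
    }

    # non-site-specific homologs in random sequence with variable flanks
    for (i in which(kind == "random")) {
      body <- built[[i]]$element_nt
      contig <- paste0(contig, random_dna(300L + sample.int(200L, 1L)))
      start0 <- nchar(contig)
      truth[[length(truth) + 1L]] <- data.frame(
        contig_id = "contig_1", start = start0, end = start0 + nchar(body),
        strand = "+", element_id = ids[i], class = class_of[["random"]],
        arch_label = specs[[i]]$arch_label, lineage = specs[[i]]$lineage,
        insertion_offset = NA_integer_, truncate5_nt = specs[[i]]$truncate5_nt,
        split = FALSE, stringsAsFactors = FALSE)
      planted[i] <- body
      contig <- paste0(contig, body)
    }
    contig <- paste0(contig, random_dna(500L))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(contig_id = character(), start = integer(), end = integer(),
                 strand = character(), element_id = character(),
                 class = character(), arch_label = character(),
                 lineage = character(), insertion_offset = integer(),
                 truncate5_nt = integer(), split = logical(),
                 stringsAsFactors = FALSE)

    contigs <- c(contig_1 = contig)
    if (isTRUE(misassemble) && any(truth$class == "R2-site-specific")) {
      row <- tail(which(truth$class == "R2-site-specific"), 1L)
      cut <- as.integer(floor((truth$start[row] + truth$end[row]) / 2))
      chimA <- random_dna(400L)
      chimB <- random_dna(400L)
      contigs <- c(contig_1 = paste0(substr(contig, 1L, cut), chimA),
                   contig_2 = paste0(chimB, substring(contig, cut + 1L)))
      after <- truth$start >= cut
      newrow <- truth[row, ]
      truth$end[row] <- cut
      truth$split[row] <- TRUE
      newrow$contig_id <- "contig_2"
      newrow$start <- 400L
      newrow$end <- 400L + (newrow$end - cut)
      newrow$split <- TRUE
      shift <- after & seq_len(nrow(truth)) != row
      truth$contig_id[shift] <- "contig_2"
      truth$start[shift] <- truth$start[shift] - cut + 400L
      truth$end[shift] <- truth$end[shift] - cut + 400L
      truth <- rbind(truth, newrow)
      rownames(truth) <- NULL
    }

    list(contigs = contigs, truth = truth,
         elements = setNames(planted, ids),
         proteins = setNames(vapply(built, `[[`, "", "protein"), ids),
         built = setNames(built, ids),
         rdna = rdna)
  })
}

#' Simulate sequencing reads from contigs
#'
#' Reads are sampled uniformly over positions and strands, with per-base
#' substitution and indel error and a flat quality string encoding the error
#' rate.
#'
#' @param contigs named character vector of contig sequences (or the
#'   `contigs` element of [build_genome_and_truth()]).
#' @param mode `"long"` or `"short"` (controls read-length spread only).
#' @param n number of reads.
#' @param mean_len mean read length (nt).
#' @param sub_rate,indel_rate per-base substitution and indel rates, each in
#'   \[0, 0.3\].
#' @param seed integer seed.
#' @param path optional FASTQ output file.
#' @return data frame with columns `id`, `seq`, `qual`, `contig`, `start`,
#'   `end` (0-based half-open source interval), `strand`.
#' @export
simulate_reads <- function(contigs, mode = c("long", "short"), n = 100L,
                           mean_len = 2000L, sub_rate = 0, indel_rate = 0,
                           seed = 1L, path = NULL) {
  mode <- match.arg(mode)
  if (length(contigs) == 0L || all(!nzchar(contigs)))
    stop("empty contigs", call. = FALSE)
  if (sub_rate < 0 || sub_rate > 0.3 || indel_rate < 0 || indel_rate > 0.3)
    stop("error rates must lie in [0, 0.3]", call. = FALSE)
  lens <- nchar(contigs)
  if (mean_len > max(lens))
    stop("mean_len exceeds the longest contig", call. = FALSE)
  sd_len <- if (mode == "long") 0.1 * mean_len else 0.02 * mean_len
  qch <- if (sub_rate + indel_rate <= 0) "I" else
    rawToChar(as.raw(33L + min(40L, as.integer(round(
      -10 * log10(sub_rate + indel_rate))))))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ok <- which(lens >= 50L)
    ci <- ok[sample.int(length(ok), n, replace = TRUE,
                        prob = lens[ok] / sum(lens[ok]))]
    out <- vector("list", n)
    for (r in seq_len(n)) {
      clen <- lens[ci[r]]
      L <- min(clen, max(50L, as.integer(round(rnorm(1, mean_len, sd_len)))))
      s0 <- sample.int(clen - L + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      frag <- substr(contigs[[ci[r]]], s0 + 1L, s0 + L)
      if (strand == "-") frag <- revcomp(frag)
      if (sub_rate > 0 || indel_rate > 0) {
        ch <- strsplit(frag, "", fixed = TRUE)[[1L]]
        u <- runif(length(ch))
        sub <- u < sub_rate
        if (any(sub))
          ch[sub] <- vapply(ch[sub], function(b)
            sample(setdiff(bases, b), 1L), "")
        u2 <- runif(length(ch))
        dele <- u2 < indel_rate / 2
        ins <- u2 >= indel_rate / 2 & u2 < indel_rate
        pieces <- ch
        pieces[dele] <- ""
        if (any(ins))
          pieces[ins] <- paste0(ch[ins], sample(bases, sum(ins),
                                                replace = TRUE))
        frag <- paste(pieces, collapse = "")
      }
      out[[r]] <- data.frame(id = sprintf("read_%04d", r), seq = frag,
                             qual = strrep(qch, nchar(frag)),
                             contig = names(contigs)[ci[r]], start = s0,
                             end = s0 + L, strand = strand,
                             stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, out)
    if (!is.null(path)) write_fastq(reads, path)
    reads
  })
}

#' Evolve a protein along a tree under the equal-rates amino-acid model
#'
#' Sites evolve independently under the 20-state equal-rates (Poisson-style)
#' substitution model, with branch lengths in expected substitutions per site
#' and an optional per-site rate multiplier.  Under this model the identity
#' probability has the closed form `P_same(t) = 1/20 + (19/20) exp(-20 t /
#' 19)`, which the test suite uses as an exact oracle.  No gaps are ever
#' introduced, so the leaves come back aligned.
#'
#' @param root_aa root protein sequence.
#' @param tree newick string or `ape::phylo` with branch lengths (expected
#'   substitutions/site).
#' @param site_rates optional numeric vector of per-site rate multipliers
#'   (length `nchar(root_aa)`).
#' @param alpha optional gamma shape; when given (and `site_rates` is not),
#'   each site draws its rate from `K` equal-probability discrete-gamma
#'   categories with mean 1.
#' @param K number of gamma categories.
#' @param seed integer seed.
#' @return named character vector of leaf sequences, with the realised
#'   per-site rates in `attr(, "site_rates")`.
#' @export
evolve_on_tree <- function(root_aa, tree, site_rates = NULL, alpha = NULL,
                           K = 4L, seed = 1L) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length) || any(phy$edge.length < 0))
    stop("tree must have non-negative branch lengths", call. = FALSE)
  S <- nchar(root_aa)
  if (S < 1L) stop("root sequence must be non-empty", call. = FALSE)
  root_v <- enc_aa(root_aa)
  if (any(root_v > 20L))
    stop("root sequence may not contain X", call. = FALSE)
  with_seed(seed, {
    rates <- if (!is.null(site_rates)) {
      if (length(site_rates) != S)
        stop("site_rates must have one entry per site", call. = FALSE)
      as.numeric(site_rates)
    } else if (!is.null(alpha)) {
      cats <- discrete_gamma(alpha, K)
      cats[sample.int(K, S, replace = TRUE)]
    } else rep(1, S)
    if (any(rates < 0)) stop("site rates must be >= 0", call. = FALSE)

    ntip <- length(phy$tip.label)
    nnode <- ntip + phy$Nnode
    seqs <- matrix(0L, nrow = nnode, ncol = S)
    root <- ntip + 1L
    seqs[root, ] <- root_v
    # cladewise edge order visits every parent before its children
    phy <- stats::reorder(phy, "cladewise")
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      bl <- phy$edge.length[e]
      v <- seqs[par, ]
      njump <- rpois(S, bl * rates)
      hit <- which(njump > 0L)
      if (length(hit)) {
        # distribution after n uniform jumps among the other 19 states:
        # P(return to start) = (1 + 19 (-1/19)^n) / 20
        q <- (1 + 19 * (-1 / 19)^njump[hit]) / 20
        move <- runif(length(hit)) >= q
        if (any(move)) {
          idx <- hit[move]
          v[idx] <- vapply(v[idx], function(s)
            sample.int(20L, 1L, prob = replace(rep(1, 20), s, 0)), 0L)
        }
      }
      seqs[child, ] <- v
    }
    leaves <- vapply(seq_len(ntip), function(i)
      paste(.AA[seqs[i, ]], collapse = ""), "")
    structure(setNames(leaves, phy$tip.label), site_rates = rates)
  })
}

# accept newick text, a file path, or a phylo object
as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    txt <- if (!grepl("[();]", tree) && file.exists(tree))
      paste(readLines(tree, warn = FALSE), collapse = "") else tree
    phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
    if (is.null(phy)) stop("malformed newick tree", call. = FALSE)
    return(phy)
  }
  stop("tree must be a phylo object, newick string, or newick file",
       call. = FALSE)
}
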