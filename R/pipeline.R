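# End-to-end orchestration: discover -> target site -> ORF/domains ->
# lineage -> phylogeny, with standard-format outputs and paper-style summary
# tables (architecture census, completeness counts, lineage co-occurrence).

#' Assemble and validate a pipeline configuration
#'
#' Inputs may be in-memory objects (named character vectors, an
#' `r2_rdna_ref`) or file paths (FASTA/newick).  Unknown parameters are
#' rejected.
#'
#' @param genome contigs: named character vector or FASTA path.
#' @param queries reference element queries: named vector or FASTA path.
#' @param rdna an [make_reference_rdna()] object, or a list with `seq` and
#'   `nick_pos`.
#' @param ref_rt_A,ref_rt_D lineage reference RT sequences (defaults: the
#'   shipped synthetic references).
#' @param host_tree optional host species tree (newick string/path/phylo).
#' @param min_score,merge_max_gap discovery stage parameters.
#' @param min_orf_aa full-length ORF threshold (aa).
#' @param window,min_identity,min_span target-site stage parameters.
#' @param bootstrap_B bootstrap replicates for the element tree (0 = none).
#' @param outgroup optional outgroup taxon for the element tree (an element
#'   id, or a named extra sequence added to the tree stage).
#' @param seed integer seed; all stage randomness derives from it.
#' @param outdir optional output directory; when given, TSV/GFF3/FASTA/
#'   newick/JSON outputs are written.
#' @return an object of class `r2_pipeline_config`.
#' @export
pipeline_config <- function(genome, queries, rdna, ref_rt_A = NULL,
                            ref_rt_D = NULL, host_tree = NULL,
                            min_score = 60, merge_max_gap = 100L,
                            min_orf_aa = 900L, window = 200L,
                            min_identity = 0.80, min_span = 50L,
                            bootstrap_B = 0L, outgroup = NULL, seed = 1L,
                            outdir = NULL) {
  genome <- as_seqset(genome, "dna")
  queries <- as_seqset(queries, "dna")
  if (!is.list(rdna) || is.null(rdna$seq) || is.null(rdna$nick_pos))
    stop("rdna must provide 'seq' and 'nick_pos'", call. = FALSE)
  if (is.null(ref_rt_A) || is.null(ref_rt_D)) {
    refs <- lineage_reference_rts()
    if (is.null(ref_rt_A)) ref_rt_A <- refs[["A"]]
    if (is.null(ref_rt_D)) ref_rt_D <- refs[["D"]]
  }
  structure(list(genome = genome, queries = queries, rdna = rdna,
                 ref_rt_A = ref_rt_A, ref_rt_D = ref_rt_D,
                 host_tree = host_tree, min_score = min_score,
                 merge_max_gap = as.integer(merge_max_gap),
                 min_orf_aa = as.integer(min_orf_aa),
                 window = as.integer(window), min_identity = min_identity,
                 min_span = as.integer(min_span),
                 bootstrap_B = as.integer(bootstrap_B), outgroup = outgroup,
                 seed = as.integer(seed), outdir = outdir),
            class = "r2_pipeline_config")
}

#' Run the curation pipeline end to end
#'
#' Discovery (seeded local alignment + locus merging), target-site junction
#' classification, ORF extraction with domain annotation, element
#' classification, PSSM lineage placement of each element's RT domain, and a
#' bootstrapped NJ tree of the trimmed ORFs.  Deterministic for a fixed
#' config and seed; an empty genome yields an empty element table.
#'
#' @param config an [pipeline_config()].
#' @return an object of class `r2_result_bundle`: list with `elements` (one
#'   row per locus: coordinates, class, completeness, nick offset,
#'   architecture label, lineage call and scores), `orfs` (named trimmed
#'   protein sequences), `tree` (`phylo` or `NULL`), `msa`, `manifest`, and
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "r2_pipeline_config"))
  hits <- scan_genome(config$queries, config$genome,
                      min_score = config$min_score)
  loci <- merge_loci(hits, max_gap = config$merge_max_gap)
  rows <- list()
  orfs <- character(0)
  rts <- character(0)
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    contig <- config$genome[[lc$contig_id]]
    eseq <- substr(contig, lc$start + 1L, lc$end)
    if (lc$strand == "-") eseq <- revcomp(eseq)
    ts <- classify_junctions(lc$start, lc$end, contig, config$rdna,
                             strand = lc$strand, window = config$window,
                             min_identity = config$min_identity,
                             min_span = config$min_span)
    orf <- extract_orfs(eseq, min_len_aa = config$min_orf_aa)
    orf_ok <- nrow(orf$full) > 0L
    rec <- if (orf_ok) orf$full[1L, ] else
      if (nrow(orf$partial) > 0L) orf$partial[1L, ] else NULL
    arch <- NULL; cls <- "unclassified"; trimmed <- NA_character_
    rt_seq <- NA_character_; intact <- NA
    if (!is.null(rec)) {
      arch <- annotate_protein(rec$aa_seq)
      cls <- classify_element(ts, arch, orf_ok = orf_ok)
      tr <- trim_n_terminus(rec$aa_seq, arch$znfs)
      trimmed <- tr$aa
      intact <- arch$rt_motifs$intact
      mt <- arch$rt_motifs$motifs
      if (nrow(mt) > 0L)
        rt_seq <- substr(rec$aa_seq, min(mt$start) + 1L, max(mt$end))
    }
    id <- sprintf("locus_%03d", i)
    lp <- if (!is.na(rt_seq))
      lineage_placement(rt_seq, config$ref_rt_A, config$ref_rt_D) else NULL
    rows[[i]] <- data.frame(
      element_id = id, contig_id = lc$contig_id, start = lc$start,
      end = lc$end, strand = lc$strand, score = lc$score,
      query_id = lc$query_id, class = cls,
      completeness = ts$completeness, nick_offset = ts$nick_offset,
      arch_label = if (is.null(arch)) NA_character_ else arch$label,
      orf_len_aa = if (is.null(rec)) NA_integer_ else rec$length_aa,
      orf_full = orf_ok, rt_intact = intact,
      lineage_call = if (is.null(lp)) NA_character_ else lp$call,
      score_vs_A = if (is.null(lp)) NA_real_ else lp$score_vs_A,
      score_vs_D = if (is.null(lp)) NA_real_ else lp$score_vs_D,
      stringsAsFactors = FALSE)
    if (!is.null(rec) && orf_ok) orfs[id] <- trimmed
    if (!is.na(rt_seq)) rts[id] <- rt_seq
  }
  elements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               score = numeric(), query_id = character(), class = character(),
               completeness = character(), nick_offset = integer(),
               arch_label = character(), orf_len_aa = integer(),
               orf_full = logical(), rt_intact = logical(),
               lineage_call = character(), score_vs_A = numeric(),
               score_vs_D = numeric(), stringsAsFactors = FALSE)

  msa <- NULL; tree <- NULL
  if (length(orfs) >= 3L) {
    msa <- trim_alignment(align_progressive(orfs))
    D <- distance_matrix(msa, "poisson")
    boot <- if (config$bootstrap_B > 0L)
      list(msa = msa, B = config$bootstrap_B,
           seed = derive_seed(config$seed, 17L)) else NULL
    og <- if (!is.null(config$outgroup) &&
              config$outgroup %in% rownames(D)) config$outgroup else NULL
    tree <- neighbor_joining(D, outgroup = og, bootstrap = boot)
  }
  bundle <- structure(list(elements = elements, orfs = orfs, rts = rts,
                           msa = msa, tree = tree,
                           manifest = build_manifest(config, elements),
                           config = config),
                      class = "r2_result_bundle")
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

build_manifest <- function(config, elements) {
  checksum <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(x, f)
    unname(tools::md5sum(f))
  }
  list(package = "r2scout",
       version = as.character(utils::packageVersion("r2scout")),
       seed = config$seed,
       n_elements = nrow(elements),
       parameters = list(min_score = config$min_score,
                         merge_max_gap = config$merge_max_gap,
                         min_orf_aa = config$min_orf_aa,
                         window = config$window,
                         min_identity = config$min_identity,
                         min_span = config$min_span,
                         bootstrap_B = config$bootstrap_B),
       tree_method = "neighbor-joining (NJ replaces ML search by design)",
       input_md5 = list(genome = checksum(paste(names(config$genome),
                                                config$genome, sep = "\t")),
                        queries = checksum(paste(names(config$queries),
                                                 config$queries, sep = "\t")),
                        rdna = checksum(config$rdna$seq)))
}

# 0-based half-open -> GFF3 1-based inclusive; the single audited converter
coords_to_gff3 <- function(start0, end0) {
  cbind(start = start0 + 1L, end = end0)
}

write_gff3 <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(elements)) {
    cc <- coords_to_gff3(elements$start, elements$end)
    attrs <- sprintf(
      "ID=%s;class=%s;completeness=%s;nick_offset=%s;arch_label=%s;lineage=%s",
      elements$element_id, elements$class, elements$completeness,
      ifelse(is.na(elements$nick_offset), ".", elements$nick_offset),
      ifelse(is.na(elements$arch_label), ".", elements$arch_label),
      ifelse(is.na(elements$lineage_call), ".", elements$lineage_call))
    lines <- sprintf("%s\tr2scout\tmobile_genetic_element\t%d\t%d\t%.1f\t%s\t.\t%s",
                     elements$contig_id, cc[, "start"], cc[, "end"],
                     elements$score, elements$strand, attrs)
    writeLines(lines, con)
  }
  invisible(path)
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.table(bundle$elements, file.path(outdir, "elements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gff3(bundle$elements, file.path(outdir, "elements.gff3"))
  if (length(bundle$orfs))
    write_fasta(bundle$orfs, file.path(outdir, "orfs_trimmed.faa"), "aa")
  if (!is.null(bundle$tree))
    ape::write.tree(bundle$tree, file.path(outdir, "elements.nwk"))
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' Summarise one or more result bundles
#'
#' Per-genome counts by class, completeness and architecture label; the list
#' of genomes where lineage A and lineage D calls co-occur; and, when a host
#' tree is supplied, the Robinson-Foulds discordance between the element
#' tree (pruned to one representative per genome) and the host tree.
#'
#' @param bundles a single `r2_result_bundle` or a named list of them (names
#'   = genome ids).
#' @param host_tree optional host species tree (newick or `phylo`) with
#'   genome ids as tips.
#' @return list with `census` (data frame), `co_occurrence` (character
#'   vector of genome ids with both lineages), and `rf_discordance`
#'   (integer or `NA`).
#' @export
summarize_run <- function(bundles, host_tree = NULL) {
  if (inherits(bundles, "r2_result_bundle"))
    bundles <- list(genome_1 = bundles)
  stopifnot(length(bundles) >= 1L, !is.null(names(bundles)))
  census <- do.call(rbind, lapply(names(bundles), function(g) {
    el <- bundles[[g]]$elements
    if (nrow(el) == 0L) return(NULL)
    agg <- stats::aggregate(list(n = el$element_id),
                            by = list(class = el$class,
                                      completeness = el$completeness,
                                      arch_label = ifelse(
                                        is.na(el$arch_label), "none",
                                        el$arch_label)),
                            FUN = length)
    cbind(genome = g, agg)
  }))
  co <- names(bundles)[vapply(bundles, function(b) {
    calls <- b$elements$lineage_call
    all(c("A", "D") %in% calls[!is.na(calls)])
  }, TRUE)]
  rf <- NA_integer_
  if (!is.null(host_tree)) {
    host <- as_phylo(host_tree)
    # one representative trimmed ORF per genome, labelled by genome id, gives
    # the cross-genome element tree the discordance is measured on
    reps <- character(0)
    for (g in names(bundles)) {
      o <- bundles[[g]]$orfs
      if (length(o) >= 1L) reps[g] <- o[[1L]]
    }
    shared <- intersect(names(reps), host$tip.label)
    if (length(shared) >= 4L) {
      msa <- trim_alignment(align_progressive(reps[shared]))
      r2_tree <- nj_tree(distance_matrix(msa, "poisson"))
      rf <- rf_distance(r2_tree, host)
    }
  }
  list(census = census, co_occurrence = co, rf_discordance = rf)
}
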