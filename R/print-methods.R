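# Compact print methods for the package's result objects.

#' @export
print.r2_element_spec <- function(x, ...) {
  cat("R2 element spec:", x$arch_label, "| lineage", x$lineage,
      "| ORF", x$orf_len_aa, "aa | offset", x$insertion_offset,
      "nt | 5' truncation", x$truncate5_nt, "nt |",
      if (x$site_specific) "site-specific" else "non-site-specific", "\n")
  invisible(x)
}

#' @export
print.r2_target_site <- function(x, ...) {
  cat("Target-site call:", x$completeness,
      "| nick offset:", ifelse(is.na(x$nick_offset), "NA", x$nick_offset),
      "nt\n")
  cat("  5' flank identity:", format(x$up_flank_identity, digits = 3),
      " 3' flank identity:", format(x$down_flank_identity, digits = 3), "\n")
  invisible(x)
}

#' @export
print.r2_architecture <- function(x, ...) {
  cat("Domain architecture:", x$label, "|", nrow(x$znfs), "ZnF,",
      if (is.null(x$mybs)) 0L else nrow(x$mybs), "Myb")
  if (!is.null(x$rt_motifs) && !is.null(x$rt_motifs$intact))
    cat(" | RT", if (isTRUE(x$rt_motifs$intact)) "intact" else "not intact")
  if (!is.na(x$cofold_znf32_plausible))
    cat(" | ZnF3:2 co-fold plausible:", x$cofold_znf32_plausible)
  cat("\n")
  invisible(x)
}

#' @export
print.r2_lineage_placement <- function(x, ...) {
  cat(sprintf(
    "Lineage placement: %s (score vs A = %.1f, vs D = %.1f, margin %.1f)\n",
    x$call, x$score_vs_A, x$score_vs_D, x$margin))
  invisible(x)
}

#' @export
print.r2_site_rates <- function(x, ...) {
  ok <- !is.na(x$posterior_mean)
  cat(sprintf(
    "Site rates: %d columns (%d usable), alpha_hat = %.3f, K = %d\n",
    length(x$posterior_mean), sum(ok), x$alpha_hat, x$K))
  cat("  bin counts (1 = most conserved):",
      paste(tabulate(x$bins[ok], 6L), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.r2_result_bundle <- function(x, ...) {
  el <- x$elements
  cat("R2 curation result:", nrow(el), "elements\n")
  if (nrow(el)) {
    cat("  classes:      ",
        paste(sprintf("%s=%d", names(table(el$class)), table(el$class)),
              collapse = ", "), "\n")
    cat("  completeness: ",
        paste(sprintf("%s=%d", names(table(el$completeness)),
                      table(el$completeness)), collapse = ", "), "\n")
  }
  if (!is.null(x$tree))
    cat("  tree:", length(x$tree$tip.label), "tips",
        if (!is.null(x$tree$node.label)) "(with bootstrap supports)" else "",
        "\n")
  invisible(x)
}
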