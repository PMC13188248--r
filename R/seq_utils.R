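# Sequence alphabets, integer encodings and small I/O wrappers shared by all
# modules.  Coordinates are 0-based half-open everywhere inside the package;
# conversion to 1-based inclusive happens only in the GFF3 writer.

.NT <- c("A", "C", "G", "T", "N")
.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AAX <- c(.AA, "X")

#' Run an expression with a private RNG stream
#'
#' Every stochastic operation in the package takes an integer `seed` and is
#' bit-reproducible for it; the caller's global RNG state is left untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("'seed' must be a single non-negative integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

enc_nt <- function(x) {
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], .NT)
  if (anyNA(v))
    stop("invalid nucleotide characters (allowed: A, C, G, T, N)", call. = FALSE)
  v
}

enc_aa <- function(x) {
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], .AAX)
  if (anyNA(v))
    stop("invalid amino-acid characters (allowed: 20 standard residues and X)",
         call. = FALSE)
  v
}

dec_seq <- function(v, alphabet) {
  out <- character(length(v))
  out[v == 0L] <- "-"
  out[v > 0L] <- alphabet[v[v > 0L]]
  paste(out, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Read sequences from a named character vector or a FASTA file
#' @noRd
as_seqset <- function(x, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (is.character(x) && length(x) == 1L && !grepl("[\n>]", x) && file.exists(x)) {
    set <- if (type == "dna") Biostrings::readDNAStringSet(x)
           else Biostrings::readAAStringSet(x)
    x <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("sequences must be a named character vector or a FASTA file path",
         call. = FALSE)
  toupper(x)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param type `"dna"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a FASTQ file into a data frame of reads
#'
#' @param path FASTQ file.
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = sub("\\s.*$", "", names(set)),
             seq = as.character(set),
             qual = as.character(methods::slot(set, "quality")),
             stringsAsFactors = FALSE)
}

#' Write simulated reads to FASTQ
#'
#' @param reads data frame with columns `id`, `seq`, `qual` (as produced by
#'   [simulate_reads()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  # writeXStringSet warns about dropping (empty) metadata columns
  suppressWarnings(
    Biostrings::writeXStringSet(set, filepath = path, format = "fastq",
                                qualities = Biostrings::BStringSet(reads$qual)))
  invisible(path)
}

# BLOSUM62 (half-bit log-odds, published constant table) extended with an X
# row/column that never scores positively, so ambiguous residues cannot
# satisfy a motif or seed a hit.
aa_submat <- function() {
  if (!is.null(.r2_cache$aa_submat)) return(.r2_cache$aa_submat)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  b <- data_env$BLOSUM62[.AA, .AA]
  m <- matrix(-4, nrow = 21L, ncol = 21L, dimnames = list(.AAX, .AAX))
  m[1:20, 1:20] <- b
  .r2_cache$aa_submat <- m
  m
}

nt_submat <- function(match = 2, mismatch = -3) {
  m <- matrix(mismatch, 5L, 5L, dimnames = list(.NT, .NT))
  diag(m) <- match
  # N is mismatch-to-all, including itself
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}
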