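# Internal helpers shared across modules. Sequences are plain uppercase
# character strings over {A,C,G,T}; coordinates are 0-based, half-open.

.BASES <- c("A", "C", "G", "T")

# Uppercase and validate a character vector of DNA sequences.
check_dna <- function(x, arg = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || length(x) == 0L)
    stop(sprintf("'%s' must be a non-empty character vector", arg), call. = FALSE)
  x <- toupper(x)
  if (!allow_empty && any(!nzchar(x)))
    stop(sprintf("'%s' contains an empty sequence", arg), call. = FALSE)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("'%s' contains characters outside A/C/G/T (N and IUPAC codes are not permitted)", arg),
         call. = FALSE)
  x
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

chars_seq <- function(ch) paste(ch, collapse = "")

revcomp <- function(x) {
  x <- check_dna(x)
  vapply(x, function(s) chars_seq(rev(seq_chars(chartr("ACGT", "TGCA", s)))),
         character(1L), USE.NAMES = FALSE)
}

# round() halves-to-even is unsuitable for "retain p * n CpGs"; use
# round-half-away-from-zero (arguments here are always >= 0).
round_half_up <- function(x) floor(x + 0.5)

has_cpg <- function(s) grepl("CG", s, fixed = TRUE)

random_dna_chars <- function(length, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(.BASES, length, replace = TRUE, prob = p)
}

# A random sequence of the given length containing no CG dinucleotide,
# including across the junctions with single flanking bases `left`/`right`.
cpg_free_random <- function(length, left = "", right = "", gc = 0.5,
                            max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    cand <- chars_seq(random_dna_chars(length, gc))
    if (!has_cpg(paste0(left, cand, right))) return(cand)
  }
  stop("failed to generate a CpG-free replacement within ", max_tries,
       " attempts", call. = FALSE)
}

# Hamming distance between two equal-length strings (substitution-only model).
hamming <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences differ in length; only substitutions are modelled (no indels)",
         call. = FALSE)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

stopifnot_scalar_seq <- function(x) {
  if (length(x) != 1L) stop("a single sequence is expected", call. = FALSE)
  invisible(x)
}

#' Write a data frame as tab-separated text
#'
#' Plain-text TSV writer used by all tabular interfaces of the package
#' (composition statistics, design manifests, barcode maps, count tables,
#' activity tables, methylation summaries).
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv_table()]
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
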