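# Dinucleotide and composition statistics: CpG counting, normalized CpG
# density (observed/expected, "OE"), G+C content, CpG-island classification.

#' Count CpG dinucleotides
#'
#' Counts forward-strand `CG` dinucleotides. A CpG site is strand-symmetric,
#' so the forward-strand count is the site count.
#'
#' @param sequence Character vector of DNA sequences (A/C/G/T only;
#'   lowercase input is uppercased).
#' @return Integer vector of CpG counts.
#' @examples
#' count_cpgs(c("ACGT", "CGCG", "AAAA"))
#' @export
count_cpgs <- function(sequence) {
  sequence <- check_dna(sequence)
  vapply(gregexpr("CG", sequence, fixed = TRUE),
         function(m) sum(m > 0L), integer(1L))
}

#' Positions of CpG dinucleotides
#'
#' 0-based positions of the C of each CpG in a single sequence, in
#' increasing order. This is the coordinate system used by all library
#' designs.
#'
#' @param sequence A single DNA sequence.
#' @return Integer vector (possibly empty) of 0-based positions.
#' @examples
#' cpg_positions("CGCG")  # 0, 2
#' @export
cpg_positions <- function(sequence) {
  stopifnot_scalar_seq(sequence)
  sequence <- check_dna(sequence)
  m <- gregexpr("CG", sequence, fixed = TRUE)[[1L]]
  if (m[1L] < 0L) return(integer(0L))
  as.integer(m) - 1L
}

nt_counts <- function(sequence) {
  n_c <- nchar(gsub("[^C]", "", sequence))
  n_g <- nchar(gsub("[^G]", "", sequence))
  cbind(n_c = n_c, n_g = n_g)
}

#' Normalized CpG density (observed/expected ratio)
#'
#' `OE = (n_CpG / (n_C * n_G)) * length`, the classical CpG
#' observed-over-expected ratio. When the sequence contains no C or no G the
#' expected count is zero and no CpG is possible; the density is defined as
#' 0 in that degenerate case.
#'
#' @inheritParams count_cpgs
#' @return Numeric vector of OE values (>= 0).
#' @examples
#' normalized_cpg_density("CGCG")  # (2/(2*2))*4 = 2
#' normalized_cpg_density("ACGT")  # 4
#' @export
normalized_cpg_density <- function(sequence) {
  sequence <- check_dna(sequence)
  cg <- count_cpgs(sequence)
  nn <- nt_counts(sequence)
  len <- nchar(sequence)
  denom <- as.numeric(nn[, "n_c"]) * as.numeric(nn[, "n_g"])
  unname(ifelse(denom == 0, 0, cg / denom * len))
}

#' G+C content
#'
#' @inheritParams count_cpgs
#' @return Numeric vector of G+C fractions in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  sequence <- check_dna(sequence)
  nn <- nt_counts(sequence)
  unname((as.numeric(nn[, "n_c"]) + as.numeric(nn[, "n_g"])) / nchar(sequence))
}

#' Classify a sequence as a CpG island
#'
#' A region qualifies as a CpG island (CGI) when it is at least `min_length`
#' long, its G+C content exceeds `min_gc` (strict), and its normalized CpG
#' density is at least `min_oe`. The defaults are the standard CGI
#' definition (>= 200 bp, G+C > 50%, OE >= 0.6).
#'
#' @inheritParams count_cpgs
#' @param min_length Minimum region length in bp.
#' @param min_gc G+C fraction that must be exceeded.
#' @param min_oe Minimum normalized CpG density.
#' @return Logical vector.
#' @export
classify_cgi <- function(sequence, min_length = 200L, min_gc = 0.5,
                         min_oe = 0.6) {
  sequence <- check_dna(sequence)
  nchar(sequence) >= min_length &
    gc_content(sequence) > min_gc &
    normalized_cpg_density(sequence) >= min_oe
}

#' Per-sequence composition statistics
#'
#' @param sequence Character vector of sequences; names (or `ids`) become
#'   the `id` column.
#' @param ids Optional identifiers.
#' @return A data frame with columns `id`, `length`, `n_cpg`, `n_c`, `n_g`,
#'   `oe`, `gc`, `is_cgi`, suitable for [write_tsv_table()].
#' @export
composition_stats <- function(sequence, ids = names(sequence)) {
  sequence <- check_dna(sequence)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequence))
  nn <- nt_counts(sequence)
  data.frame(
    id = ids,
    length = nchar(sequence),
    n_cpg = count_cpgs(sequence),
    n_c = as.integer(nn[, "n_c"]),
    n_g = as.integer(nn[, "n_g"]),
    oe = normalized_cpg_density(sequence),
    gc = gc_content(sequence),
    is_cgi = classify_cgi(sequence),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# ---- promoter records -------------------------------------------------------

validate_motifs <- function(motifs, seq_length) {
  if (is.null(motifs))
    return(data.frame(tf = character(), start = integer(), end = integer(),
                      bound = logical(), score = numeric(),
                      stringsAsFactors = FALSE))
  stopifnot(is.data.frame(motifs))
  needed <- c("tf", "start", "end", "bound")
  missing <- setdiff(needed, names(motifs))
  if (length(missing))
    stop("motif annotations lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"score" %in% names(motifs)) motifs$score <- NA_real_
  motifs$start <- as.integer(motifs$start)
  motifs$end <- as.integer(motifs$end)
  ok <- motifs$start >= 0L & motifs$start < motifs$end & motifs$end <= seq_length
  if (!all(ok))
    stop("motif intervals must satisfy 0 <= start < end <= sequence length",
         call. = FALSE)
  motifs[, c("tf", "start", "end", "bound", "score")]
}

#' Create a promoter record
#'
#' A promoter record bundles a reference sequence with an optional
#' transcription start offset and transcription-factor motif annotations
#' (0-based, half-open intervals; `bound = TRUE` marks motifs supported by a
#' ChIP peak).
#'
#' @param id Identifier.
#' @param sequence DNA sequence (A/C/G/T).
#' @param tss_offset Optional 0-based position of the transcription start
#'   within the sequence.
#' @param motifs Optional data frame with columns `tf`, `start`, `end`,
#'   `bound` and optionally `score`.
#' @return An object of class `promoter_record`.
#' @export
promoter_record <- function(id, sequence, tss_offset = NA_integer_,
                            motifs = NULL) {
  stopifnot(length(id) == 1L)
  stopifnot_scalar_seq(sequence)
  sequence <- check_dna(sequence)
  len <- nchar(sequence)
  if (!is.na(tss_offset)) {
    tss_offset <- as.integer(tss_offset)
    if (tss_offset < 0L || tss_offset >= len)
      stop("tss_offset must lie within the sequence", call. = FALSE)
  }
  structure(
    list(id = as.character(id), sequence = sequence,
         tss_offset = tss_offset, motifs = validate_motifs(motifs, len)),
    class = "promoter_record"
  )
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf("promoter_record '%s': %d bp, %d CpGs, OE = %.3f, GC = %.3f\n",
              x$id, nchar(x$sequence), count_cpgs(x$sequence),
              normalized_cpg_density(x$sequence), gc_content(x$sequence)))
  if (nrow(x$motifs))
    cat(sprintf("  %d motif annotation(s), %d bound\n",
                nrow(x$motifs), sum(x$motifs$bound)))
  invisible(x)
}

#' Read promoter records from a FASTA file
#'
#' @param path FASTA file path.
#' @return A named list of [promoter_record()] objects.
#' @export
read_promoters <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  recs <- lapply(seq_along(dss),
                 function(i) promoter_record(ids[i], as.character(dss[[i]])))
  names(recs) <- ids
  recs
}

#' Write sequences to a FASTA file
#'
#' Accepts a named character vector, a list of [promoter_record()]s, or a
#' mutant construct library.
#'
#' @param x Sequences to write.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  if (is.list(x)) {
    seqs <- vapply(x, function(r) {
      if (inherits(r, "promoter_record")) r$sequence
      else if (inherits(r, "mutant_construct")) r$sequence
      else stop("unsupported element type", call. = FALSE)
    }, character(1L))
    names(seqs) <- vapply(x, function(r) {
      if (inherits(r, "promoter_record")) r$id else r$construct_id
    }, character(1L))
  } else {
    seqs <- check_dna(x)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
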