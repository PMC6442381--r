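# Assignment of read pairs to reference constructs by mismatch (Hamming)
# distance with an error budget and an ambiguity margin, plus the
# barcode -> promoter table with purity filtering.

#' Assignment parameters
#'
#' @param max_error_fraction Fraction of the total sequenced bases allowed
#'   as mismatches to the best reference (default 0.20, i.e. 120 mismatches
#'   in 600 sequenced bases).
#' @param margin Ambiguity gate on the second-closest reference (default 3).
#' @param purity_ratio Maximum second-most-abundant / most-abundant
#'   association ratio for a barcode to be kept (default 0.3, strict).
#' @param margin_mode `"absolute"` (default): the second-best distance
#'   itself must be at least `margin`; `"gap"`: the difference between the
#'   second-best and best distances must be at least `margin`.
#' @return An object of class `assignment_params`.
#' @export
assignment_params <- function(max_error_fraction = 0.20, margin = 3L,
                              purity_ratio = 0.3,
                              margin_mode = c("absolute", "gap")) {
  stopifnot(max_error_fraction > 0, max_error_fraction < 1,
            margin >= 0, purity_ratio >= 0, purity_ratio < 1)
  structure(list(max_error_fraction = max_error_fraction,
                 margin = as.integer(margin),
                 purity_ratio = purity_ratio,
                 margin_mode = match.arg(margin_mode)),
            class = "assignment_params")
}

#' Mismatch distance between a read pair and a reference
#'
#' Total Hamming mismatches summed over the read segments (one or two
#' reads). Reads and their reference segments must be equal length: the
#' model is substitution-only and indels are rejected at ingest.
#'
#' @param reads Character vector of one or two read sequences.
#' @param reference Character vector of the corresponding reference
#'   segments (same lengths).
#' @return Non-negative integer mismatch count.
#' @export
read_distance <- function(reads, reference) {
  if (length(reads) != length(reference))
    stop("reads and reference segments must pair up", call. = FALSE)
  sum(vapply(seq_along(reads),
             function(i) hamming(reads[i], reference[i]), numeric(1L)))
}

# references normalised to a list of equal-structure segment vectors
norm_refs <- function(references) {
  if (is.character(references)) references <- as.list(references)
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("references must be named", call. = FALSE)
  references
}

#' Match a read (pair) to the closest reference
#'
#' Computes the mismatch distance to every reference; with `d1 <= d2` the
#' best and second-best distances, the read is assigned to the best
#' reference iff `d1` is within the error budget
#' (`max_error_fraction * total sequenced bases`), the margin gate on `d2`
#' passes, and `d1 < d2` (ties are ambiguous and never assigned).
#' `UNASSIGNED` is represented as `NA`.
#'
#' @param reads Character vector of one or two read sequences.
#' @param references Named list (or named character vector) whose elements
#'   are reference segment vectors matching `reads`.
#' @param params [assignment_params()].
#' @return The name of the assigned reference, or `NA_character_`.
#' @export
match_read <- function(reads, references, params = assignment_params()) {
  references <- norm_refs(references)
  d <- vapply(references, function(r) read_distance(reads, r), numeric(1L))
  total_bases <- sum(nchar(reads))
  best <- which.min(d)
  d1 <- d[best]
  d2 <- if (length(d) > 1L) min(d[-best]) else Inf
  ok_margin <- switch(params$margin_mode,
                      absolute = d2 >= params$margin,
                      gap = (d2 - d1) >= params$margin)
  if (d1 <= params$max_error_fraction * total_bases && ok_margin && d1 < d2)
    names(references)[best]
  else
    NA_character_
}

#' Assign many reads to references
#'
#' Vectorised driver over [match_read()] semantics: reads are compared to
#' every reference segment-wise via integer comparison, so assigning tens of
#' thousands of reads is fast.
#'
#' @param read1 Character vector of first reads.
#' @param read2 Optional character vector of second reads (same length as
#'   `read1`) when the reference also has a second segment.
#' @param references Named character vector (segment 1) or named list of
#'   `c(segment1, segment2)` vectors.
#' @param params [assignment_params()].
#' @return Data frame with columns `read`, `assigned` (`NA` =
#'   unassigned), `d1`, `d2`.
#' @export
assign_reads <- function(read1, read2 = NULL, references,
                         params = assignment_params()) {
  references <- norm_refs(references)
  n_seg <- length(references[[1L]])
  segs <- list(read1)
  if (n_seg == 2L) {
    if (is.null(read2)) stop("references have two segments but read2 is missing",
                             call. = FALSE)
    segs <- list(read1, read2)
  }
  ref_mats <- lapply(seq_len(n_seg), function(s)
    vapply(references, function(r) utf8ToInt(r[s]),
           integer(nchar(references[[1L]][s]))))
  total_bases <- sum(vapply(seq_len(n_seg),
                            function(s) nchar(segs[[s]][1L]), integer(1L)))
  budget <- params$max_error_fraction * total_bases
  m <- length(references)
  nm <- names(references)
  n_reads <- length(read1)
  assigned <- rep(NA_character_, n_reads)
  d1v <- numeric(n_reads)
  d2v <- numeric(n_reads)
  for (i in seq_len(n_reads)) {
    d <- numeric(m)
    for (s in seq_len(n_seg))
      d <- d + colSums(ref_mats[[s]] != utf8ToInt(segs[[s]][i]))
    best <- which.min(d)
    d1 <- d[best]
    d2 <- if (m > 1L) min(d[-best]) else Inf
    ok_margin <- switch(params$margin_mode,
                        absolute = d2 >= params$margin,
                        gap = (d2 - d1) >= params$margin)
    if (d1 <= budget && ok_margin && d1 < d2) assigned[i] <- nm[best]
    d1v[i] <- d1
    d2v[i] <- d2
  }
  data.frame(
    read = if (!is.null(names(read1))) names(read1) else seq_len(n_reads),
    assigned = assigned, d1 = d1v, d2 = d2v,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Extract the barcode from a second read
#'
#' Locates the upstream and downstream anchors of a [barcode_pattern()]
#' (leftmost position where both anchors match with at most
#' `max_anchor_mismatches` mismatches each) and returns the fixed-length
#' insert between them, or `NA` if the anchors cannot be located.
#'
#' @param read2 A single read sequence.
#' @param pattern A [barcode_pattern()].
#' @param max_anchor_mismatches Mismatch tolerance per anchor.
#' @return Barcode string, or `NA_character_`.
#' @export
extract_barcode <- function(read2, pattern = barcode_pattern(),
                            max_anchor_mismatches = 1L) {
  stopifnot_scalar_seq(read2)
  read2 <- check_dna(read2)
  up <- pattern$up_anchor; down <- pattern$down_anchor
  lu <- nchar(up); ld <- nchar(down); lb <- pattern$bc_length
  ri <- utf8ToInt(read2)
  ui <- utf8ToInt(up); di <- utf8ToInt(down)
  last <- length(ri) - (lu + lb + ld) + 1L
  if (last < 1L) return(NA_character_)
  for (pos in seq_len(last)) {
    if (sum(ri[pos:(pos + lu - 1L)] != ui) > max_anchor_mismatches) next
    dpos <- pos + lu + lb
    if (sum(ri[dpos:(dpos + ld - 1L)] != di) > max_anchor_mismatches) next
    return(substr(read2, pos + lu, pos + lu + lb - 1L))
  }
  NA_character_
}

#' Build the barcode-to-promoter table with purity filtering
#'
#' Tallies, per barcode, how often it was observed together with each
#' assigned promoter. A barcode is `unique` when it associates with a
#' single promoter, or when the ratio of the second-most-abundant to the
#' most-abundant association is below `purity_ratio` (strict); otherwise it
#' is `impure` and excluded downstream. Barcodes seen only with unassigned
#' reads are `unassigned`.
#'
#' @param assignments Data frame with columns `barcode` and `promoter`
#'   (`NA` for unassigned reads).
#' @param params [assignment_params()].
#' @return Data frame with columns `barcode`, `top_promoter`, `n_top`,
#'   `n_second`, `second_top_ratio`, `n_reads`, `status`.
#' @export
build_barcode_table <- function(assignments, params = assignment_params()) {
  stopifnot(all(c("barcode", "promoter") %in% names(assignments)))
  rows <- lapply(split(assignments, assignments$barcode), function(df) {
    tab <- sort(table(df$promoter[!is.na(df$promoter)]), decreasing = TRUE)
    if (!length(tab))
      return(data.frame(barcode = df$barcode[1L], top_promoter = NA_character_,
                        n_top = 0L, n_second = 0L, second_top_ratio = NA_real_,
                        n_reads = nrow(df), status = "unassigned",
                        stringsAsFactors = FALSE))
    n_top <- as.integer(tab[1L])
    n_second <- if (length(tab) > 1L) as.integer(tab[2L]) else 0L
    ratio <- n_second / n_top
    status <- if (length(tab) == 1L || ratio < params$purity_ratio)
      "unique" else "impure"
    data.frame(barcode = df$barcode[1L], top_promoter = names(tab)[1L],
               n_top = n_top, n_second = n_second, second_top_ratio = ratio,
               n_reads = nrow(df), status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unique barcode -> promoter map from a barcode table
#'
#' @param barcode_table Output of [build_barcode_table()].
#' @return Data frame with columns `barcode`, `promoter` restricted to
#'   `status == "unique"`.
#' @export
barcode_map <- function(barcode_table) {
  keep <- barcode_table$status == "unique"
  data.frame(barcode = barcode_table$barcode[keep],
             promoter = barcode_table$top_promoter[keep],
             stringsAsFactors = FALSE)
}

#' Read paired FASTQ files
#'
#' @param r1_path,r2_path FASTQ file paths (records paired by order).
#' @return List with character vectors `read1`, `read2` (named by record id).
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(r1) != length(r2))
    stop("paired FASTQ files differ in record count", call. = FALSE)
  list(read1 = stats::setNames(as.character(r1), names(r1)),
       read2 = stats::setNames(as.character(r2), names(r2)))
}

#' Write paired reads to FASTQ files
#'
#' @param read1,read2 Character vectors of read sequences (parallel, named
#'   by read id or auto-numbered).
#' @param r1_path,r2_path Output paths.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq_pairs <- function(read1, read2, r1_path, r2_path) {
  ids <- if (!is.null(names(read1))) names(read1) else
    sprintf("read%06d", seq_along(read1))
  s1 <- Biostrings::DNAStringSet(stats::setNames(read1, ids))
  s2 <- Biostrings::DNAStringSet(stats::setNames(read2, ids))
  Biostrings::writeXStringSet(s1, r1_path, format = "fastq")
  Biostrings::writeXStringSet(s2, r2_path, format = "fastq")
  invisible(c(r1_path, r2_path))
}
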