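# Promoter mutant-library designs. All designs are substitution-only: every
# construct has the same length as its parent. Positions are 0-based.

new_construct <- function(parent_id, construct_id, strategy, sequence,
                          mutated_positions,
                          retained_cpg_fraction = NA_real_,
                          barcodes = character()) {
  structure(
    list(parent_id = parent_id, construct_id = construct_id,
         strategy = strategy, sequence = sequence,
         mutated_positions = as.integer(mutated_positions),
         retained_cpg_fraction = retained_cpg_fraction,
         barcodes = barcodes),
    class = "mutant_construct"
  )
}

#' @export
print.mutant_construct <- function(x, ...) {
  cat(sprintf("mutant_construct '%s' (%s of '%s'): %d position(s) mutated, OE = %.3f\n",
              x$construct_id, x$strategy, x$parent_id,
              length(x$mutated_positions),
              normalized_cpg_density(x$sequence)))
  invisible(x)
}

mutated_vs <- function(parent_seq, mutant_seq) {
  which(utf8ToInt(mutant_seq) != utf8ToInt(parent_seq)) - 1L
}

#' Design manifest for a construct library
#'
#' Flattens a list of mutant constructs into a per-construct table with the
#' achieved normalized CpG density and G+C content, so composition drift
#' introduced by random replacements is auditable.
#'
#' @param constructs List of `mutant_construct` objects.
#' @return Data frame with columns `construct_id`, `parent_id`, `strategy`,
#'   `retained_cpg_fraction`, `n_mutated`, `mutated_positions`
#'   (semicolon-joined), `oe`, `gc`.
#' @export
design_manifest <- function(constructs) {
  stopifnot(is.list(constructs))
  data.frame(
    construct_id = vapply(constructs, `[[`, character(1L), "construct_id"),
    parent_id = vapply(constructs, `[[`, character(1L), "parent_id"),
    strategy = vapply(constructs, `[[`, character(1L), "strategy"),
    retained_cpg_fraction = vapply(constructs, `[[`, numeric(1L),
                                   "retained_cpg_fraction"),
    n_mutated = vapply(constructs, function(x) length(x$mutated_positions),
                       integer(1L)),
    mutated_positions = vapply(constructs, function(x)
      paste(x$mutated_positions, collapse = ";"), character(1L)),
    oe = vapply(constructs, function(x) normalized_cpg_density(x$sequence),
                numeric(1L)),
    gc = vapply(constructs, function(x) gc_content(x$sequence), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Mutable (non-motif) CpG positions of a promoter
#'
#' A CpG is mutable when its dinucleotide interval `[p, p+2)` does not
#' intersect any motif annotation with `bound = TRUE` (motifs supported by a
#' ChIP peak). Unbound motif annotations do not mask CpGs.
#'
#' @param promoter A [promoter_record()].
#' @return Integer vector of 0-based CpG positions.
#' @export
mutable_cpgs <- function(promoter) {
  stopifnot(inherits(promoter, "promoter_record"))
  pos <- cpg_positions(promoter$sequence)
  bm <- promoter$motifs[promoter$motifs$bound, , drop = FALSE]
  if (!nrow(bm) || !length(pos)) return(pos)
  keep <- vapply(pos, function(p)
    !any(p < bm$end & (p + 2L) > bm$start), logical(1L))
  pos[keep]
}

check_windows <- function(windows, seq_length) {
  stopifnot(is.data.frame(windows), all(c("start", "end") %in% names(windows)))
  windows$start <- as.integer(windows$start)
  windows$end <- as.integer(windows$end)
  windows <- windows[order(windows$start), , drop = FALSE]
  if (any(windows$start < 0L) || any(windows$end > seq_length) ||
      any(windows$start >= windows$end))
    stop("windows must satisfy 0 <= start < end <= promoter length",
         call. = FALSE)
  if (nrow(windows) > 1L &&
      any(windows$start[-1L] < windows$end[-nrow(windows)]))
    stop("windows overlap", call. = FALSE)
  windows
}

#' Window-combination mutant library
#'
#' Partitions the mutable CpGs of a promoter into user-given windows and
#' enumerates every WT/mutant combination of those windows: `2^k` constructs
#' for `k` windows. In a mutant window the C of every mutable CpG is
#' replaced by `substitution_base`; bound-motif CpGs are never touched. The
#' all-WT combination reproduces the parent sequence exactly.
#'
#' @param promoter A [promoter_record()].
#' @param windows Data frame with 0-based half-open `start`/`end` columns;
#'   windows must be disjoint.
#' @param substitution_base `"A"` or `"T"`.
#' @return List of `mutant_construct` objects (length `2^k`), ordered with
#'   the all-WT construct first.
#' @export
window_combination_library <- function(promoter, windows,
                                       substitution_base = c("A", "T")) {
  stopifnot(inherits(promoter, "promoter_record"))
  substitution_base <- match.arg(substitution_base)
  len <- nchar(promoter$sequence)
  windows <- check_windows(windows, len)
  k <- nrow(windows)
  mut <- mutable_cpgs(promoter)
  per_window <- lapply(seq_len(k), function(j)
    mut[mut >= windows$start[j] & mut < windows$end[j]])
  combos <- as.matrix(expand.grid(rep(list(c(0L, 1L)), max(k, 1L)))[seq_len(2^k), , drop = FALSE])
  if (k == 0L) combos <- matrix(integer(0L), nrow = 1L, ncol = 0L)
  parent_ch <- seq_chars(promoter$sequence)
  lapply(seq_len(nrow(combos)), function(i) {
    ch <- parent_ch
    pos <- integer(0L)
    for (j in seq_len(k)) if (combos[i, j] == 1L) pos <- c(pos, per_window[[j]])
    if (length(pos)) ch[pos + 1L] <- substitution_base
    id <- paste0(promoter$id, "_cmb_",
                 if (k) paste(combos[i, ], collapse = "") else "wt")
    new_construct(promoter$id, id, "window_combination", chars_seq(ch),
                  sort(pos))
  })
}

#' CpG density series by random partial mutation
#'
#' For each retention fraction `p`, retains `round(p * n_mutable)` randomly
#' chosen mutable CpGs (round-half-away-from-zero) and mutates the C of
#' every other mutable CpG to `substitution_base`. The random choice is
#' re-drawn independently for each density level, seed-reproducibly.
#'
#' @inheritParams window_combination_library
#' @param retention_fractions Numeric vector of fractions in `[0, 1]`.
#' @param seed Integer seed.
#' @return List of `mutant_construct` objects, one per fraction, with
#'   `retained_cpg_fraction` set.
#' @export
density_series_library <- function(promoter, retention_fractions,
                                   substitution_base = c("A", "T"),
                                   seed) {
  stopifnot(inherits(promoter, "promoter_record"))
  substitution_base <- match.arg(substitution_base)
  stopifnot(all(retention_fractions >= 0 & retention_fractions <= 1))
  mut <- mutable_cpgs(promoter)
  n <- length(mut)
  if (n == 0L)
    stop("promoter has no mutable CpGs; a density series is undefined",
         call. = FALSE)
  parent_ch <- seq_chars(promoter$sequence)
  withr::with_seed(seed, {
    lapply(seq_along(retention_fractions), function(i) {
      p <- retention_fractions[i]
      n_keep <- min(n, round_half_up(p * n))
      keep <- mut[sample.int(n, n_keep)]
      drop <- setdiff(mut, keep)
      ch <- parent_ch
      if (length(drop)) ch[drop + 1L] <- substitution_base
      id <- sprintf("%s_dens_%02d_p%s", promoter$id, i, format(p))
      new_construct(promoter$id, id, "density_series", chars_seq(ch),
                    sort(drop), retained_cpg_fraction = p)
    })
  })
}

# Replace [start, end) with a random CpG-free scramble; if a PWM is given,
# additionally require the mutated neighbourhood to score below 0 so the
# motif is destroyed.
destroy_interval <- function(parent_ch, start, end, pwm = NULL,
                             max_tries = 1000L) {
  len <- length(parent_ch)
  left <- if (start > 0L) parent_ch[start] else ""
  right <- if (end < len) parent_ch[end + 1L] else ""
  for (i in seq_len(max_tries)) {
    cand <- cpg_free_random(end - start, left, right)
    if (!is.null(pwm)) {
      w <- nrow(pwm$matrix)
      cs <- max(0L, start - (w - 1L))
      ce <- min(len, end + (w - 1L))
      ch <- parent_ch
      ch[(start + 1L):end] <- seq_chars(cand)
      sc <- logodds_scan(chars_seq(ch[(cs + 1L):ce]), pwm)
      if (!is.finite(sc) || sc >= 0) next
    }
    if (identical(cand, chars_seq(parent_ch[(start + 1L):end]))) next
    return(cand)
  }
  stop("failed to find a destroying replacement for interval [", start, ",",
       end, ")", call. = FALSE)
}

#' Motif mutation library
#'
#' One construct per single motif occurrence plus one construct per
#' transcription factor with all of its motifs mutated. Each motif interval
#' is replaced by a random CpG-free scramble (no CG inside the interval or
#' across its junctions); when a PWM for the factor is supplied, the
#' replacement must additionally score below 0 log2 log-odds in the mutated
#' neighbourhood. The replacement for a given interval is drawn once, so a
#' factor with a single motif has identical "single" and "all" constructs.
#'
#' @inheritParams density_series_library
#' @param motifs Data frame with columns `tf`, `start`, `end` (0-based
#'   half-open).
#' @param pwms Optional named list of [pwm()] objects, keyed by `tf`.
#' @return List of `mutant_construct` objects.
#' @export
motif_mutation_library <- function(promoter, motifs, seed, pwms = NULL) {
  stopifnot(inherits(promoter, "promoter_record"))
  if (is.null(motifs) || !nrow(motifs)) return(list())
  motifs <- validate_motifs(motifs, nchar(promoter$sequence))
  parent_ch <- seq_chars(promoter$sequence)
  withr::with_seed(seed, {
    repl <- lapply(seq_len(nrow(motifs)), function(i)
      destroy_interval(parent_ch, motifs$start[i], motifs$end[i],
                       pwm = pwms[[motifs$tf[i]]]))
    apply_repl <- function(idx) {
      ch <- parent_ch
      for (i in idx)
        ch[(motifs$start[i] + 1L):motifs$end[i]] <- seq_chars(repl[[i]])
      chars_seq(ch)
    }
    singles <- lapply(seq_len(nrow(motifs)), function(i) {
      tf <- motifs$tf[i]
      nth <- sum(motifs$tf[seq_len(i)] == tf)
      s <- apply_repl(i)
      new_construct(promoter$id,
                    sprintf("%s_%s_site%d", promoter$id, tf, nth),
                    "motif_mutation", s, mutated_vs(promoter$sequence, s))
    })
    alls <- lapply(unique(motifs$tf), function(tf) {
      idx <- which(motifs$tf == tf)
      s <- apply_repl(idx)
      new_construct(promoter$id, sprintf("%s_%s_all", promoter$id, tf),
                    "motif_mutation", s, mutated_vs(promoter$sequence, s))
    })
    c(singles, alls)
  })
}

#' Tiling replacement library
#'
#' Divides the promoter (or a sub-region) into consecutive windows of
#' `window_size` bp and generates one construct per complete window, with
#' that window replaced by a random CpG-free sequence that also creates no
#' CG across either junction. A trailing partial window is not mutated.
#'
#' @inheritParams density_series_library
#' @param window_size Tile width in bp (>= 2; with width 1 a junction-safe
#'   CpG-free replacement cannot be guaranteed).
#' @param region Optional `c(start, end)` 0-based half-open sub-region to
#'   tile; default is the whole promoter.
#' @return List of `mutant_construct` objects, one per tile.
#' @export
tiling_replacement_library <- function(promoter, window_size = 10L, seed,
                                       region = NULL) {
  stopifnot(inherits(promoter, "promoter_record"))
  window_size <- as.integer(window_size)
  if (window_size < 2L)
    stop("window_size must be >= 2", call. = FALSE)
  len <- nchar(promoter$sequence)
  if (is.null(region)) region <- c(0L, len)
  stopifnot(region[1L] >= 0L, region[2L] <= len, region[1L] < region[2L])
  k <- (region[2L] - region[1L]) %/% window_size
  parent_ch <- seq_chars(promoter$sequence)
  withr::with_seed(seed, {
    lapply(seq_len(k), function(i) {
      s <- region[1L] + (i - 1L) * window_size
      e <- s + window_size
      repl <- destroy_interval(parent_ch, s, e)
      ch <- parent_ch
      ch[(s + 1L):e] <- seq_chars(repl)
      sq <- chars_seq(ch)
      new_construct(promoter$id,
                    sprintf("%s_tile%02d", promoter$id, i),
                    "tiling_replacement", sq, mutated_vs(promoter$sequence, sq))
    })
  })
}

#' CpG add-back library in a CpG-free baseline context
#'
#' Replaces the given low-effect blocks of a promoter by random CpG-free
#' sequence to form a baseline construct, then re-introduces CG
#' dinucleotides at the original WT CpG positions within those blocks, in
#' random but nested combinations of the requested sizes. The baseline
#' keeps the WT G of every block CpG in place and substitutes A at the C
#' position (the C-to-A convention of the density designs); add-back
#' restores the C. Nesting (each larger add-back set contains the smaller
#' ones) makes normalized CpG density strictly increasing in the add-back
#' count on the shared baseline.
#'
#' @inheritParams density_series_library
#' @param low_effect_blocks Data frame with `start`/`end` columns (0-based
#'   half-open), disjoint.
#' @param addback_counts Integer vector; each must not exceed the number of
#'   WT CpGs fully inside the blocks.
#' @return List with elements `baseline` (a `mutant_construct`) and
#'   `addbacks` (list of `mutant_construct`, one per count).
#' @export
addback_library <- function(promoter, low_effect_blocks, addback_counts,
                            seed) {
  stopifnot(inherits(promoter, "promoter_record"))
  len <- nchar(promoter$sequence)
  blocks <- check_windows(low_effect_blocks, len)
  cg <- cpg_positions(promoter$sequence)
  avail <- cg[vapply(cg, function(p)
    any(p >= blocks$start & (p + 2L) <= blocks$end), logical(1L))]
  addback_counts <- as.integer(addback_counts)
  if (any(addback_counts < 0L) || any(addback_counts > length(avail)))
    stop("addback counts must lie in [0, ", length(avail),
         "] (WT CpGs fully inside the blocks)", call. = FALSE)
  parent_ch <- seq_chars(promoter$sequence)
  withr::with_seed(seed, {
    base_ch <- parent_ch
    for (j in seq_len(nrow(blocks))) {
      s <- blocks$start[j]; e <- blocks$end[j]
      in_block <- avail[avail >= s & (avail + 2L) <= e]
      left <- if (s > 0L) base_ch[s] else ""
      right <- if (e < len) base_ch[e + 1L] else ""
      repeat {
        repl <- random_dna_chars(e - s)
        # keep the WT G, put A at the C slot; the forced A before each G
        # also guarantees those Gs cannot form a CG
        repl[in_block - s + 1L] <- "A"
        repl[in_block - s + 2L] <- "G"
        if (!has_cpg(paste0(left, chars_seq(repl), right))) break
      }
      base_ch[(s + 1L):e] <- repl
    }
    baseline_seq <- chars_seq(base_ch)
    baseline <- new_construct(
      promoter$id, paste0(promoter$id, "_baseline"), "addback",
      baseline_seq, mutated_vs(promoter$sequence, baseline_seq),
      retained_cpg_fraction = 0)
    perm <- avail[sample.int(length(avail))]
    addbacks <- lapply(addback_counts, function(m) {
      ch <- base_ch
      if (m > 0L) ch[perm[seq_len(m)] + 1L] <- "C"
      sq <- chars_seq(ch)
      new_construct(promoter$id,
                    sprintf("%s_addback_%02d", promoter$id, m),
                    "addback", sq, mutated_vs(promoter$sequence, sq),
                    retained_cpg_fraction = if (length(avail)) m / length(avail) else 0)
    })
    list(baseline = baseline, addbacks = addbacks)
  })
}

# ---- barcodes ---------------------------------------------------------------

#' Barcode pattern
#'
#' Degenerate-base pattern for reporter barcodes plus the fixed anchor
#' sequences that flank the barcode on the second read. `N` expands to
#' A/C/G/T and `W` to A/T; literal A/C/G/T positions are kept fixed. The
#' default pattern and anchors correspond to the annealed barcode oligo
#' `CGCCGAA NNNNWNNNNWNNNNN AGCTCGG`.
#'
#' @param pattern Pattern string over `{N, W, A, C, G, T}`.
#' @param up_anchor,down_anchor Fixed flanking sequences.
#' @return An object of class `barcode_pattern`.
#' @export
barcode_pattern <- function(pattern = "NNNNWNNNNWNNNNN",
                            up_anchor = "CGCCGAA",
                            down_anchor = "AGCTCGG") {
  pattern <- toupper(pattern)
  if (grepl("[^NWACGT]", pattern))
    stop("pattern may only contain N, W, A, C, G, T", call. = FALSE)
  structure(list(pattern = pattern,
                 bc_length = nchar(pattern),
                 up_anchor = check_dna(up_anchor),
                 down_anchor = check_dna(down_anchor)),
            class = "barcode_pattern")
}

#' Size of a barcode pattern space
#'
#' @param pattern Pattern string or [barcode_pattern()].
#' @return Number of distinct barcodes the pattern can produce.
#' @export
barcode_space_size <- function(pattern) {
  if (inherits(pattern, "barcode_pattern")) pattern <- pattern$pattern
  ch <- seq_chars(toupper(pattern))
  prod(ifelse(ch == "N", 4, ifelse(ch == "W", 2, 1)))
}

pattern_alphabets <- function(pattern) {
  lapply(seq_chars(pattern), function(c)
    switch(c, N = .BASES, W = c("A", "T"), c))
}

#' Generate distinct pattern-matching barcodes
#'
#' Draws barcodes uniformly from the pattern space, keeping a candidate only
#' if its Hamming distance to every already-accepted barcode is at least
#' `min_pairwise_distance` (default 3, which tolerates one sequencing error
#' without collision).
#'
#' @param n Number of barcodes.
#' @param pattern Pattern string or [barcode_pattern()].
#' @param min_pairwise_distance Minimum pairwise Hamming distance.
#' @param seed Integer seed.
#' @param max_tries Attempt budget before giving up.
#' @return Character vector of `n` distinct barcodes.
#' @export
generate_barcodes <- function(n, pattern = "NNNNWNNNNWNNNNN",
                              min_pairwise_distance = 3L, seed,
                              max_tries = 200L * n + 1000L) {
  if (inherits(pattern, "barcode_pattern")) pattern <- pattern$pattern
  n <- as.integer(n)
  if (n == 0L) return(character(0L))
  if (n > barcode_space_size(pattern))
    stop("requested more barcodes than the pattern space contains",
         call. = FALSE)
  alphabets <- pattern_alphabets(toupper(pattern))
  L <- length(alphabets)
  withr::with_seed(seed, {
    accepted <- matrix(0L, nrow = L, ncol = 0L)
    out <- character(0L)
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not generate ", n, " barcodes at pairwise distance >= ",
             min_pairwise_distance, " within ", max_tries, " attempts",
             call. = FALSE)
      cand <- vapply(alphabets, function(a) a[sample.int(length(a), 1L)],
                     character(1L))
      ci <- utf8ToInt(chars_seq(cand))
      if (ncol(accepted) &&
          any(colSums(accepted != ci) < min_pairwise_distance)) next
      accepted <- cbind(accepted, ci)
      out <- c(out, chars_seq(cand))
    }
    out
  })
}
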