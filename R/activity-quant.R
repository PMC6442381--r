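# Quantification of transcriptional activity from DNA/RNA barcode counts:
# scale-to-smaller normalization, DNA representation filter, zero-RNA
# imputation, pseudocount enrichment, per-promoter log2 activities.

#' Quantification parameters
#'
#' @param alpha Pseudocount added to the RNA/DNA ratio (default 0.05). The
#'   log2 activity of a fully silent promoter is exactly `log2(alpha)`.
#' @param min_dna_reads Scaled DNA count a barcode must strictly exceed to
#'   be kept (default 20).
#' @param min_barcodes_per_promoter Minimum retained barcodes for a
#'   promoter to be reported (default 3; set to 1 for low-coverage
#'   libraries).
#' @return An object of class `quant_params`.
#' @export
quant_params <- function(alpha = 0.05, min_dna_reads = 20,
                         min_barcodes_per_promoter = 3L) {
  stopifnot(alpha > 0, min_dna_reads >= 0, min_barcodes_per_promoter >= 1L)
  structure(list(alpha = alpha, min_dna_reads = min_dna_reads,
                 min_barcodes_per_promoter = as.integer(min_barcodes_per_promoter)),
            class = "quant_params")
}

#' Scale two count vectors to the smaller total
#'
#' The sample with the larger total is multiplied by
#' `smaller total / larger total`; the other is unchanged. After scaling
#' both totals are equal, so per-barcode RNA/DNA ratios estimate relative
#' expression independently of sequencing depth.
#'
#' @param dna_counts,rna_counts Named numeric vectors of raw counts.
#' @return List with scaled `dna`, `rna`, and `scaled` (which sample was
#'   rescaled: `"dna"`, `"rna"`, or `"none"`).
#' @export
scale_to_smaller <- function(dna_counts, rna_counts) {
  td <- sum(dna_counts); tr <- sum(rna_counts)
  if (td <= 0 || tr <= 0)
    stop("both samples must have a positive total count", call. = FALSE)
  if (td > tr) {
    list(dna = dna_counts * tr / td, rna = rna_counts, scaled = "dna")
  } else if (tr > td) {
    list(dna = dna_counts, rna = rna_counts * td / tr, scaled = "rna")
  } else {
    list(dna = dna_counts, rna = rna_counts, scaled = "none")
  }
}

#' Filter barcodes by scaled DNA representation
#'
#' @param dna_scaled Named numeric vector of scaled DNA counts.
#' @param params [quant_params()].
#' @return Character vector of retained barcode names (scaled count
#'   strictly greater than `min_dna_reads`).
#' @export
filter_dna <- function(dna_scaled, params = quant_params()) {
  names(dna_scaled)[dna_scaled > params$min_dna_reads]
}

#' Barcode-level enrichment with pseudocount
#'
#' `n_r / n_d + alpha`. RNA counts of barcodes that passed the DNA filter
#' but were never seen in the RNA sample are 0 by the imputation rule, so
#' their enrichment is exactly `alpha`.
#'
#' @param n_r RNA counts (numeric vector).
#' @param n_d DNA counts (must be positive; the DNA filter guarantees
#'   this).
#' @param alpha Pseudocount.
#' @return Numeric vector of enrichments; `log2` is taken downstream.
#' @export
barcode_enrichment <- function(n_r, n_d, alpha = 0.05) {
  if (any(n_d <= 0))
    stop("DNA counts must be positive; apply filter_dna() first", call. = FALSE)
  n_r / n_d + alpha
}

#' Per-promoter log2 activity from barcode enrichments
#'
#' Log2 activity is the arithmetic mean of `log2(enrichment)` over the
#' promoter's retained barcodes. Promoters with fewer than
#' `min_barcodes_per_promoter` barcodes are dropped with a message.
#'
#' @param enrichments Data frame with columns `promoter`, `barcode`,
#'   `enrichment`.
#' @param params [quant_params()].
#' @return Data frame with columns `promoter`, `n_barcodes`,
#'   `log2_activity`.
#' @export
promoter_activity <- function(enrichments, params = quant_params()) {
  stopifnot(all(c("promoter", "enrichment") %in% names(enrichments)))
  grp <- split(log2(enrichments$enrichment), enrichments$promoter)
  n <- vapply(grp, length, integer(1L))
  drop <- names(grp)[n < params$min_barcodes_per_promoter]
  if (length(drop))
    message("dropping ", length(drop), " promoter(s) with fewer than ",
            params$min_barcodes_per_promoter, " barcodes: ",
            paste(drop, collapse = ", "))
  keep <- n >= params$min_barcodes_per_promoter
  data.frame(promoter = names(grp)[keep],
             n_barcodes = n[keep],
             log2_activity = vapply(grp[keep], mean, numeric(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantify one replicate
#'
#' Runs the full per-replicate chain: scale DNA and RNA to the smaller
#' total, drop under-represented barcodes (scaled DNA <= `min_dna_reads`),
#' impute RNA = 0 for retained barcodes absent from the RNA sample, form
#' pseudocount enrichments, and average log2 enrichments per promoter over
#' the unique (purity-filtered) barcodes of `barcode_map`.
#'
#' @param dna_counts,rna_counts Named numeric vectors of raw counts for one
#'   replicate.
#' @param barcode_map Data frame with columns `barcode`, `promoter`
#'   (unique barcodes only; see [barcode_map()]).
#' @param params [quant_params()].
#' @return Data frame as in [promoter_activity()].
#' @export
quantify_replicate <- function(dna_counts, rna_counts, barcode_map,
                               params = quant_params()) {
  sc <- scale_to_smaller(dna_counts, rna_counts)
  keep <- filter_dna(sc$dna, params)
  keep <- keep[keep %in% barcode_map$barcode]
  rna <- sc$rna[match(keep, names(sc$rna))]
  rna[is.na(rna)] <- 0
  enr <- data.frame(
    barcode = keep,
    promoter = barcode_map$promoter[match(keep, barcode_map$barcode)],
    enrichment = barcode_enrichment(rna, sc$dna[keep], params$alpha),
    stringsAsFactors = FALSE
  )
  promoter_activity(enr, params)
}

#' Quantify activities across replicates from a long count table
#'
#' @param counts Long data frame with columns `barcode`, `sample`
#'   (`"DNA"`/`"RNA"`), `replicate`, `count`.
#' @param barcode_map Data frame with columns `barcode`, `promoter`.
#' @param params [quant_params()].
#' @return List with `per_replicate` (columns `promoter`, `replicate`,
#'   `n_barcodes`, `log2_activity`) and `aggregated` (see
#'   [aggregate_replicates()]).
#' @export
quantify_activity <- function(counts, barcode_map, params = quant_params()) {
  stopifnot(all(c("barcode", "sample", "replicate", "count") %in% names(counts)))
  reps <- sort(unique(counts$replicate))
  per_rep <- lapply(reps, function(r) {
    sub <- counts[counts$replicate == r, , drop = FALSE]
    dna <- sub[sub$sample == "DNA", ]
    rna <- sub[sub$sample == "RNA", ]
    act <- quantify_replicate(stats::setNames(dna$count, dna$barcode),
                              stats::setNames(rna$count, rna$barcode),
                              barcode_map, params)
    if (nrow(act)) act$replicate <- r
    act
  })
  per_rep <- do.call(rbind, per_rep[vapply(per_rep, nrow, integer(1L)) > 0L])
  list(per_replicate = per_rep, aggregated = aggregate_replicates(per_rep))
}

#' Aggregate per-replicate activities
#'
#' Unweighted mean across replicates and the sample standard deviation
#' (n - 1); the SD is `NA` for promoters quantified in a single replicate.
#'
#' @param per_replicate Data frame with columns `promoter`,
#'   `log2_activity` (and typically `replicate`).
#' @return Data frame with columns `promoter`, `n_replicates`,
#'   `mean_log2_activity`, `sd_log2_activity`.
#' @export
aggregate_replicates <- function(per_replicate) {
  grp <- split(per_replicate$log2_activity, per_replicate$promoter)
  data.frame(
    promoter = names(grp),
    n_replicates = vapply(grp, length, integer(1L)),
    mean_log2_activity = vapply(grp, mean, numeric(1L)),
    sd_log2_activity = vapply(grp, function(v)
      if (length(v) > 1L) stats::sd(v) else NA_real_, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Activities relative to a reference promoter
#'
#' Subtracts the reference's log2 activity within each replicate, then
#' aggregates across replicates.
#'
#' @param per_replicate Per-replicate activity table (columns `promoter`,
#'   `replicate`, `log2_activity`).
#' @param reference Reference promoter id (must be quantified in every
#'   replicate present).
#' @return Aggregated data frame as in [aggregate_replicates()], where the
#'   activities are log2 ratios to the reference.
#' @export
relative_activity <- function(per_replicate, reference) {
  reps <- unique(per_replicate$replicate)
  out <- lapply(reps, function(r) {
    sub <- per_replicate[per_replicate$replicate == r, , drop = FALSE]
    ref <- sub$log2_activity[sub$promoter == reference]
    if (length(ref) != 1L)
      stop("reference promoter '", reference, "' missing in replicate ", r,
           call. = FALSE)
    sub$log2_activity <- sub$log2_activity - ref
    sub
  })
  aggregate_replicates(do.call(rbind, out))
}

#' Per-promoter log2 fold change between two conditions
#'
#' @param aggregated_a,aggregated_b Aggregated activity tables (see
#'   [aggregate_replicates()]) for conditions A and B.
#' @return Data frame with columns `promoter`, `log2_fold_change`
#'   (A minus B); promoters missing in either condition are dropped with a
#'   message.
#' @export
condition_fold_change <- function(aggregated_a, aggregated_b) {
  shared <- intersect(aggregated_a$promoter, aggregated_b$promoter)
  dropped <- setdiff(union(aggregated_a$promoter, aggregated_b$promoter),
                     shared)
  if (length(dropped))
    message("dropping ", length(dropped),
            " promoter(s) missing in one condition")
  data.frame(
    promoter = shared,
    log2_fold_change =
      aggregated_a$mean_log2_activity[match(shared, aggregated_a$promoter)] -
      aggregated_b$mean_log2_activity[match(shared, aggregated_b$promoter)],
    stringsAsFactors = FALSE
  )
}

#' Mean-variance diagnostic across candidate pseudocounts
#'
#' For each candidate `alpha`, quantifies one replicate and reports the
#' mean across promoters of the per-promoter variance of barcode log2
#' enrichments. Plotting this against `alpha` lets users pick the smallest
#' pseudocount that roughly stabilises the variance.
#'
#' @inheritParams quantify_replicate
#' @param alphas Numeric vector of candidate pseudocounts.
#' @return Data frame with columns `alpha`, `mean_variance`.
#' @export
alpha_diagnostic <- function(dna_counts, rna_counts, barcode_map,
                             alphas = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5),
                             params = quant_params()) {
  sc <- scale_to_smaller(dna_counts, rna_counts)
  keep <- filter_dna(sc$dna, params)
  keep <- keep[keep %in% barcode_map$barcode]
  rna <- sc$rna[match(keep, names(sc$rna))]
  rna[is.na(rna)] <- 0
  prom <- barcode_map$promoter[match(keep, barcode_map$barcode)]
  mv <- vapply(alphas, function(a) {
    l2 <- log2(barcode_enrichment(rna, sc$dna[keep], a))
    v <- vapply(split(l2, prom), function(x)
      if (length(x) > 1L) stats::var(x) else NA_real_, numeric(1L))
    mean(v, na.rm = TRUE)
  }, numeric(1L))
  data.frame(alpha = alphas, mean_variance = mv)
}
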