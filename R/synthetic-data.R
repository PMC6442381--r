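# Seeded generators producing inputs with known ground truth for every
# pipeline stage: promoters with controllable CpG density, activity models,
# overdispersed count matrices, substitution-error read pairs, logistic
# binding windows, and bisulfite call tables.
#
# Every generator is a pure function of (config, seed): each one derives its
# RNG stream from config$seed plus a fixed, documented offset (promoters +0,
# activities +1, counts +2, reads +3, binding windows +4, methylation +5,
# barcodes +6), so generators can be called in any order reproducibly.

#' Simulation configuration
#'
#' Bundles the study conditions of the synthetic experiment. Defaults:
#' 600-bp promoters (a -400..+200 TSS span), 20 promoters, 3 replicates,
#' 8 barcodes per construct, sequencing depth 200 reads per barcode,
#' activity model `true = beta0 + beta_oe * OE + N(0, sigma)` with
#' `beta0 = -3`, `beta_oe = 4`, `sigma = 0.25` log2 units, negative
#' binomial DNA counts (size 10) with Poisson RNA given abundance, binding
#' model `logit P(bound) = a + b * motif_score + c * oe` with
#' `(a, b, c) = (-6, 0.4, 4)`, and methylation decreasing in CpG density
#' (logistic intercept 2, slope -6 per OE unit).
#'
#' @param seed Integer seed (mandatory).
#' @param n_promoters,promoter_length,gc Promoter set geometry and base
#'   composition.
#' @param target_oe Optional vector of target normalized CpG densities in
#'   `(0, 2]` (recycled); default draws from a bimodal low/high mixture.
#' @param oe_tolerance Acceptance tolerance on achieved OE.
#' @param motif_set Optional named character vector of consensus motifs to
#'   embed.
#' @param motif_prob Per-promoter, per-motif embedding probability.
#' @param beta0,beta_oe,sigma Activity model coefficients (log2 scale) and
#'   noise SD.
#' @param motif_effects Named numeric vector of per-motif activity effects.
#' @param n_replicates,barcodes_per_construct,dna_depth,rna_depth,dispersion
#'   Sequencing model: depths are expected reads per barcode; `dispersion`
#'   is the negative binomial size of DNA counts.
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @param read_length Length of the simulated first read.
#' @param binding List with logistic coefficients `a`, `b`, `c`, motif
#'   score distribution `score_mean`/`score_sd`, OE range `oe_max`, and
#'   ChIP enrichment means/SD for bound and unbound windows.
#' @param methylation List with logistic `intercept` and `slope` (per OE
#'   unit) of the per-CpG methylation probability, and `coverage`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_promoters = 20L,
                       promoter_length = 600L,
                       gc = 0.55,
                       target_oe = NULL,
                       oe_tolerance = 0.05,
                       motif_set = NULL,
                       motif_prob = 0.5,
                       beta0 = -3,
                       beta_oe = 4,
                       sigma = 0.25,
                       motif_effects = numeric(0L),
                       n_replicates = 3L,
                       barcodes_per_construct = 8L,
                       dna_depth = 200,
                       rna_depth = 200,
                       dispersion = 10,
                       error_rate = 0,
                       read_length = 300L,
                       binding = list(a = -6, b = 0.4, c = 4,
                                      score_mean = 8, score_sd = 4,
                                      oe_max = 1.2,
                                      enrich_bound_mean = 4.5,
                                      enrich_unbound_mean = 0.5,
                                      enrich_sd = 1),
                       methylation = list(intercept = 2, slope = -6,
                                          coverage = 30L)) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(error_rate >= 0, error_rate <= 0.1, sigma >= 0,
            dna_depth >= 0, rna_depth >= 0, dispersion > 0,
            gc > 0, gc < 1, n_replicates >= 1L,
            barcodes_per_construct >= 1L)
  if (!is.null(target_oe) &&
      (any(target_oe <= 0) || any(target_oe > 2)))
    stop("target_oe must lie in (0, 2]", call. = FALSE)
  structure(list(seed = as.integer(seed), n_promoters = as.integer(n_promoters),
                 promoter_length = as.integer(promoter_length), gc = gc,
                 target_oe = target_oe, oe_tolerance = oe_tolerance,
                 motif_set = motif_set, motif_prob = motif_prob,
                 beta0 = beta0, beta_oe = beta_oe, sigma = sigma,
                 motif_effects = motif_effects,
                 n_replicates = as.integer(n_replicates),
                 barcodes_per_construct = as.integer(barcodes_per_construct),
                 dna_depth = dna_depth, rna_depth = rna_depth,
                 dispersion = dispersion, error_rate = error_rate,
                 read_length = as.integer(read_length),
                 binding = binding, methylation = methylation),
            class = "sim_config")
}

# Iteratively insert/remove CG dinucleotides at random unmasked positions
# until the whole-sequence OE lands within tolerance of the target.
adjust_oe <- function(ch, target, tol, mask = NULL, max_iter = 20000L) {
  L <- length(ch)
  if (is.null(mask)) mask <- logical(L)
  strip_all <- target <= tol
  for (iter in seq_len(max_iter)) {
    s <- chars_seq(ch)
    oe <- normalized_cpg_density(s)
    if (strip_all) {
      pos <- cpg_positions(s) + 1L
      pos <- pos[!mask[pos] & !mask[pos + 1L]]
      if (!length(pos)) return(ch)
      ch[pos] <- "A"
      next
    }
    if (abs(oe - target) <= tol) return(ch)
    if (oe < target) {
      elig <- which(!mask[seq_len(L - 1L)] & !mask[2L:L])
      if (!length(elig))
        stop("no unmasked position available to raise CpG density", call. = FALSE)
      p <- elig[sample.int(length(elig), 1L)]
      ch[p] <- "C"; ch[p + 1L] <- "G"
    } else {
      pos <- cpg_positions(s) + 1L
      pos <- pos[!mask[pos] & !mask[pos + 1L]]
      if (!length(pos))
        stop("no unmasked CpG available to lower CpG density", call. = FALSE)
      p <- pos[sample.int(length(pos), 1L)]
      ch[p] <- "A"
    }
  }
  stop("could not reach the target CpG density within ", max_iter,
       " adjustment steps", call. = FALSE)
}

#' Generate promoters with controlled CpG density
#'
#' Draws random sequences at the configured G+C content, optionally embeds
#' consensus motifs (recorded as bound annotations and protected from
#' density adjustment), and then inserts or removes CG dinucleotides at
#' random unmasked positions until each promoter's normalized CpG density
#' is within `oe_tolerance` of its target. Default targets follow a
#' bimodal low/high mixture; targets at or below the tolerance strip all
#' unmasked CpGs.
#'
#' @param config A [sim_config()].
#' @return List with `promoters` (named list of [promoter_record()]) and
#'   `truth` (data frame `id`, `target_oe`, `oe`).
#' @export
gen_promoters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_promoters
    L <- config$promoter_length
    targets <- config$target_oe
    if (is.null(targets)) {
      hi <- stats::runif(n, 0.6, 1.2)
      lo <- stats::runif(n, 0.08, 0.35)
      targets <- ifelse(stats::runif(n) < 0.5, lo, hi)
    } else {
      targets <- rep_len(targets, n)
    }
    recs <- vector("list", n)
    achieved <- numeric(n)
    for (i in seq_len(n)) {
      ch <- random_dna_chars(L, config$gc)
      mask <- logical(L)
      motifs <- NULL
      if (!is.null(config$motif_set)) {
        ann <- list()
        for (tf in names(config$motif_set)) {
          if (stats::runif(1L) >= config$motif_prob) next
          m <- check_dna(config$motif_set[[tf]])
          w <- nchar(m)
          free <- which(!vapply(seq_len(L - w + 1L), function(s)
            any(mask[s:(s + w - 1L)]), logical(1L)))
          if (!length(free)) next
          s <- free[sample.int(length(free), 1L)]
          ch[s:(s + w - 1L)] <- seq_chars(m)
          mask[s:(s + w - 1L)] <- TRUE
          ann[[length(ann) + 1L]] <- data.frame(
            tf = tf, start = s - 1L, end = s - 1L + w, bound = TRUE,
            score = NA_real_, stringsAsFactors = FALSE)
        }
        if (length(ann)) motifs <- do.call(rbind, ann)
      }
      ch <- adjust_oe(ch, targets[i], config$oe_tolerance, mask)
      id <- sprintf("prom%03d", i)
      recs[[i]] <- promoter_record(id, chars_seq(ch), motifs = motifs)
      achieved[i] <- normalized_cpg_density(recs[[i]]$sequence)
    }
    names(recs) <- vapply(recs, `[[`, character(1L), "id")
    list(promoters = recs,
         truth = data.frame(id = names(recs), target_oe = targets,
                            oe = achieved, stringsAsFactors = FALSE))
  })
}

#' Ground-truth log2 activities from the linear density model
#'
#' `true = beta0 + beta_oe * OE + sum(motif effects of intact motifs) +
#' N(0, sigma)`. Motif effects are added for each TF listed in the
#' optional `intact_tfs` column (semicolon-joined names) that has an entry
#' in `config$motif_effects`.
#'
#' @param manifest Data frame with columns `construct_id`, `oe`, and
#'   optionally `intact_tfs`.
#' @param config A [sim_config()].
#' @return Data frame with columns `construct_id`, `oe`,
#'   `true_log2_activity`.
#' @export
gen_true_activities <- function(manifest, config) {
  stopifnot(inherits(config, "sim_config"),
            all(c("construct_id", "oe") %in% names(manifest)))
  withr::with_seed(config$seed + 1L, {
    mu <- config$beta0 + config$beta_oe * manifest$oe
    if ("intact_tfs" %in% names(manifest) && length(config$motif_effects)) {
      mu <- mu + vapply(manifest$intact_tfs, function(s) {
        tfs <- strsplit(s, ";", fixed = TRUE)[[1L]]
        sum(config$motif_effects[tfs[tfs %in% names(config$motif_effects)]])
      }, numeric(1L), USE.NAMES = FALSE)
    }
    data.frame(construct_id = manifest$construct_id, oe = manifest$oe,
               true_log2_activity = mu + stats::rnorm(nrow(manifest), 0, config$sigma),
               stringsAsFactors = FALSE)
  })
}

#' Simulate DNA/RNA barcode counts
#'
#' Assigns `barcodes_per_construct` pattern barcodes to each construct.
#' Per replicate and barcode, a latent abundance `a ~ Gamma(4, 4)` (mean 1)
#' models library bottlenecking; DNA counts are negative binomial with mean
#' `dna_depth * a` and size `dispersion`, and RNA counts are Poisson with
#' mean `rna_depth * a * 2^true_activity`, so the expected RNA/DNA ratio is
#' proportional to `2^true`. Replicates are independent.
#'
#' @param truth Data frame from [gen_true_activities()].
#' @param config A [sim_config()].
#' @return List with `counts` (long data frame `barcode`, `sample`,
#'   `replicate`, `count`), `barcode_map` (`barcode`, `promoter`), and
#'   `truth` (per-barcode, with `barcode`, `construct_id`,
#'   `true_log2_activity`).
#' @export
gen_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  bpc <- config$barcodes_per_construct
  n_bc <- nrow(truth) * bpc
  bcs <- generate_barcodes(n_bc, seed = config$seed + 6L)
  map <- data.frame(barcode = bcs,
                    promoter = rep(truth$construct_id, each = bpc),
                    stringsAsFactors = FALSE)
  true_bc <- rep(truth$true_log2_activity, each = bpc)
  withr::with_seed(config$seed + 2L, {
    out <- lapply(seq_len(config$n_replicates), function(r) {
      a <- stats::rgamma(n_bc, shape = 4, rate = 4)
      dna <- stats::rnbinom(n_bc, mu = config$dna_depth * a,
                            size = config$dispersion)
      rna <- stats::rpois(n_bc, lambda = config$rna_depth * a * 2^true_bc)
      rbind(
        data.frame(barcode = bcs, sample = "DNA", replicate = r, count = dna,
                   stringsAsFactors = FALSE),
        data.frame(barcode = bcs, sample = "RNA", replicate = r, count = rna,
                   stringsAsFactors = FALSE)
      )
    })
    list(counts = do.call(rbind, out), barcode_map = map,
         truth = data.frame(barcode = bcs,
                            construct_id = rep(truth$construct_id, each = bpc),
                            true_log2_activity = true_bc,
                            stringsAsFactors = FALSE))
  })
}

add_substitution_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  vapply(reads, function(s) {
    L <- nchar(s)
    k <- stats::rbinom(1L, L, rate)
    if (k == 0L) return(s)
    pos <- sample.int(L, k)
    ch <- seq_chars(s)
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(.BASES, b), 1L), character(1L))
    chars_seq(ch)
  }, character(1L), USE.NAMES = FALSE)
}

#' Simulate paired reads for barcode-to-construct assignment
#'
#' Read 1 carries the first `read_length` bases of the construct; read 2
#' carries the barcode between its fixed anchors. Substitution errors are
#' i.i.d. per base at `config$error_rate`. The returned truth table maps
#' each read to its construct and barcode.
#'
#' @param references Named character vector of construct sequences.
#' @param barcode_assignments Data frame with columns `barcode`,
#'   `promoter` mapping each barcode to its construct.
#' @param config A [sim_config()].
#' @param n_reads Total number of read pairs (spread uniformly over
#'   barcodes).
#' @param pattern A [barcode_pattern()] supplying the read-2 anchors.
#' @return List with `read1`, `read2` (named character vectors) and
#'   `truth` (data frame `read`, `construct_id`, `barcode`).
#' @export
gen_reads <- function(references, barcode_assignments, config, n_reads,
                      pattern = barcode_pattern()) {
  stopifnot(inherits(config, "sim_config"),
            all(barcode_assignments$promoter %in% names(references)))
  rl <- min(config$read_length, min(nchar(references)))
  withr::with_seed(config$seed + 3L, {
    pick <- sample.int(nrow(barcode_assignments), n_reads, replace = TRUE)
    bc <- barcode_assignments$barcode[pick]
    cons <- barcode_assignments$promoter[pick]
    ids <- sprintf("read%06d", seq_len(n_reads))
    r1 <- substr(references[cons], 1L, rl)
    r2 <- paste0(pattern$up_anchor, bc, pattern$down_anchor)
    r1 <- add_substitution_errors(r1, config$error_rate)
    r2 <- add_substitution_errors(r2, config$error_rate)
    names(r1) <- ids; names(r2) <- ids
    list(read1 = r1, read2 = r2,
         truth = data.frame(read = ids, construct_id = cons, barcode = bc,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate genomic windows under the additive logistic binding model
#'
#' Motif scores are normal, CpG densities uniform on
#' `[0, binding$oe_max]`; the bound flag is Bernoulli with
#' `logit P = a + b * score + c * oe`, and the ChIP log2 enrichment is
#' drawn from the bound or unbound normal so that [call_bound()] at 2.5
#' approximately reproduces the labels (the achieved consistency is stored
#' in the `label_consistency` attribute).
#'
#' @param config A [sim_config()].
#' @param n Number of windows (>= 100).
#' @return Data frame with columns `id`, `oe`, `motif_score`,
#'   `chip_log2_enrichment`, `bound`, `prob`.
#' @export
gen_binding_windows <- function(config, n) {
  stopifnot(inherits(config, "sim_config"), n >= 100L)
  b <- config$binding
  withr::with_seed(config$seed + 4L, {
    score <- stats::rnorm(n, b$score_mean, b$score_sd)
    oe <- stats::runif(n, 0, b$oe_max)
    prob <- stats::plogis(b$a + b$b * score + b$c * oe)
    bound <- stats::rbinom(n, 1L, prob) == 1L
    enr <- stats::rnorm(n, ifelse(bound, b$enrich_bound_mean,
                                  b$enrich_unbound_mean), b$enrich_sd)
    out <- data.frame(id = sprintf("win%05d", seq_len(n)), oe = oe,
                      motif_score = score, chip_log2_enrichment = enr,
                      bound = bound, prob = prob, stringsAsFactors = FALSE)
    attr(out, "label_consistency") <- mean(call_bound(enr) == bound)
    out
  })
}

#' Simulate bisulfite methylation calls
#'
#' Per CpG of each construct, the methylation probability is logistic and
#' decreasing in the construct's normalized CpG density
#' (`plogis(intercept + slope * OE)` with a negative slope); totals are
#' fixed at the configured coverage and methylated counts are binomial.
#'
#' @param references Named character vector of construct sequences.
#' @param config A [sim_config()].
#' @return Data frame with columns `promoter`, `cpg_position`,
#'   `n_methylated`, `n_total`.
#' @export
gen_methylation_calls <- function(references, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$methylation
  withr::with_seed(config$seed + 5L, {
    rows <- lapply(names(references), function(id) {
      s <- references[[id]]
      pos <- cpg_positions(s)
      if (!length(pos)) return(NULL)
      p <- stats::plogis(m$intercept + m$slope * normalized_cpg_density(s))
      data.frame(promoter = id, cpg_position = pos,
                 n_methylated = stats::rbinom(length(pos), m$coverage, p),
                 n_total = m$coverage, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
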