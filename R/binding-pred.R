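# CpG-density-aware TF binding prediction: PWM log-odds scanning, tiled
# genomic windows, binding calls from ChIP enrichment, subset statistics,
# the additive logistic motif+density model, and precision-recall curves.

#' Position weight matrix
#'
#' Per-position base probabilities (rows = positions, columns = A, C, G,
#' T). Cells are regularised by adding a pseudo-probability of 1e-3 and
#' renormalising, so log-odds scores stay finite.
#'
#' @param matrix Numeric matrix, one row per motif position, four columns
#'   in A, C, G, T order; each row must sum to 1 (tolerance 1e-6).
#' @param name TF identifier.
#' @return An object of class `pwm` with the regularised probability matrix
#'   and its log2 odds against a uniform background.
#' @export
pwm <- function(matrix, name = "motif") {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L)
    stop("a PWM needs four columns (A, C, G, T)", call. = FALSE)
  if (any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-6))
    stop("each PWM row must be a probability distribution summing to 1",
         call. = FALSE)
  reg <- (matrix + 1e-3) / (1 + 4e-3)
  colnames(reg) <- .BASES
  structure(list(name = name, matrix = reg, width = nrow(reg),
                 log2odds = log2(reg / 0.25)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, max score %.2f\n", x$name, x$width,
              sum(apply(x$log2odds, 1L, max))))
  invisible(x)
}

#' Read a PWM from text
#'
#' Format: a header line `>NAME` followed by one whitespace-separated row
#' of four probabilities (A C G T) per motif position.
#'
#' @param path File path.
#' @return A [pwm()].
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "motif"
  if (startsWith(lines[1L], ">")) {
    name <- trimws(sub("^>", "", lines[1L]))
    lines <- lines[-1L]
  }
  mat <- do.call(rbind, lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  pwm(mat, name)
}

#' Write a PWM to text
#'
#' @param x A [pwm()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  writeLines(c(paste0(">", x$name),
               apply(x$matrix, 1L, function(r)
                 paste(format(r, digits = 15), collapse = "\t"))),
             path)
  invisible(path)
}

#' Best PWM log-odds score in a window
#'
#' Maximum over all offsets (and, by default, both strands) of the log2
#' log-odds score against a uniform background,
#' `sum_i log2(p_i(base_i) / 0.25)`. The reverse strand is scored on the
#' reverse complement. Returns `-Inf` when the window is shorter than the
#' motif.
#'
#' @param sequence A single window sequence.
#' @param pwm A [pwm()].
#' @param both_strands Score the reverse complement too (default `TRUE`).
#' @return Best log2 log-odds score (scalar).
#' @export
logodds_scan <- function(sequence, pwm, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"))
  stopifnot_scalar_seq(sequence)
  sequence <- check_dna(sequence)
  best <- scan_one_strand(sequence, pwm)
  if (both_strands)
    best <- max(best, scan_one_strand(revcomp(sequence), pwm))
  best
}

scan_one_strand <- function(sequence, pwm) {
  L <- nchar(sequence)
  w <- pwm$width
  if (L < w) return(-Inf)
  idx <- match(seq_chars(sequence), .BASES)
  n_off <- L - w + 1L
  s <- numeric(n_off)
  for (j in seq_len(w))
    s <- s + pwm$log2odds[j, idx[j:(j + n_off - 1L)]]
  max(s)
}

#' Tile a span into fixed-size windows
#'
#' Non-overlapping consecutive windows; a trailing remainder shorter than
#' `window_size` is dropped.
#'
#' @param span_length Total span in nt.
#' @param window_size Window width in nt (default 600).
#' @param offset 0-based start of the span.
#' @return Data frame with columns `id`, `start`, `end` (0-based,
#'   half-open).
#' @export
tile_windows <- function(span_length, window_size = 600L, offset = 0L) {
  window_size <- as.integer(window_size)
  stopifnot(window_size >= 1L)
  k <- span_length %/% window_size
  start <- offset + (seq_len(k) - 1L) * window_size
  data.frame(id = sprintf("win%05d", seq_len(k)),
             start = start, end = start + window_size,
             stringsAsFactors = FALSE)
}

#' Call bound windows from ChIP enrichment
#'
#' @param chip_log2_enrichment Numeric vector of log2 enrichments over
#'   input.
#' @param enrichment_threshold Strict threshold (default 2.5).
#' @return Logical vector: bound iff enrichment strictly exceeds the
#'   threshold.
#' @export
call_bound <- function(chip_log2_enrichment, enrichment_threshold = 2.5) {
  chip_log2_enrichment > enrichment_threshold
}

#' Bound fraction and recall per window subset
#'
#' Evaluates the four standard subsets — all windows, windows with a motif
#' scoring at least `motif_threshold`, windows with normalized CpG density
#' at least `oe_threshold`, and windows with both — reporting each subset's
#' bound fraction and its recall (bound windows in the subset / all bound
#' windows).
#'
#' @param windows Data frame with columns `oe`, `motif_score`, `bound`.
#' @param motif_threshold Minimum best motif log-odds score (default 12).
#' @param oe_threshold Minimum normalized CpG density (default 0.6).
#' @return Data frame with columns `subset`, `n`, `n_bound`,
#'   `bound_fraction` (`NA` for an empty subset), `recall`.
#' @export
subset_stats <- function(windows, motif_threshold = 12, oe_threshold = 0.6) {
  stopifnot(all(c("oe", "motif_score", "bound") %in% names(windows)))
  sel <- list(
    all = rep(TRUE, nrow(windows)),
    motif = windows$motif_score >= motif_threshold,
    oe = windows$oe >= oe_threshold,
    motif_oe = windows$motif_score >= motif_threshold &
      windows$oe >= oe_threshold
  )
  total_bound <- sum(windows$bound)
  do.call(rbind, lapply(names(sel), function(nm) {
    s <- sel[[nm]]
    n <- sum(s)
    nb <- sum(windows$bound & s)
    data.frame(subset = nm, n = n, n_bound = nb,
               bound_fraction = if (n > 0L) nb / n else NA_real_,
               recall = if (total_bound > 0L) nb / total_bound else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Fit the additive logistic binding model
#'
#' Maximum-likelihood logistic regression of the bound flag on the best
#' motif score and the normalized CpG density:
#' `logit P(bound) = a + b * motif_score + c * oe`. Complete separation is
#' flagged and, when the glmnet package is available, refit with a light
#' ridge penalty.
#'
#' @param windows Data frame with columns `bound`, `motif_score`, `oe`.
#' @return An object of class `logistic_binding_model` with elements
#'   `intercept`, `coef_motif`, `coef_oe`, `separation`, `fit`.
#' @export
fit_logistic <- function(windows) {
  stopifnot(all(c("bound", "motif_score", "oe") %in% names(windows)))
  y <- as.integer(windows$bound)
  if (length(unique(y)) < 2L)
    stop("both bound and unbound windows are required to fit the model",
         call. = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ motif_score + oe, data = windows, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (separation) {
    if (requireNamespace("glmnet", quietly = TRUE)) {
      warning("complete separation detected; refitting with a ridge penalty",
              call. = FALSE)
      x <- as.matrix(windows[, c("motif_score", "oe")])
      rf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = 1e-3)
      cf <- c(as.numeric(rf$a0),
              as.numeric(glmnet::coef.glmnet(rf)[c("motif_score", "oe"), ]))
      names(cf) <- c("(Intercept)", "motif_score", "oe")
    } else {
      warning("complete separation detected; coefficients are unreliable",
              call. = FALSE)
    }
  }
  structure(list(intercept = unname(cf["(Intercept)"]),
                 coef_motif = unname(cf["motif_score"]),
                 coef_oe = unname(cf["oe"]),
                 separation = separation, fit = fit),
            class = "logistic_binding_model")
}

#' @export
print.logistic_binding_model <- function(x, ...) {
  cat(sprintf("logistic binding model: logit P = %.3f + %.3f * motif + %.3f * oe%s\n",
              x$intercept, x$coef_motif, x$coef_oe,
              if (x$separation) " (separation flagged)" else ""))
  invisible(x)
}

#' @export
predict.logistic_binding_model <- function(object, newdata, ...) {
  stats::plogis(object$intercept +
                  object$coef_motif * newdata$motif_score +
                  object$coef_oe * newdata$oe)
}

#' Precision-recall curve over equally spaced cutoffs
#'
#' For each of `n_cutoffs` values equally spaced from the minimum to the
#' maximum of `score`, computes precision (fraction of windows with score
#' greater than or equal to the cutoff that are bound) and recall (bound
#' windows at or above the cutoff divided by all bound windows). At the
#' minimum cutoff recall is 1 and precision equals the overall bound
#' fraction.
#'
#' @param score Numeric vector (e.g. `oe`, `motif_score`, or a model
#'   probability).
#' @param bound Logical vector.
#' @param n_cutoffs Number of cutoffs (default 100).
#' @param score_name Label stored with the curve.
#' @return Data frame of class `pr_curve` with columns `cutoff`,
#'   `precision`, `recall`.
#' @export
pr_curve <- function(score, bound, n_cutoffs = 100L,
                     score_name = deparse(substitute(score))) {
  stopifnot(length(score) == length(bound))
  if (!any(bound))
    stop("at least one bound window is required for a precision-recall curve",
         call. = FALSE)
  cutoffs <- seq(min(score), max(score), length.out = n_cutoffs)
  total_bound <- sum(bound)
  precision <- numeric(n_cutoffs)
  recall <- numeric(n_cutoffs)
  for (i in seq_len(n_cutoffs)) {
    sel <- score >= cutoffs[i]
    precision[i] <- sum(bound[sel]) / sum(sel)
    recall[i] <- sum(bound[sel]) / total_bound
  }
  structure(data.frame(cutoff = cutoffs, precision = precision,
                       recall = recall),
            class = c("pr_curve", "data.frame"), score_name = score_name)
}

#' Area under a precision-recall curve
#'
#' Trapezoidal area over the recall axis. The curve is anchored at recall
#' 0 with the precision of its lowest-recall point, so scores whose recall
#' never drops below a plateau (e.g. a perfectly separating score) still
#' integrate over the full recall range.
#'
#' @param curve A [pr_curve()].
#' @return Scalar area.
#' @export
pr_auc <- function(curve) {
  # ascending recall; among equal recalls the most stringent cutoff sits
  # next to the recall-0 anchor
  o <- order(curve$recall, -curve$cutoff)
  r <- c(0, curve$recall[o])
  p <- c(curve$precision[nrow(curve)], curve$precision[o])
  sum(diff(r) * (p[-1L] + p[-length(p)]) / 2)
}
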