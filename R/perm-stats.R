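# Spearman rank correlation with approximate and exact permutation
# significance, and replicate-wise correlation summaries.

check_corr_input <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("at least 3 paired observations are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for a constant vector", call. = FALSE)
  invisible(NULL)
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  check_corr_input(x, y)
  stats::cor(x, y, method = "spearman")
}

new_perm_result <- function(rho, p, n_perm, mode, seed, alternative) {
  structure(list(rho = rho, p_value = p, n_permutations = n_perm,
                 mode = mode, seed = seed, alternative = alternative),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s permutation test: rho = %.4f, p = %.4g (%s, %s permutations)\n",
              x$mode, x$rho, x$p_value, x$alternative,
              format(x$n_permutations, big.mark = ",")))
  invisible(x)
}

# numerical guard for |rho_perm| == |rho_obs| comparisons in floating point
.RHO_EPS <- 1e-12

perm_count <- function(rho_perm, rho_obs, alternative) {
  switch(alternative,
         two.sided = sum(abs(rho_perm) >= abs(rho_obs) - .RHO_EPS),
         greater = sum(rho_perm >= rho_obs - .RHO_EPS),
         less = sum(rho_perm <= rho_obs + .RHO_EPS))
}

#' Approximate (Monte Carlo) permutation test for Spearman correlation
#'
#' Permutes `y` `n_perm` times and compares the permuted coefficients with
#' the observed one. The reported p-value uses the add-one correction
#' `p = (1 + k) / (1 + n_perm)`, which is never zero and gives a valid
#' test.
#'
#' @inheritParams spearman_rho
#' @param n_perm Number of random permutations (>= 100; default 9999).
#' @param seed Integer seed (required; permutations are reproducible).
#' @param alternative `"two.sided"` (on `|rho|`, default), `"greater"`, or
#'   `"less"`.
#' @return An object of class `perm_test`.
#' @export
perm_test_approx <- function(x, y, n_perm = 9999L, seed,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_corr_input(x, y)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L)
    stop("n_perm must be at least 100", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n <- length(x)
  rxc <- rank(x); rxc <- rxc - mean(rxc)
  ryc <- rank(y); ryc <- ryc - mean(ryc)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  rho_obs <- sum(rxc * ryc) / denom
  rho_perm <- withr::with_seed(seed,
    vapply(seq_len(n_perm),
           function(i) sum(rxc * ryc[sample.int(n)]), numeric(1L))) / denom
  k <- perm_count(rho_perm, rho_obs, alternative)
  new_perm_result(rho_obs, (1 + k) / (1 + n_perm), n_perm, "approximate",
                  seed, alternative)
}

# all permutations of 1..n as an n! x n integer matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * m + 1L):(i * m)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], m, n - 1L)
  }
  out
}

#' Exact permutation test for Spearman correlation
#'
#' Enumerates all `n!` permutations of `y` (the identity included) and
#' reports the exact proportion with a coefficient at least as extreme as
#' the observed one. Restricted to small samples; above `max_n` an error
#' directs to the approximate test.
#'
#' @inheritParams perm_test_approx
#' @param max_n Largest sample size to enumerate exhaustively (default 9,
#'   i.e. at most 362,880 permutations).
#' @return An object of class `perm_test`.
#' @export
perm_test_exact <- function(x, y,
                            alternative = c("two.sided", "greater", "less"),
                            max_n = 9L) {
  alternative <- match.arg(alternative)
  check_corr_input(x, y)
  n <- length(x)
  if (n > max_n)
    stop("n = ", n, " exceeds the exhaustive bound (", max_n,
         "); use perm_test_approx()", call. = FALSE)
  rxc <- rank(x); rxc <- rxc - mean(rxc)
  ryc <- rank(y); ryc <- ryc - mean(ryc)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  rho_obs <- sum(rxc * ryc) / denom
  pm <- all_permutations(n)
  rho_perm <- as.numeric(matrix(ryc[pm], nrow(pm), n) %*% rxc) / denom
  k <- perm_count(rho_perm, rho_obs, alternative)
  new_perm_result(rho_obs, k / nrow(pm), nrow(pm), "exact", NA_integer_,
                  alternative)
}

#' Replicate-wise Spearman correlation with pooled permutation significance
#'
#' Computes the correlation separately within each replicate, reports the
#' mean and standard deviation across replicates, and tests significance by
#' permuting `y` within each replicate and comparing the mean permuted
#' coefficient with the observed mean (add-one corrected).
#'
#' @param x,y Numeric vectors.
#' @param replicate Replicate labels (same length).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed (required).
#' @param alternative As in [perm_test_approx()].
#' @return List of class `replicate_correlation` with `rho_by_replicate`,
#'   `mean_rho`, `sd_rho`, `p_value`, `n_permutations`, `alternative`.
#' @export
replicate_correlation <- function(x, y, replicate, n_perm = 9999L, seed,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(length(x) == length(y), length(x) == length(replicate))
  xs <- split(x, replicate); ys <- split(y, replicate)
  prep <- lapply(names(xs), function(r) {
    check_corr_input(xs[[r]], ys[[r]])
    rxc <- rank(xs[[r]]); rxc <- rxc - mean(rxc)
    ryc <- rank(ys[[r]]); ryc <- ryc - mean(ryc)
    list(rxc = rxc, ryc = ryc,
         denom = sqrt(sum(rxc^2) * sum(ryc^2)))
  })
  names(prep) <- names(xs)
  rho_r <- vapply(prep, function(p) sum(p$rxc * p$ryc) / p$denom, numeric(1L))
  obs <- mean(rho_r)
  perm_means <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i)
    mean(vapply(prep, function(p)
      sum(p$rxc * p$ryc[sample.int(length(p$ryc))]) / p$denom,
      numeric(1L))), numeric(1L)))
  k <- perm_count(perm_means, obs, alternative)
  structure(list(rho_by_replicate = rho_r, mean_rho = obs,
                 sd_rho = if (length(rho_r) > 1L) stats::sd(rho_r) else NA_real_,
                 p_value = (1 + k) / (1 + n_perm),
                 n_permutations = n_perm, alternative = alternative),
            class = "replicate_correlation")
}

#' @export
print.replicate_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f +/- %.3f (%d replicates), permutation p = %.4g\n",
              x$mean_rho, x$sd_rho, length(x$rho_by_replicate), x$p_value))
  invisible(x)
}
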