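# Summaries of per-CpG bisulfite methylation calls.

#' Per-CpG methylation fraction
#'
#' @param n_methylated,n_total Integer vectors of methylated and total
#'   calls per CpG (`0 <= n_methylated <= n_total`).
#' @return Numeric vector of fractions; `NA` where `n_total` is 0 (such
#'   CpGs are excluded by [promoter_methylation()]).
#' @export
cpg_methylation <- function(n_methylated, n_total) {
  stopifnot(length(n_methylated) == length(n_total))
  if (any(n_methylated < 0) || any(n_methylated > n_total))
    stop("n_methylated must lie in [0, n_total]", call. = FALSE)
  ifelse(n_total > 0, n_methylated / n_total, NA_real_)
}

#' Per-promoter methylation level
#'
#' The unweighted mean of the per-CpG methylation fractions over the CpGs
#' with coverage of at least `min_coverage`; CpGs below the coverage floor
#' are excluded, and promoters with no covered CpG are dropped with a
#' message.
#'
#' @param calls Data frame with columns `promoter`, `cpg_position`,
#'   `n_methylated`, `n_total`.
#' @param min_coverage Minimum total calls for a CpG to contribute
#'   (default 1).
#' @return Data frame with columns `promoter`, `n_cpgs`,
#'   `mean_methylation`.
#' @export
promoter_methylation <- function(calls, min_coverage = 1L) {
  stopifnot(all(c("promoter", "n_methylated", "n_total") %in% names(calls)))
  calls$frac <- cpg_methylation(calls$n_methylated, calls$n_total)
  keep <- !is.na(calls$frac) & calls$n_total >= min_coverage
  dropped <- setdiff(unique(calls$promoter), unique(calls$promoter[keep]))
  if (length(dropped))
    message("dropping ", length(dropped),
            " promoter(s) with no covered CpG: ",
            paste(dropped, collapse = ", "))
  grp <- split(calls$frac[keep], calls$promoter[keep])
  data.frame(promoter = names(grp),
             n_cpgs = vapply(grp, length, integer(1L)),
             mean_methylation = vapply(grp, mean, numeric(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}
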