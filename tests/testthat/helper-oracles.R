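# Independent oracles and small fixture builders used across the suite.

# Brute-force composition statistics by explicit dinucleotide enumeration.
brute_oe <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  n_cpg <- 0L
  for (i in seq_len(n - 1L))
    if (ch[i] == "C" && ch[i + 1L] == "G") n_cpg <- n_cpg + 1L
  n_c <- sum(ch == "C")
  n_g <- sum(ch == "G")
  if (n_c * n_g == 0) return(0)
  n_cpg / (n_c * n_g) * n
}

brute_gc <- function(s) {
  ch <- strsplit(s, "")[[1]]
  mean(ch %in% c("C", "G"))
}

rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                        collapse = "")

rand_seq <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

# Exhaustive PWM scan: every offset on both strands, position-by-position.
brute_pwm_scan <- function(s, p) {
  score_at <- function(seqv, off) {
    sc <- 0
    for (j in seq_len(p$width))
      sc <- sc + p$log2odds[j, match(seqv[off + j - 1L], c("A", "C", "G", "T"))]
    sc
  }
  best <- -Inf
  for (strand_seq in c(s, rc(s))) {
    ch <- strsplit(strand_seq, "")[[1]]
    if (length(ch) < p$width) next
    for (off in seq_len(length(ch) - p$width + 1L))
      best <- max(best, score_at(ch, off))
  }
  best
}

rand_pwm <- function(width, name = "rand") {
  m <- matrix(runif(width * 4), width, 4)
  pwm(m / rowSums(m), name)
}

# A 420-bp promoter with a CpG every 10 bp and no motif annotations.
toy_promoter <- function(n_rep = 42L, id = "toy") {
  promoter_record(id, paste(rep("ACGTATATAT", n_rep), collapse = ""))
}
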