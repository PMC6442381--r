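make_promoter_with_cpg_at_10 <- function(motifs = NULL) {
  promoter_record("p", paste0(strrep("A", 10), "CG", strrep("A", 8)),
                  motifs = motifs)
}

test_that("mutable CpGs exclude only bound-motif overlaps", {
  bound <- data.frame(tf = "X", start = 8, end = 14, bound = TRUE)
  expect_identical(mutable_cpgs(make_promoter_with_cpg_at_10(bound)),
                   integer(0))
  touch <- data.frame(tf = "X", start = 11, end = 17, bound = TRUE)
  expect_identical(mutable_cpgs(make_promoter_with_cpg_at_10(touch)),
                   integer(0))
  unbound <- data.frame(tf = "X", start = 8, end = 14, bound = FALSE)
  expect_identical(mutable_cpgs(make_promoter_with_cpg_at_10(unbound)), 10L)
  expect_identical(mutable_cpgs(make_promoter_with_cpg_at_10()), 10L)
})

test_that("window combinations enumerate 2^k substitution-only constructs", {
  p <- toy_promoter()
  w5 <- data.frame(start = c(0, 100, 200, 300, 400),
                   end = c(100, 200, 300, 400, 420))
  lib <- window_combination_library(p, w5, "T")
  expect_length(lib, 32L)
  expect_identical(lib[[1]]$sequence, p$sequence)  # all-WT combination
  expect_true(all(vapply(lib, function(x) nchar(x$sequence), 1L) ==
                    nchar(p$sequence)))
  # all-mutant combination has no CpG left in any window
  allmut <- lib[[32]]
  expect_identical(count_cpgs(allmut$sequence), 0L)
  expect_true(all(vapply(lib, function(x)
    all(strsplit(x$sequence, "")[[1]][x$mutated_positions + 1] == "T"),
    TRUE)))
  expect_length(window_combination_library(p, w5[1:4, ]), 16L)
  expect_length(window_combination_library(p, w5[0, ]), 1L)
  expect_error(window_combination_library(
    p, data.frame(start = c(0, 50), end = c(100, 150))), "overlap")
})

test_that("bound-motif CpGs survive every window combination", {
  seqs <- paste(rep("ACGTATATAT", 42), collapse = "")
  p <- promoter_record("p", seqs,
                       motifs = data.frame(tf = "X", start = 100, end = 110,
                                           bound = TRUE))
  lib <- window_combination_library(
    p, data.frame(start = c(0, 100, 200), end = c(100, 200, 300)))
  for (x in lib)
    expect_identical(substr(x$sequence, 101, 110), substr(seqs, 101, 110))
})

test_that("density series retains round(p * n) CpGs and is seed-stable", {
  # 35 mutable CpGs; retention 0.657 must keep 23 and mutate 12
  p35 <- promoter_record("p35", paste(rep("ACGTATATAT", 35), collapse = ""))
  expect_length(mutable_cpgs(p35), 35L)
  lib <- density_series_library(p35, c(0, 0.657, 1), "A", seed = 3)
  expect_identical(count_cpgs(lib[[1]]$sequence), 0L)
  expect_length(lib[[2]]$mutated_positions, 12L)
  expect_identical(count_cpgs(lib[[2]]$sequence), 23L)
  expect_identical(lib[[3]]$sequence, p35$sequence)
  again <- density_series_library(p35, c(0, 0.657, 1), "A", seed = 3)
  expect_identical(vapply(lib, `[[`, "", "sequence"),
                   vapply(again, `[[`, "", "sequence"))
  pe <- promoter_record("pe", "ATATATAT")
  expect_error(density_series_library(pe, 0.5, seed = 1), "no mutable CpGs")
})

test_that("density series CpG density is non-decreasing in retention", {
  p <- toy_promoter()
  lib <- density_series_library(p, c(0, 0.25, 0.5, 0.75, 1), "A", seed = 11)
  oes <- vapply(lib, function(x) normalized_cpg_density(x$sequence), 1)
  expect_false(is.unsorted(oes))
  fr <- design_manifest(lib)$retained_cpg_fraction
  expect_equal(fr, c(0, 0.25, 0.5, 0.75, 1))
})

test_that("motif mutation enumerates singles plus per-TF all constructs", {
  s <- paste(rep("ATATATATAT", 40), collapse = "")
  motifs <- data.frame(tf = c("GABPA", "GABPA", "SP1", "SP1"),
                       start = c(20, 60, 120, 160),
                       end = c(30, 70, 130, 170), bound = TRUE)
  p <- promoter_record("p", s, motifs = motifs)
  lib <- motif_mutation_library(p, motifs, seed = 9)
  expect_length(lib, 6L)  # 4 singles + 2 all-motif
  ids <- vapply(lib, `[[`, "", "construct_id")
  expect_setequal(ids, c("p_GABPA_site1", "p_GABPA_site2", "p_SP1_site1",
                         "p_SP1_site2", "p_GABPA_all", "p_SP1_all"))
  # replacements introduce no CpG, junctions included
  for (x in lib) expect_identical(count_cpgs(x$sequence), 0L)
  # a TF with a single motif yields identical single/all sequences
  one <- motif_mutation_library(p, motifs[1, ], seed = 9)
  expect_identical(one[[1]]$sequence, one[[2]]$sequence)
  expect_length(motif_mutation_library(p, motifs[0, ], seed = 9), 0L)
})

test_that("motif mutation destroys the PWM site when a PWM is given", {
  s <- paste0(strrep("AT", 20), "GGGGGGGG", strrep("AT", 20))
  motifs <- data.frame(tf = "G8", start = 40, end = 48, bound = TRUE)
  p <- promoter_record("p", s, motifs = motifs)
  m <- matrix(rep(c(0.01, 0.01, 0.97, 0.01), 8), ncol = 4, byrow = TRUE)
  gpwm <- pwm(m, "G8")
  expect_gt(logodds_scan(s, gpwm), 12)
  lib <- motif_mutation_library(p, motifs, seed = 2, pwms = list(G8 = gpwm))
  expect_lt(logodds_scan(lib[[1]]$sequence, gpwm), 12)
})

test_that("tiling replacements are CpG-free including junctions", {
  p <- toy_promoter()  # 420 bp
  lib <- tiling_replacement_library(p, 10, seed = 21)
  expect_length(lib, 42L)
  for (i in seq_along(lib)) {
    s <- (i - 1) * 10
    e <- i * 10
    window_with_flanks <- substr(lib[[i]]$sequence, max(1, s), min(420, e + 1))
    expect_false(grepl("CG", window_with_flanks, fixed = TRUE))
    # outside the tile the sequence is untouched
    expect_identical(substr(lib[[i]]$sequence, e + 2, 420),
                     substr(p$sequence, e + 2, 420))
  }
  expect_error(tiling_replacement_library(p, 1, seed = 1), ">= 2")
  expect_identical(vapply(tiling_replacement_library(p, 10, seed = 21),
                          `[[`, "", "sequence"),
                   vapply(lib, `[[`, "", "sequence"))
})

test_that("add-back restores WT CpG positions with strictly increasing density", {
  p <- toy_promoter()
  blocks <- data.frame(start = c(0, 200), end = c(100, 300))
  wt_in_blocks <- Filter(function(q)
    (q >= 0 & q + 2 <= 100) | (q >= 200 & q + 2 <= 300),
    cpg_positions(p$sequence))
  n_avail <- length(wt_in_blocks)
  counts <- c(0, 5, 10, n_avail)
  ab <- addback_library(p, blocks, counts, seed = 17)
  base_oe <- normalized_cpg_density(ab$baseline$sequence)
  expect_lt(base_oe, normalized_cpg_density(p$sequence))
  expect_identical(ab$addbacks[[1]]$sequence, ab$baseline$sequence)
  oes <- vapply(ab$addbacks, function(x) normalized_cpg_density(x$sequence), 1)
  expect_true(all(diff(oes) > 0))
  # full add-back restores exactly the WT CpG position set inside the blocks
  full <- ab$addbacks[[length(counts)]]
  pos_full <- cpg_positions(full$sequence)
  expect_setequal(pos_full[(pos_full >= 0 & pos_full + 2 <= 100) |
                             (pos_full >= 200 & pos_full + 2 <= 300)],
                  wt_in_blocks)
  # outside the blocks nothing moved
  expect_identical(substr(full$sequence, 101, 200),
                   substr(p$sequence, 101, 200))
  expect_error(addback_library(p, blocks, n_avail + 1, seed = 1), "counts")
})

test_that("barcode generation honours pattern, distance, and determinism", {
  bcs <- generate_barcodes(60, seed = 4)
  expect_length(unique(bcs), 60L)
  expect_true(all(nchar(bcs) == 15L))
  # W positions (5 and 10, 1-based) are A or T
  expect_true(all(substr(bcs, 5, 5) %in% c("A", "T")))
  expect_true(all(substr(bcs, 10, 10) %in% c("A", "T")))
  dmin <- min(sapply(seq_along(bcs), function(i)
    sapply(seq_along(bcs)[-i], function(j)
      sum(strsplit(bcs[i], "")[[1]] != strsplit(bcs[j], "")[[1]]))))
  expect_gte(dmin, 3L)
  expect_identical(generate_barcodes(60, seed = 4), bcs)
  expect_identical(generate_barcodes(0, seed = 1), character(0))
  expect_equal(barcode_space_size("NNNNWNNNNWNNNNN"), 4^13 * 2^2)
  expect_error(generate_barcodes(17, pattern = "NN", seed = 1,
                                 min_pairwise_distance = 1))
  expect_error(generate_barcodes(16, pattern = "NN", seed = 1,
                                 min_pairwise_distance = 2,
                                 max_tries = 2000), "could not generate")
})
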