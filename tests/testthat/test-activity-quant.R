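test_that("scaling to the smaller total equalises totals and preserves ratios", {
  dna <- c(b1 = 1200000, b2 = 800000)
  rna <- c(b1 = 600000, b2 = 400000)
  sc <- scale_to_smaller(dna, rna)
  expect_equal(sum(sc$dna), sum(sc$rna))
  expect_equal(sc$dna, dna * 0.5)
  expect_identical(sc$rna, rna)
  expect_equal(sc$dna[["b1"]] / sc$dna[["b2"]], dna[["b1"]] / dna[["b2"]])
  eq <- scale_to_smaller(c(a = 10), c(a = 10))
  expect_identical(eq$scaled, "none")
  expect_error(scale_to_smaller(c(a = 0), c(a = 5)), "positive total")
})

test_that("the DNA representation filter is strictly greater-than", {
  dna <- c(low = 20.0, ok = 20.5, zero = 0, high = 100)
  expect_setequal(filter_dna(dna), c("ok", "high"))
})

test_that("barcode enrichment follows n_r/n_d + alpha with the zero-RNA rule", {
  expect_equal(barcode_enrichment(0, 40, 0.05), 0.05)
  expect_equal(log2(barcode_enrichment(0, 40, 0.05)), log2(0.05))
  expect_equal(barcode_enrichment(40, 40, 0.05), 1.05)
  expect_equal(barcode_enrichment(40, 40, 1e-12), 1, tolerance = 1e-9)
  expect_error(barcode_enrichment(5, 0, 0.05), "positive")
})

test_that("promoter activity averages log2 enrichments and enforces the barcode floor", {
  enr <- data.frame(
    promoter = c("P1", "P1", "P1", "P2", "P2"),
    barcode = paste0("b", 1:5),
    enrichment = c(0.5, 2, 1, 1, 1))
  act <- suppressMessages(promoter_activity(enr, quant_params()))
  expect_identical(act$promoter, "P1")  # P2 has 2 < 3 barcodes
  expect_equal(act$log2_activity, mean(log2(c(0.5, 2, 1))))
  act1 <- promoter_activity(enr, quant_params(min_barcodes_per_promoter = 1))
  expect_equal(act1$log2_activity[act1$promoter == "P2"], 0)
})

test_that("replicate aggregation uses the unweighted mean and sample SD", {
  pr <- data.frame(promoter = c("P", "P", "P", "Q"),
                   replicate = c(1, 2, 3, 1),
                   log2_activity = c(1, 2, 3, 5))
  agg <- aggregate_replicates(pr)
  expect_equal(agg$mean_log2_activity[agg$promoter == "P"], 2)
  expect_equal(agg$sd_log2_activity[agg$promoter == "P"], 1)
  expect_true(is.na(agg$sd_log2_activity[agg$promoter == "Q"]))
})

test_that("relative activities are per-replicate shifts against the reference", {
  pr <- data.frame(promoter = rep(c("WT", "M"), each = 3),
                   replicate = rep(1:3, 2),
                   log2_activity = c(1, 2, 3, 2, 3, 4))
  rel <- relative_activity(pr, "WT")
  expect_equal(rel$mean_log2_activity[rel$promoter == "WT"], 0)
  expect_equal(rel$mean_log2_activity[rel$promoter == "M"], 1)
  expect_equal(rel$sd_log2_activity[rel$promoter == "M"], 0)
  expect_error(relative_activity(pr[pr$promoter == "M", ], "WT"), "missing")
})

test_that("condition fold changes difference matched promoters and centre at zero under the null", {
  a <- data.frame(promoter = c("P1", "P2", "P3"),
                  mean_log2_activity = c(1, 2, 3))
  expect_equal(condition_fold_change(a, a)$log2_fold_change, c(0, 0, 0))
  b <- a; b$mean_log2_activity <- b$mean_log2_activity - 1
  expect_equal(condition_fold_change(a, b)$log2_fold_change, c(1, 1, 1))
  withr::with_seed(44, {
    big <- data.frame(promoter = paste0("P", 1:200),
                      mean_log2_activity = rnorm(200))
    tko <- big
    tko$mean_log2_activity <- big$mean_log2_activity + rnorm(200, 0, 0.3)
  })
  fc <- condition_fold_change(big, tko)
  expect_lt(abs(mean(fc$log2_fold_change)), 3 * 0.3 / sqrt(200))
  part <- a[1:2, ]
  expect_message(condition_fold_change(a, part), "missing in one condition")
})

sim_quant <- function(seed, rna_mult = 1) {
  cfg <- sim_config(seed = seed, n_promoters = 12L)
  gp <- gen_promoters(cfg)
  ta <- gen_true_activities(
    data.frame(construct_id = gp$truth$id, oe = gp$truth$oe), cfg)
  cc <- gen_counts(ta, cfg)
  cc$counts$count[cc$counts$sample == "RNA"] <-
    cc$counts$count[cc$counts$sample == "RNA"] * rna_mult
  list(truth = ta,
       q = suppressMessages(quantify_activity(cc$counts, cc$barcode_map)))
}

test_that("activities never fall below the pseudocount floor", {
  s <- sim_quant(77)
  expect_true(all(s$q$per_replicate$log2_activity >= log2(0.05) - 1e-12))
})

test_that("quantified activities are invariant to a global RNA scale factor", {
  s1 <- sim_quant(78, rna_mult = 1)
  s3 <- sim_quant(78, rna_mult = 3)
  m <- merge(s1$q$aggregated, s3$q$aggregated, by = "promoter")
  expect_equal(m$mean_log2_activity.x, m$mean_log2_activity.y,
               tolerance = 1e-10)
})

test_that("relative activities recover the simulated truth without bias", {
  s <- sim_quant(79)
  m <- merge(s$q$aggregated, s$truth, by.x = "promoter",
             by.y = "construct_id")
  expect_gt(cor(m$mean_log2_activity, m$true_log2_activity,
                method = "spearman"), 0.9)
  # shift-free comparison: centre both on the same promoter set
  above_floor <- m$true_log2_activity > log2(0.05) + 2
  est_rel <- m$mean_log2_activity - mean(m$mean_log2_activity[above_floor])
  true_rel <- m$true_log2_activity - mean(m$true_log2_activity[above_floor])
  expect_lt(max(abs(est_rel[above_floor] - true_rel[above_floor])), 0.35)
  expect_lt(abs(mean(est_rel[above_floor] - true_rel[above_floor])), 0.1)
})

test_that("the alpha diagnostic reports a variance per candidate pseudocount", {
  cfg <- sim_config(seed = 80, n_promoters = 6L)
  gp <- gen_promoters(cfg)
  ta <- gen_true_activities(
    data.frame(construct_id = gp$truth$id, oe = gp$truth$oe), cfg)
  cc <- gen_counts(ta, cfg)
  r1 <- cc$counts[cc$counts$replicate == 1, ]
  dna <- r1$count[r1$sample == "DNA"]; names(dna) <- r1$barcode[r1$sample == "DNA"]
  rna <- r1$count[r1$sample == "RNA"]; names(rna) <- r1$barcode[r1$sample == "RNA"]
  d <- alpha_diagnostic(dna, rna, cc$barcode_map)
  expect_identical(names(d), c("alpha", "mean_variance"))
  expect_true(all(is.finite(d$mean_variance)))
})
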