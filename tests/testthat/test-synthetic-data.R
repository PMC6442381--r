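test_that("promoter generation hits target CpG densities deterministically", {
  cfg <- sim_config(seed = 21, n_promoters = 6L,
                    target_oe = c(0.2, 0.5, 0.9, 1.2, 0.7, 0.3))
  gp <- gen_promoters(cfg)
  expect_true(all(abs(gp$truth$oe - gp$truth$target_oe) <=
                    cfg$oe_tolerance + 1e-9))
  gp2 <- gen_promoters(cfg)
  expect_identical(vapply(gp$promoters, `[[`, "", "sequence"),
                   vapply(gp2$promoters, `[[`, "", "sequence"))
  # a target at the tolerance floor strips every CpG
  cfg0 <- sim_config(seed = 22, n_promoters = 2L, target_oe = 0.05)
  gp0 <- gen_promoters(cfg0)
  expect_true(all(vapply(gp0$promoters,
                         function(p) count_cpgs(p$sequence), 1L) == 0L))
  expect_error(sim_config(seed = 1, target_oe = 2.5), "\\(0, 2\\]")
})

test_that("embedded motifs are annotated, protected, and scoreable", {
  cfg <- sim_config(seed = 23, n_promoters = 8L,
                    motif_set = c(NRF1 = "GCGCATGCGC"), motif_prob = 1)
  gp <- gen_promoters(cfg)
  for (p in gp$promoters) {
    expect_equal(nrow(p$motifs), 1L)
    s <- p$motifs$start[1]
    expect_identical(substr(p$sequence, s + 1, s + 10), "GCGCATGCGC")
  }
})

test_that("true activities follow the linear density model", {
  cfg0 <- sim_config(seed = 24, sigma = 0)
  man <- data.frame(construct_id = c("a", "b"), oe = c(0.5, 0.7))
  ta <- gen_true_activities(man, cfg0)
  expect_equal(diff(ta$true_log2_activity), 4 * 0.2)
  # motif effects add for intact motifs only
  cfg_m <- sim_config(seed = 24, sigma = 0,
                      motif_effects = c(GABPA = 1.5))
  man$intact_tfs <- c("GABPA", "")
  ta_m <- gen_true_activities(man, cfg_m)
  expect_equal(ta_m$true_log2_activity[1] - ta$true_log2_activity[1], 1.5)
  expect_equal(ta_m$true_log2_activity[2], ta$true_log2_activity[2])
  # a null density effect leaves activities unrelated to OE
  cfg_null <- sim_config(seed = 25, beta_oe = 0, sigma = 0.5)
  man50 <- data.frame(construct_id = paste0("c", 1:50),
                      oe = seq(0.1, 1.2, length.out = 50))
  ta_null <- gen_true_activities(man50, cfg_null)
  expect_lt(abs(cor(ta_null$oe, ta_null$true_log2_activity)), 0.35)
})

test_that("counts reproduce the expected RNA/DNA enrichment structure", {
  cfg <- sim_config(seed = 26, n_replicates = 1L,
                    barcodes_per_construct = 2000L, sigma = 0)
  truth <- data.frame(construct_id = c("lo", "hi"), oe = c(0, 0),
                      true_log2_activity = c(0, 2))
  cc <- gen_counts(truth, cfg)
  expect_identical(nrow(cc$barcode_map), 4000L)
  dna <- cc$counts[cc$counts$sample == "DNA", ]
  rna <- cc$counts[cc$counts$sample == "RNA", ]
  prom <- cc$barcode_map$promoter[match(dna$barcode, cc$barcode_map$barcode)]
  ratio <- function(p) sum(rna$count[prom == p]) / sum(dna$count[prom == p])
  # expected RNA/DNA ratio scales as 2^(activity difference)
  expect_equal(ratio("hi") / ratio("lo"), 4, tolerance = 0.1)
  cc2 <- gen_counts(truth, cfg)
  expect_identical(cc$counts$count, cc2$counts$count)
})

test_that("zero RNA depth drives every promoter to the pseudocount floor", {
  cfg <- sim_config(seed = 27, n_promoters = 4L, rna_depth = 0)
  gp <- gen_promoters(cfg)
  ta <- gen_true_activities(
    data.frame(construct_id = gp$truth$id, oe = gp$truth$oe), cfg)
  cc <- gen_counts(ta, cfg)
  expect_true(all(cc$counts$count[cc$counts$sample == "RNA"] == 0))
})

test_that("simulated reads are deterministic and carry their truth table", {
  cfg <- sim_config(seed = 28, n_promoters = 3L, promoter_length = 200L,
                    error_rate = 0.01)
  gp <- gen_promoters(cfg)
  refs <- vapply(gp$promoters, `[[`, "", "sequence")
  bmap <- data.frame(barcode = generate_barcodes(6, seed = 29),
                     promoter = rep(names(refs), each = 2))
  rd <- gen_reads(refs, bmap, cfg, n_reads = 300)
  expect_length(rd$read1, 300L)
  expect_identical(nrow(rd$truth), 300L)
  rd2 <- gen_reads(refs, bmap, cfg, n_reads = 300)
  expect_identical(rd$read1, rd2$read1)
  expect_identical(rd$read2, rd2$read2)
  # at a 1% substitution rate reads differ from their reference
  mm <- mapply(function(r, cons)
    sum(utf8ToInt(r) != utf8ToInt(substr(refs[cons], 1, nchar(r)))),
    rd$read1, rd$truth$construct_id)
  expect_gt(mean(mm), 0.5)  # about 2 errors expected per 200-nt read
  expect_lt(mean(mm), 5)
})

test_that("binding windows follow the logistic model and enrichment labels", {
  cfg0 <- sim_config(seed = 30,
                     binding = list(a = -1, b = 0, c = 0, score_mean = 8,
                                    score_sd = 4, oe_max = 1.2,
                                    enrich_bound_mean = 4.5,
                                    enrich_unbound_mean = 0.5, enrich_sd = 1))
  w <- gen_binding_windows(cfg0, 5000)
  p0 <- plogis(-1)
  se <- sqrt(p0 * (1 - p0) / 5000)
  expect_lt(abs(mean(w$bound) - p0), 3 * se)
  expect_gt(attr(w, "label_consistency"), 0.9)
  # with a motif effect only, the motif score dominates the density score
  cfg_b <- sim_config(seed = 31,
                      binding = list(a = -4, b = 0.8, c = 0, score_mean = 4,
                                     score_sd = 3, oe_max = 1.2,
                                     enrich_bound_mean = 4.5,
                                     enrich_unbound_mean = 0.5, enrich_sd = 1))
  wb <- gen_binding_windows(cfg_b, 4000)
  auc_motif <- pr_auc(pr_curve(wb$motif_score, wb$bound))
  auc_oe <- pr_auc(pr_curve(wb$oe, wb$bound))
  expect_gt(auc_motif, auc_oe + 0.1)
  w2 <- gen_binding_windows(cfg_b, 4000)
  expect_identical(wb$bound, w2$bound)
})

test_that("methylation calls decrease with CpG density", {
  cfg <- sim_config(seed = 32, n_promoters = 2L, target_oe = c(0.2, 1.0))
  gp <- gen_promoters(cfg)
  refs <- vapply(gp$promoters, `[[`, "", "sequence")
  names(refs) <- c("lo", "hi")
  oe <- normalized_cpg_density(refs)
  expect_lt(oe[1], oe[2])
  calls <- gen_methylation_calls(refs, cfg)
  pm <- promoter_methylation(calls)
  m_lo <- pm$mean_methylation[pm$promoter == "lo"]
  m_hi <- pm$mean_methylation[pm$promoter == "hi"]
  expect_gt(m_lo, m_hi)
  # a flat slope removes the density dependence
  cfg0 <- sim_config(seed = 33,
                     methylation = list(intercept = 0, slope = 0,
                                        coverage = 200L))
  pm0 <- promoter_methylation(gen_methylation_calls(refs, cfg0))
  expect_lt(abs(diff(pm0$mean_methylation)), 0.1)
  calls2 <- gen_methylation_calls(refs, cfg)
  expect_identical(calls$n_methylated, calls2$n_methylated)
})
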