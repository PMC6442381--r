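# cpgmpra

Design and analysis of barcoded promoter reporter libraries that dissect
the contribution of CpG dinucleotide density to mammalian promoter
activity.

Two thirds of mammalian promoters overlap CpG islands — regions of at
least 200 bp with G+C content above 50% and a CpG observed/expected ratio
of at least 0.6 — and CGI promoters are systematically more active than
CpG-poor ones. But promoter sequences confound CpG density with
transcription-factor motifs. Untangling the two requires mutant promoter
libraries in which CpGs *outside* bound TF motifs are altered in a
controlled way and assayed in parallel through barcoded reporters.
`cpgmpra` is the computational toolkit for that experiment, for
epigenomics and regulatory-genomics groups running (or simulating)
barcoded parallel reporter assays.

## What it computes

**Normalized CpG density.** For a region of length *L* with
*n*<sub>CpG</sub> CG dinucleotides, *n*<sub>C</sub> cytosines and
*n*<sub>G</sub> guanines,

&nbsp;&nbsp;&nbsp;&nbsp;OE = ( *n*<sub>CpG</sub> / (*n*<sub>C</sub> ·
*n*<sub>G</sub>) ) × *L*,

with `classify_cgi()` applying the standard CGI rule (≥ 200 bp, GC > 0.5,
OE ≥ 0.6).

**Library design.** Five substitution-only mutant designs over the
non-motif CpG set (window combinations, 2^k constructs for k windows;
random density series; motif mutations; 10-bp tiling replacements; CpG
add-backs in a CpG-free baseline), plus degenerate-pattern barcodes
(`NNNNWNNNNWNNNNN`) with a minimum pairwise Hamming distance.

**Assignment and quantification.** Reads are matched to references by
mismatch count under a 20%-of-sequenced-bases error budget, an ambiguity
margin of 3 to the second-closest reference, and strict-best tie
rejection; barcodes with a second/top association ratio ≥ 0.3 are
discarded as impure. Per barcode, enrichment is *n*<sub>r</sub> /
*n*<sub>d</sub> + α (α = 0.05, after scaling both libraries to the
smaller total and dropping barcodes with ≤ 20 scaled DNA reads), and a
promoter's log2 activity is the mean log2 enrichment of its barcodes.

**Statistics and prediction.** Spearman correlations with approximate or
exact permutation p-values; PWM log-odds scanning over both strands;
bound-window calls at ChIP log2 enrichment > 2.5; the additive logistic
model `logit P(bound) = a + b·motif + c·OE`; precision-recall curves over
100 equally spaced cutoffs; and per-promoter bisulfite methylation
summaries.

**Synthetic data.** Seeded generators with known ground truth for every
stage — promoters with controlled OE, activity models, overdispersed
count matrices, substitution-error read pairs, logistic binding windows,
methylation calls.

See `vignettes/cpg-density-reporter-analysis.Rmd` for the full methods
account.

## Worked example

```r
library(cpgmpra)

## 1. Simulate a small study: 12 promoters spanning the CpG-density range
cfg <- sim_config(seed = 1, n_promoters = 12)
gp  <- gen_promoters(cfg)
gp$promoters[[1]]
#> promoter_record 'prom001': 600 bp, 11 CpGs, OE = 0.312, GC = 0.502

## 2. Known ground truth: activity rises with normalized CpG density
truth  <- gen_true_activities(
  data.frame(construct_id = gp$truth$id, oe = gp$truth$oe), cfg)
counts <- gen_counts(truth, cfg)

## 3. Quantify per-promoter log2 activities from the barcode counts
act <- quantify_activity(counts$counts, counts$barcode_map)
head(act$aggregated, 4)
#>   promoter n_replicates mean_log2_activity sd_log2_activity
#> 1  prom001            3         -1.1281908       0.08225382
#> 2  prom002            3         -1.2816937       0.33784819
#> 3  prom003            3         -0.4380289       0.35459995
#> 4  prom004            3         -1.4202935       0.16080196

## 4. Does activity correlate with CpG density across replicates?
per_rep <- merge(act$per_replicate, gp$truth, by.x = "promoter", by.y = "id")
replicate_correlation(per_rep$oe, per_rep$log2_activity, per_rep$replicate,
                      n_perm = 9999, seed = 2)
#> Spearman rho = 0.914 +/- 0.020 (3 replicates), permutation p = 0.0001
```

The first promoter is CpG-poor (OE 0.31, below the 0.6 island threshold)
and sits low on the activity scale; across the panel the estimated log2
activities track the simulated density effect, with a replicate-averaged
Spearman correlation of 0.91 that no permutation of the activities
matches (p = 1e-4 at 9,999 permutations). Silent promoters floor exactly
at log2(0.05) ≈ −4.32, the pseudocount limit.

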