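---
title: "Dissecting CpG density effects on promoter activity with cpgmpra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting CpG density effects on promoter activity with cpgmpra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgmpra)
```

## The problem

Two thirds of mammalian promoters overlap CpG islands (CGIs): regions of at
least 200 bp with a G+C content above 50% and a CpG observed/expected ratio
of at least 0.6. CGI promoters are, on average, far more active than
CpG-poor promoters, but promoter sequences confound CpG density with the
complex binding motifs of transcription factors (TFs). Separating the two
requires promoter mutant libraries in which CpGs outside bound TF motifs
are altered in a controlled way, assayed in parallel from a single genomic
locus through barcoded reporters. `cpgmpra` implements the computational
side of that experiment end to end: composition statistics, mutant-library
design, read-to-construct assignment, barcode-level activity
quantification, permutation statistics, CpG-density-aware binding
prediction, and bisulfite methylation summaries — together with seeded
simulators that give every stage inputs with known ground truth.

## Normalized CpG density

For a region of length $L$ with $n_{CpG}$ CG dinucleotides, $n_C$
cytosines, and $n_G$ guanines,

$$\mathrm{OE} = \frac{n_{CpG}}{n_C \, n_G} \times L .$$

`normalized_cpg_density()` implements exactly this quantity and defines it
as 0 when $n_C n_G = 0$ (no CpG structure is possible without both bases).
`classify_cgi()` applies the standard CGI rule: length $\geq$ 200 bp, G+C
$>$ 0.5 (strict), OE $\geq$ 0.6. OE is computed over the full supplied
region; callers who want a fixed promoter span (for example −400 to +200
around the TSS) pass that span as the sequence. All coordinates in the
package are 0-based and half-open.

## Library designs

All five designs are substitution-only: constructs always retain the
parent length, so downstream assignment can assume fixed-length reads.
The mutable set is defined by `mutable_cpgs()`: a CpG at position $p$ is
protected exactly when $[p, p+2)$ intersects a motif annotation with
`bound = TRUE` (a motif supported by a ChIP peak); unbound motif
predictions do not protect.

* **Window combinations** (`window_combination_library()`) enumerate all
  $2^k$ WT/mutant combinations of $k$ disjoint windows, mutating the C of
  every mutable CpG in a mutant window to A or T. The design is fully
  deterministic.
* **Density series** (`density_series_library()`) retain a random subset
  of `round(p * n_mutable)` CpGs per retention fraction $p$
  (round-half-away-from-zero, so 0.657 of 35 CpGs retains 23 and mutates
  12) and mutate the rest. The subset is re-drawn independently at every
  density level so that effects cannot be attributed to one particular
  mutated set.
* **Motif mutations** (`motif_mutation_library()`) replace each motif
  interval with a random CpG-free scramble; when a PWM is supplied the
  replacement must also score below 0 log2 log-odds in the mutated
  neighbourhood, guaranteeing the site is destroyed. Each interval's
  replacement is drawn once and reused in the per-TF "all motifs"
  construct, so a TF with a single site has identical single/all
  constructs.
* **Tiling replacements** (`tiling_replacement_library()`) substitute each
  complete window (default 10 bp) with a random CpG-free sequence. Every
  random replacement in the package is resampled until no CG occurs inside
  the replaced interval *or across either junction*; without that
  constraint replacements would create unintended CpGs. A window size of 1
  is rejected because junction-safe CpG-free replacement cannot be
  guaranteed. The tiled extent is an explicit argument (`region`) rather
  than a guess about partial trailing windows.
* **Add-backs** (`addback_library()`) replace designated low-effect blocks
  with CpG-free sequence and then restore CG dinucleotides at the original
  WT CpG positions in random combinations. Two deliberate choices here:
  the baseline keeps the WT G of each block CpG and substitutes A at the C
  slot — mirroring the C-to-A convention of the density designs and
  pinning "the same spatial locations" unambiguously — and the random
  add-back subsets are nested (prefixes of one seeded permutation), which
  makes OE strictly increasing in the add-back count on the shared
  baseline.

Because random CpG-free replacements drift in G+C content,
`design_manifest()` reports achieved OE and GC per construct so that
composition effects stay auditable.

Barcodes follow the degenerate pattern `NNNNWNNNNWNNNNN` (length 15,
positions 5 and 10 restricted to A/T; pattern space $4^{13} \times 2^2
\approx 2.7 \times 10^8$) flanked by the fixed anchors `CGCCGAA` and
`AGCTCGG`. `generate_barcodes()` enforces a minimum pairwise Hamming
distance (default 3 — chosen so a single sequencing error cannot convert
one barcode into another) by rejection sampling with a bounded attempt
budget.

## Read assignment and barcode purity

Mutant libraries differ from their references by known substitutions, so
reads are matched by mismatch count rather than by a gapped aligner that
caps mismatches. For each read (pair) the package computes Hamming
distances $d_1 \le d_2$ to the best and second-best reference and assigns
iff

1. $d_1 \le$ `max_error_fraction` × total sequenced bases (default 0.20,
   i.e. 120 mismatches over 2 × 300 nt),
2. the ambiguity gate passes — by default the *absolute* reading
   $d_2 \ge 3$; the gap reading $d_2 - d_1 \ge$ margin is available via
   `margin_mode = "gap"`, and
3. $d_1 < d_2$ strictly; ties are never assigned, so ambiguity cannot
   create phantom counts.

These gates give a useful property verified in the test suite: with
references at least the margin apart, substitution errors convert
assignments into `UNASSIGNED` but essentially never into a wrong
reference. Indels are outside the model and rejected at ingest.

Barcodes are tallied against their assigned promoters; a barcode is kept
(`unique`) when it associates with a single promoter or when the
second/top association ratio is below 0.3 (strict, on read counts), else
it is `impure` and excluded. The kept map feeds quantification.

## Activity quantification

Per replicate, the DNA and RNA libraries are scaled to the smaller total
count, barcodes with scaled DNA counts of 20 or fewer are discarded
(strictly "more than 20" passes), retained barcodes missing from RNA get
an RNA count of 0 (absence reflects lack of activity), and each barcode's
enrichment is

$$e = \frac{n_r}{n_d} + \alpha, \qquad \alpha = 0.05 .$$

The promoter's log2 activity is the arithmetic mean of $\log_2 e$ over its
unique barcodes; promoters with fewer than `min_barcodes_per_promoter`
(default 3, reducible to 1 for low-coverage libraries) are dropped with a
message. Activities are floored at $\log_2 \alpha \approx -4.32$: a fully
silent promoter sits exactly there. Replicates are scaled and quantified
independently (they are independent sequencing runs) and aggregated as an
unweighted mean with a sample SD. Because the scale-to-smaller step fixes
only the *relative* scale of RNA to DNA, absolute log2 activities are
identified up to a per-replicate additive constant; comparisons should use
`relative_activity()` (log2 ratios to a designated WT construct, computed
within replicate) or `condition_fold_change()` between conditions. The
pseudocount default is a configuration value; `alpha_diagnostic()` ships
the mean–variance curve across candidate $\alpha$ so users can re-derive
"the smallest value that roughly stabilises the variance" on their own
data.

## Binding prediction

PWMs are probability matrices (rows = positions) regularised by adding
$10^{-3}$ per cell and renormalising so log-odds scores stay finite.
`logodds_scan()` returns the maximum over all offsets and both strands of
$\sum_i \log_2(p_i(b_i)/0.25)$; motifs are directional, so the
both-strand maximum is the standard choice for "window contains a motif".
Genomic tiles (default 600 nt, non-overlapping, remainder dropped) are
called bound when their ChIP log2 enrichment strictly exceeds 2.5.
`subset_stats()` reports bound fraction and recall for the four standard
subsets (all; motif score ≥ 12; OE ≥ 0.6; both). The additive model

$$\mathrm{logit}\, P(\mathrm{bound}) = a + b \cdot \mathrm{motif\ score}
  + c \cdot \mathrm{OE}$$

is fit by maximum likelihood (`glm`); features are left in natural units
(the problem is convex, scaling is presentational). Complete separation is
flagged and refit with a light ridge penalty when glmnet is available.
Precision-recall curves follow the ≥-cutoff definition over 100 equally
spaced cutoffs from the minimum to the maximum score, so the minimum
cutoff always yields recall 1 and precision equal to the bound fraction.
`pr_auc()` integrates the curve over recall, anchoring recall 0 at the
precision of the most stringent cutoff.

## Permutation statistics

`spearman_rho()` uses mid-ranks. Significance is two-sided on $|\rho|$ by
default, permuting `y` only:

* approximate mode draws `n_perm` random permutations and reports
  $(1 + k)/(1 + n_\mathrm{perm})$ — the add-one correction keeps the test
  valid and the p-value strictly positive;
* exact mode enumerates all $n!$ permutations (identity included, so the
  p-value is at least $1/n!$) and reports the raw proportion; it refuses
  $n > 9$ and points to the approximate mode.

Floating-point ties at $|\rho_\mathrm{perm}| = |\rho_\mathrm{obs}|$ are
counted as at-least-as-extreme via a $10^{-12}$ guard. For replicated
experiments, `replicate_correlation()` computes $\rho$ within each
replicate, reports mean ± SD, and permutes within replicates while using
the mean $\rho$ as the test statistic — a design choice (the alternative,
testing each replicate separately, is available by calling the plain tests
per replicate).

## The synthetic experiment

The generators in `sim_config()` define the study conditions used
throughout the tests and the acceptance script; they are fixed once and
not tuned per run:

* **Promoters**: 20 sequences of 600 bp (a −400..+200 TSS span) at G+C
  0.55, with target OE drawn from a bimodal low/high mixture (or supplied
  explicitly) and achieved within ±0.05 by iterative CG
  insertion/removal at random unmasked positions — simple and auditable.
  Embedded consensus motifs are annotated and protected.
* **Activities**: `true = -3 + 4·OE + motif effects + N(0, 0.25)` log2
  units, so activities rise gradually with CpG density over roughly the
  dynamic range a reporter assay resolves.
* **Counts**: 8 barcodes per construct, 3 independent replicates; per
  barcode a Gamma(4, 4) abundance models library bottlenecking, DNA is
  negative binomial (mean 200 × abundance, size 10) and RNA is Poisson
  with mean proportional to abundance × $2^{\mathrm{true}}$ — the simplest
  structure under which the pseudocount estimator behaves as intended.
* **Reads**: read 1 is the construct prefix (300 nt), read 2 is
  anchor+barcode+anchor, with i.i.d. substitutions at the configured rate.
* **Binding windows**: motif scores Normal(8, 4), OE Uniform(0, 1.2),
  bound Bernoulli with logistic coefficients (−6, 0.4, 4), enrichments
  from bound/unbound normals so the 2.5 threshold reproduces ~98% of
  labels (the achieved consistency is attached to the output).
* **Methylation**: per-CpG probability `plogis(2 − 6·OE)` — methylation
  rises steeply as CpG density falls — with fixed coverage 30 and binomial
  methylated counts.

Every generator is a pure function of the configuration seed plus a fixed
offset per generator (promoters +0, activities +1, counts +2, reads +3,
windows +4, methylation +5, barcodes +6), so outputs are byte-identical
across runs and call orders.

What the simulations do *not* emulate: quality-dependent Illumina error
profiles and indels, PCR chimeras and UMI structure, GC amplification
bias, genuine chromatin context, and real ChIP libraries. Passing the
recovery suites therefore demonstrates correctness of the estimators under
the stated statistical model, not performance on any particular published
dataset; genome-wide bound percentages in the literature depend on the
underlying ChIP data and are not reproduction targets here.

## Problem sizes and runtime choices

The test suite and `scripts/acceptance.R` use 20 promoters × 8 barcodes ×
3 replicates at depth 200 for quantification recovery, 10,000 simulated
reads for assignment robustness, 20,000 windows for logistic coefficient
recovery, and 1,000 null simulations × 999 permutations for type-I
calibration — sizes at which the Monte-Carlo error of each check is
comfortably below its acceptance margin while the whole suite runs in
about a minute on one CPU.

## Known limitations

* Assignment is substitution-only; libraries with designed indels need a
  different matcher (an edit-distance mode would slot behind the same
  gates).
* Absolute activities are depth-relative (see above); only relative and
  fold-change comparisons are calibrated.
* `perm_test_exact()` is limited to n ≤ 9 by design.
* The OE-targeting generator treats the whole sequence; it does not
  reproduce positional CpG clustering within real islands.
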