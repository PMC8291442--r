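---
title: "Methods: comparative methylome reprogramming analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative methylome reprogramming analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdyn)
```

# Scope and data model

`methdyn` analyses DNA methylome reprogramming between gametes and early
embryos from per-cytosine WGBS call tables. The unit of data is the
`MethylomeTable`: one sample (a species at a developmental stage) as
records of `(chrom, pos, strand, context, n_meth, n_total)`, with the
methylation level of a site defined as `ML = n_meth / n_total`. All
internal coordinates are 0-based half-open; the on-disk dialects
(Bismark-style cytosine reports, 1-based; count-bearing bedGraph,
0-based) are converted exactly at the I/O boundary, so round-trips
through the readers and writers are identities. Read alignment and
methylation extraction from FASTQ are out of scope — the package starts
where a Bismark-class extractor ends.

Two defaults deserve mention because the field uses several conventions:

* **CpG dyad merging.** Counts from the two strands of a symmetric CpG
  are pooled onto the plus-strand position before analysis (doubling
  effective coverage). This is common practice but not universal;
  `merge_cpg_dyads()` is a separate step and the pipeline flag
  `merge_dyads` disables it.
* **Coverage filter.** Per-site statistics use a minimum depth of 5 by
  default. The cutoff is exposed everywhere (`min_cov`); results in this
  package are insensitive to values of 3–10 at the simulated depth of
  30x.
* **Promoters.** `[TSS − 1000, TSS + 500)` on the transcribed
  orientation, clipped at zero. Promoter span conventions vary between
  studies; both extents are configurable in `make_promoters()`.

# Global statistics

`global_ml()` reports the arithmetic mean of per-site MLs (`site_mean`,
the default) and the pooled read-weighted ratio (`count_weighted`). Both
are reported because published global levels rarely state their
weighting; the two agree exactly under uniform coverage and differ
little at 30x negative-binomial depth.

The bisulfite conversion rate is estimated from an unmethylated control
(a spike-in-like contig in the simulations): the pooled fraction of reads
calling unmethylated. Non-CpG (CHG/CHH) methylation in most animal
genomes is at or below the conversion-failure floor, so raw non-CpG
levels are corrected by subtracting the non-conversion rate and flooring
at zero. The correction is exact in expectation: a truly unmethylated
site reads methylated with exactly the non-conversion probability.

Distributional structure is summarised by a fixed-bin (width 0.1)
histogram of per-site MLs and a bimodality index, the fraction of sites
with ML ≤ 0.2 or ≥ 0.8. The 0.2/0.8 cutoffs operationalize the
observation that animal CpGs are either essentially unmethylated or
essentially fully methylated; any high-contrast methylome scores close
to 1.

# Positional structure

`tss_metaprofile()` builds the classic ±6 kb, 100-bp-bin metaplot around
TSSs. Offsets are strand-oriented (`pos − tss` on plus, `tss − pos` on
minus strand) and bin *k* covers `[−6000 + 100k, −6000 + 100(k+1))`.
Averaging is over all (gene, site) pairs in a bin rather than per-gene
first: the per-pair estimator is robust when many genes contribute few
covered CpGs, which is the regime of sparse invertebrate methylomes.
A consequence used in the tests: flipping every gene's strand exactly
mirrors the profile (bin *i* ↔ bin *119 − i*).

`segment_domains()` recovers the mosaic architecture with a deliberately
simple, fully deterministic procedure: a centered running mean over 5
CpGs, thresholding at 0.5, maximal constant-state runs, and absorption
of runs shorter than 5 CpGs into the longer flanking run (ties prefer
the preceding run). An HMM or changepoint model would be the natural
alternative; for bimodal methylomes the smoothed threshold is adequate
(per-site state recovery is ~0.98–0.99 on the mosaic presets), has only
three parameters, and cannot disagree with itself across runs. Domain
`mean_ml` is computed from raw (unsmoothed) site MLs so that the
CpG-weighted mean over domains equals the global site-mean — a
conservation property the tests assert. Chromosome edges use shrinking
windows; a chromosome with fewer CpGs than the smoothing window is
emitted as a single domain with a warning rather than dropped.

Promoter CpG-density classes cut the per-promoter density (CpGs per bp)
at the dataset's 0.25 and 0.75 quantiles with strict inequalities, so
ties at a cutoff fall into the intermediate class and a degenerate
all-equal dataset is entirely intermediate.

# Reprogramming comparisons

Sperm–oocyte divergence is reported two ways — the difference of global
MLs, and the mean absolute difference of 1-kb-binned MLs over co-covered
bins — because a global delta can hide compensating regional changes.
The binned statistic is the one that orders the architecture series.

DMP calling pools each promoter's CpG counts into a 2×2 table and
applies a two-sided Fisher exact test with Benjamini–Hochberg correction
and an effect-size filter |Δ| ≥ 0.2. With two samples and no biological
replicates this pooled-count design is the standard choice; it is
deterministic, its null is exact at any depth, and the promoter (not the
CpG) is the biological unit of interest here. The test statistic and
thresholds are arguments, not constants. Swapping the samples negates
Δ and swaps the hyper/hypo labels with p unchanged.

Stage-dynamics classification is intentionally transparent: `D`, the
range of per-stage global MLs, maps to none/minor/moderate/dramatic at
0.02/0.05/0.15. These cutoffs are this package's operationalization of
qualitative clade labels; they are configuration values, chosen so that
flat mosaic trajectories (range within sampling noise at 50,000 CpGs)
read "none", small gamete asymmetries read "minor", and the
demethylation–remethylation trajectory reads "dramatic". The
genome-wide demethylation flag is raised when an embryonic stage drops
below half the gamete mean — far enough below any gamete asymmetry, and
comfortably above the demethylated level itself.

The paired Wilcoxon signed-rank test for gene-set promoter contrasts
drops zero differences (the classic convention — visible with small
gene sets, which is why it is documented), uses the exact signed-rank
null up to n = 25 non-zero differences, switches to direct enumeration
of the 2^n sign assignments with midranks when tied |differences| make
the tabulated null invalid (n ≤ 15), and otherwise uses the normal
approximation with continuity correction. Methylation–expression
association uses Spearman rank correlation between promoter ML and
`log2(FPKM + 1)`; a gene is called "expressed" at FPKM ≥ 1, a threshold
with no canonical value, exposed as an argument.

# The synthetic methylome generator

The generator is first-class, tested code: it encodes the statistical
structure the analyses assume and provides ground truth for recovery
tests. Six presets emulate the observed span of animal methylome
architectures; their calibration constants are chosen so the closed-form
expected global ML lands on published species-level values:

| preset | architecture | p_dom / CGI | domain ML | background | expected ML |
|---|---|---|---|---|---|
| `anemone_mosaic` | mosaic | 0.115 | 0.92 | 0.005 | ≈ 0.11 |
| `bee_sparse` | mosaic | 0.008 | 0.85 | 0.003 | ≈ 0.01 |
| `deutero_mosaic` | mosaic | 0.29 | 0.92 | 0.005 | ≈ 0.27 |
| `chicken_intermediate` | mosaic | 0.45 | 0.92 | 0.01 | ≈ 0.42 |
| `fish_global` | global + CGIs | 10% CGI | 0.88 | 0.03 (CGI) | ≈ 0.795 |
| `mammal_global` | global + CGIs | 10% CGI | 0.88 | 0.03 (CGI) | ≈ 0.795 |

Design choices, and why:

* **CpG landscape.** Inter-CpG gaps are geometric (mean 100 bp outside,
  10 bp inside CGI clusters of 50 CpGs). This reproduces the inverse
  density–methylation relationship once truth is assigned, without
  simulating sequence.
* **Domains.** CpGs are partitioned into geometric blocks of mean 10
  CpGs. True inter-domain length distributions are not well
  characterised; geometric is a modeling choice, flagged as such, that
  yields mosaic browser-track texture at small scale.
* **Near-exact calibration.** Blocks are marked methylated by randomized
  greedy selection until the nominal CpG fraction `p_dom` is reached,
  rather than independent per-block coin flips. The realized domain
  fraction then matches `p_dom` to within one block, so the closed-form
  expectation `p_dom·domain_ml + (1 − p_dom)·background_ml` holds
  tightly and recovery tolerances are dominated by count noise, not by
  landscape resampling.
* **Gamete asymmetry.** A preset-specific fraction of domain units is
  switched in the oocyte. In mosaic presets the switch silences
  methylated domains (sperm ≥ oocyte, the direction observed in
  invertebrate deuterostomes); in global presets units flip in both
  directions, so CpG islands can be oocyte-hypermethylated — the
  HOX-cluster situation in fish. Preset defaults (anemone 0.02, bee 0,
  deuterostome 0.10, chicken 0.15, fish 0.12, mammal 0.40) make the
  binned gamete divergence strictly increasing along the
  anemone → deuterostome → fish → mammal series.
* **Stage trajectories.** Mosaic presets inherit the sperm truth in all
  embryo stages (stable architecture). `fish_global` remodels the
  oocyte truth onto the paternal pattern at the "mbt" stage.
  `mammal_global` sets the "icm" truth to 0.3 × the per-site gamete
  mean, then restores the paternal pattern — producing the
  demethylation–remethylation trajectory and triggering the flag.
* **Designed annotation.** Each dataset carries ~200 regular genes (in
  global presets anchored at CGIs, the vertebrate promoter
  architecture), a 10-gene HOX-like cluster, and a 10-gene "signaling"
  set. The HOX cluster is forced unmethylated at all stages in mosaic
  presets, oocyte-hypermethylated then remodeled in `fish_global`, and
  partially methylated in gametes / demethylated from "icm" onwards in
  `mammal_global`. Truth-level promoter deltas ≥ 0.5 define the designed
  DMP list.
* **Error and coverage model.** Depth is `NegBin(mu = 30, size = 5)`;
  each read reports methylated with probability `m(1 − g) + (1 − m)f`,
  with non-conversion `f = 0.0074` (matching a 99.26% conversion rate;
  presets emulating libraries with perfect conversion use `f = 0`) and
  over-conversion `g = 0.001`. The control contig and the per-stage
  CHH sites are simulated at `m = 0`.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: sequence composition and repeat structure,
partially methylated domains and other intermediate-ML compartments,
biological replicate variance beyond count noise, batch effects,
mapping artefacts, and real transcriptomes (the expression tables used
in the association analyses are drawn anti-correlated by construction).
Recovery rates on this generator are upper bounds for field data.

# Problem sizes and determinism

All simulation-based tests and the analysis scripts run at 15,000–50,000
CpGs and 30x mean coverage, sizes at which every statistic's sampling
error is well inside its test tolerance while a full suite completes in
well under a minute of compute. Every random draw flows from a single
integer seed; identical spec + seed is bit-reproducible, and technical
replicates are drawn by re-running `simulate_counts()` on one
`TruthSet` with a different count seed.

Numerical corner cases are handled explicitly rather than silently:
zero-coverage sites are retained by the readers and removed only by the
coverage filter; degenerate correlations (constant ML or expression)
return `NaN` with a warning; an all-zero paired contrast returns p = 1
with a warning; segmentation ties prefer the preceding run; quantile
ties in density classes resolve downward.

# Known limitations

* The DMP design (Fisher on pooled counts + BH + |Δ| ≥ 0.2) ignores
  within-promoter heterogeneity; a promoter with one strongly divergent
  CpG among many flat ones can be called. Per-CpG testing is
  deliberately out of scope.
* Dynamics-class thresholds are calibrated to site-mean global MLs at
  depth ≥ 5; substantially different coverage filters shift `D` slightly
  through the non-conversion floor.
* The segmentation's fixed threshold (0.5) is inappropriate for
  methylomes dominated by intermediate MLs (e.g. partially methylated
  domains); the parameter is exposed but no alternative model ships.
* `classify_dynamics()` requires the gamete stages by name; trajectories
  without gametes can still be classified but carry no demethylation
  flag semantics.
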