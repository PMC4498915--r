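---
title: "Methods: statistical models and design decisions in rfxtargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical models and design decisions in rfxtargets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfxtargets)
```

`rfxtargets` calls direct transcription-factor target genes by intersecting
two independent lines of genome-wide evidence: reproducible binding peaks in
promoter windows (ChIP-seq) and knockout differential expression (RNA-seq).
It is modelled on the regulatory logic of RFX-family factors, which bind a
~14-bp inverted-repeat X-box motif in the promoters of ciliary genes. Every
analysis step runs on synthetic data with planted ground truth, so each
statistical claim the package makes is verifiable against a known answer.
This vignette documents the generative model, the estimators, and the design
decisions that are not forced by the mathematics.

## The synthetic-data model

`sim_config()` fixes every generator parameter; `simulate_genome()` and the
`simulate_*()` functions are deterministic functions of a config. Defaults
describe a testis-like study: a knockout versus wild type at two postnatal
ages (P21, P30), 3 RNA-seq replicates per group, 2 ChIP replicates plus one
input.

**Genome and regulon.** `n_genes` (default 2000) two-exon gene models are
packed without overlap onto two chromosomes, each gene 2 kb long with a
600 bp margin so that every promoter window fits inside its chromosome.
`n_targets` (default 200) genes form the planted regulon: each receives one
X-box site (default consensus `GTTGCCATGGCAAC`, a perfect palindrome) at a
uniformly drawn offset inside its promoter window, a knockout effect of
`effect_log2fc` (default 2, i.e. 4-fold) in a planted direction and age
pattern, and, with probability `frac_rfx2_like_targets` (0.85), a
developmental profile that tracks the activating factor. `n_indirect`
(default 20) genes are differentially expressed without a binding site,
emulating secondary effects.

**Promoter window.** Strand-aware −500/+50 bp around the TSS (length 550).
Internally all coordinates are 0-based half-open; GFF3's 1-based closed
convention is converted only at the file boundary.

**ChIP coverage.** Per 50-bp bin, input coverage is Poisson with mean
`chip_depth` (30); IP coverage is Poisson with the same mean except at bins
overlapping a planted site, where the mean is multiplied by
`chip_enrichment` (10). Replicates draw from independent named substreams.
This emulates a point-source factor with uniform mappability; it does not
emulate fragment-length smearing, GC bias, or copy-number variation.

**RNA-seq counts.** Gene baselines are log-normal
(`baseline_meanlog = log(100)`, `baseline_sdlog = 1`); counts are negative
binomial with dispersion `nb_dispersion` (0.1), with the knockout effect
applied multiplicatively in the KO groups at the planted age(s).

**Developmental profiles.** The reference trajectory is a logistic rise with
half-maximum at day 19 over days {7, 14, 17, 21, 30}, matching a factor
whose expression surges as round spermatids appear. Profile classes are
`rfx2_like` (scaled reference), `flat`, and `declining`, with multiplicative
log-normal noise (`profile_noise_sdlog = 0.1`) and a fraction
(`frac_unreliable = 0.1`) scaled below the reliability floor.

**Ciliary evidence.** A gene is cilia-positive when it is on the
gold-standard list or has at least one high-confidence citation. The
generator plants positives at rate `cilia_frac_regulon` (0.6) in the regulon
and `cilia_frac_background` (0.1) elsewhere — the strong enrichment expected
if the factor's direct program is ciliogenic.

**Reproducibility.** Every stochastic stage draws from
`substream_seed(seed, name)`, so regenerating one assay never perturbs
another, and two runs from one config are byte-identical (the GFF3 writer
strips the date stamp for this reason).

## Differential expression

The DGE module is authored in-package (the point is a tested, transparent
implementation); `edgeR` and `DESeq2` are used only as independent
cross-checks in the test suite.

**Normalization** is median-of-ratios: per sample, the median across
all-positive genes of the ratio to the row geometric mean, rescaled to unit
geometric mean.

**Dispersion** is method-of-moments per gene with a bias-corrected
denominator, `max(mu^2 - v/n, 0.5 * mu^2)` — the naive plug-in `mu^2`
overestimates the squared mean and biases dispersion downward, which makes
null p-values slightly liberal. Raw estimates are shrunk toward a lowess
trend on mean expression with a prior weight of 20 pseudo-observations,
floored at `1e-8`.

**The exact test** conditions on the pooled total of a gene across both
groups: group sums are negative binomial with size `n_g / alpha`, and the
two-sided p-value sums the probabilities of all allocations at most as
likely as the observed one (with a `1 + 1e-7` slack against ties in floating
point). As `alpha -> 0` this reduces to the conditional binomial test. The
test suite verifies agreement with brute-force enumeration to `1e-10`.

**Calls** use p < 0.01 with nested fold tiers at 2-, 3- and 10-fold.

```{r dge-example}
cfg <- sim_config(n_genes = 300, n_targets = 30, seed = 11)
gen <- simulate_genome(cfg)
cnt <- simulate_counts(gen$annotation, gen$regulon, cfg)
dge <- run_dge(cnt$counts, cnt$samples)
glance(dge)
```

## Peak calling and promoter assignment

The caller tests each 50-bp bin's IP count against a Poisson rate given by
the input rescaled to IP depth and floored at the genome-wide mean (the
floor guards against zero-coverage input bins). Benjamini–Hochberg
correction is applied within replicate; significant bins at most one bin
apart merge into peaks, and the summit is the centre of the maximum-IP bin.

`filter_reproducible()` anchors on the replicate with the most peaks and
keeps a peak when every other replicate has a peak with reciprocal overlap
of at least 0.5; the reported coordinates are the union of the anchor and
its best partners. The union (rather than the intersection) was chosen so
that a planted site near a peak edge in one replicate is still covered by
the reported interval.

Peaks are classified by their centre with precedence
promoter > exon > intron > intergenic; TSS distances are signed in the
gene's orientation, and a centre exactly equidistant from two TSSs flags
both genes as ambiguous rather than picking one arbitrarily.

## Motif analysis

PWMs are scored as per-position log2 odds against a 0-order background
(default: the composition of the scanned set). Both strands are scanned —
the reverse strand through a complemented, reversed score matrix, reported
in forward coordinates — and the default hit threshold is 60% of the
maximum achievable score: a deliberately permissive binary "contains the
motif" call, since downstream use is set membership, not binding-energy
ranking.

`discover_motif_em()` fits a ZOOPS (zero-or-one occurrence per sequence)
mixture by EM. The M-step is the exact maximum-likelihood update, so the
log-likelihood is non-decreasing at every iteration; the pseudocount (0.5)
smooths only the final reported PWM. Starting points are the two most
frequent words of the target width across the sequence set plus random
subsequences — frequent words are cheap, surprisingly effective seeds for
over-represented motifs and make the default run reproducible. The
`inverted_repeat_score` (mean column-wise correlation between the PWM and
its reverse complement) quantifies the palindromic structure expected of an
X-box.

Set-level enrichment of motif carriers in a foreground versus a disjoint
background is a one-sided hypergeometric test, validated in the test suite
against exhaustive enumeration for small universes, including the
closed-form case N = 20, |A| = 5, |B| = 4, overlap 3 → 155/4845 ≈ 0.032.

## Integration

A gene is a **direct target** when it is a ChIP target (reproducible peak
in its promoter window) and differentially expressed at either age, in
either direction. Profile consistency ("consistent with activation by the
factor") is operationalized as Pearson correlation ≥ 0.8 with the reference
trajectory and a ≥4-fold rise across the time course, evaluated only for
genes whose maximum RPKM clears a reliability floor of 1 — the thresholds
are configurable via `profile_criteria()` because no principled unique
choice exists. Cilia flags follow the gold-or-high-citation rule, and genes
missing from the evidence table are negative, never errors (databases are
incomplete). Hypergeometric universe: genes with mean normalized count
above an expression floor, i.e. an expression-matched background.

```{r integrate-example}
ws <- file.path(tempdir(), "methods_ws")
res <- run_pipeline(ws, sim_config(n_genes = 300, n_targets = 30, seed = 12),
                    quiet = TRUE)
res$calls
```

## Problem sizes and limitations

Default problem sizes (2000 genes, 200 targets, 2 ChIP replicates at depth
30) run the full pipeline in well under a minute on one CPU; the unit and
acceptance test suites complete in a few minutes. The generator is a
caricature by design: uniform mappability, independent bins, a single exact
site per target, no batch effects, no isoforms. It is sufficient to verify
the estimators and the integration logic, not to benchmark performance on
real sequencing data. Numerical choices worth knowing: count pseudocount
0.5 in fold-change estimates, dispersion floor `1e-8`, EM tolerance `1e-6`,
and a `1e-12` probability floor in the EM M-step purely against floating
point underflow.
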