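---
title: "Methods: solubility and co-translational decay from 5'P degradome data"
author: "fivepsol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solubility and co-translational decay from 5'P degradome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fivepsol)
```

# Background

During co-translational 5'→3' mRNA decay, the Xrn1 exonuclease degrades a
transcript while ribosomes are still translating it. The exonuclease
catches up to the trailing ribosome and stalls, so the 5'-monophosphate
(5'P) ends of decay intermediates captured by 5'P degradome sequencing
(5'P-Seq) accumulate a fixed distance — about 17 nt — upstream of the
ribosome's A-site codon. Two consequences drive everything in this package:

1. **Frame periodicity.** Because ribosomes step in 3-nt codons, 5'P ends
   of co-translational intermediates fall preferentially into one of the
   three reading-frame phases. A-site codons start at transcript positions
   `3k` (0-based, with 0 the first base of the start codon), so protected
   5' ends sit at `3k − 17 ≡ 1 (mod 3)`: frame 1 is the co-translational
   signature.
2. **Codon-resolved dwelling.** If the ribosome dwells longer at some
   codons, 5'P ends pile up 17 nt upstream of those codons. Shifting each
   5' end +17 nt therefore reads out A-site occupancy codon by codon.

The second axis of the package is *mRNA solubility*. Cells fractionated
into a soluble lysate and a total pool (which additionally contains
insoluble, often condensate- or aggregate-associated mRNAs) yield paired
RNA-Seq libraries; the log2 ratio of a gene's soluble to total abundance is
its solubility. Depleting deadenylation-complex subunits (e.g. Not1 or
Not4) shifts solubility in opposite directions for specific gene classes,
which the package detects with an interaction ("ratio-of-ratios") test.

Because library depth is arbitrary, absolute statements ("more decay
intermediates per transcript") require an external anchor: a fixed amount
of foreign-species spike-in RNA added per sample. Spike-anchored
normalization underlies the *relative degradation* estimator (5'P over
RNA-Seq counts).

# Coordinate conventions

All transcript coordinates are 0-based half-open; codon `k` (0-based)
occupies nucleotides `[3k, 3k+3)`. Genomic inputs (GFF3, BED-like frames,
promoter tables) are 1-based closed and converted at the boundary. CDSs
with multiple parts are spliced in transcription order; on the minus
strand the rightmost exon is transcribed first and the assembled sequence
is reverse-complemented once, so `cds_sequence` always reads 5'→3'. Where
a quantity needs per-gene coordinates of intron-containing genes, the
spliced CDS coordinate system is used throughout — positions in introns
never carry signal.

# Count models and differential tests

## Negative-binomial Wald contrast

`nb_contrast()` is the shared two-group engine. Counts are normalized by
median-of-ratios size factors (`size_factors_median_ratio()`): per sample,
the median over all-positive genes of the ratio of the gene's count to its
geometric mean across samples, with the median taken on the log scale.
The log2 fold change is `log2(meanB + pc) − log2(meanA + pc)` with
pseudocount `pc = 0.5` on the normalized-mean scale, which keeps
low-count genes finite without materially biasing genes above ~50 counts.

The standard error comes from the delta method under the NB variance
`mu + alpha·mu²`. Dispersion `alpha` is estimated per gene by method of
moments, pooled across both groups, and floored at 0.01 — with triplicate
data the moment estimator is extremely noisy, and the floor prevents
spuriously tiny standard errors for genes whose replicates happen to agree.

The Wald statistic `LFC/SE` is referred to a **t distribution on
`nA + nB − 2` degrees of freedom** rather than a normal. The dispersion
entering the SE is itself estimated from very few replicates; a normal
reference is anti-conservative at triplicate scale (empirically, type-I
error of ~0.08–0.10 at nominal 0.05), while the t reference keeps the null
rejection rate within a couple of points of nominal. This is the one place
the implementation deliberately deviates from a textbook Wald z test, and
it is validated by a calibration test on simulated NB nulls.

Genes whose summed normalized counts fall below `count_floor = 10` are
reported with NA statistics. No further independent filtering is applied
before the Benjamini–Hochberg adjustment: the count floor is the only
screen, so FDRs are computed over all floor-passing genes.

## Solubility and its normalization

`solubility()` contrasts soluble vs total RNA-Seq within each condition.
The default normalization is **library-size** (median-of-ratios on target
genes): solubility is a compositional, within-species quantity, and
library normalization makes it robust to variable spike-in recovery in the
fractionation itself. A `normalization = "spike"` switch is exposed for
designs where the spike-in is trusted end-to-end, and `"none"` for
pre-normalized counts.

An identifiability caveat follows from the normalization: per-gene
solubility log-ratios are estimated only **up to an additive constant**
(the unknown soluble/total depth ratio). Comparisons across genes and all
differential quantities (deltas between conditions, interactions) are
unaffected; absolute levels should be interpreted after centering — the
package's own validation compares estimates to truth after
median-centering both.

## Relative degradation

`relative_degradation()` contrasts 5'P against RNA-Seq counts for the same
condition and fraction, with size factors computed **on the spike-in genes
only**. The spike-in amount per sample is constant and its 5'P rate is
condition-invariant, so it anchors the otherwise incomparable 5'P and RNA
library scales. The estimator obeys two exact contracts (asserted by
tests): doubling every target gene's 5'P counts shifts all LFCs by +1, and
doubling target *and* spike 5'P counts together leaves LFCs unchanged.

## Interaction test and solubility categories

`ratio_of_ratios()` tests whether two LFCs differ: estimate
`lfc_a − lfc_b`, standard error `sqrt(se_a² + se_b²)` (independent
samples), normal reference. Applied to solubility changes under two
depletions it feeds `classify_categories()`:

* **red** — interaction FDR < 0.05, solubility decreases > 0.5 log2 units
  under Not1 depletion and increases > 0.5 under Not4 depletion;
* **green** — the mirror image;
* **orange** / **blue** — interaction not significant and both deltas
  positive / both negative;
* **none** — everything else; genes missing any input are flagged
  `incomplete`.

All cutoffs are strict inequalities and exposed as arguments.

# Codon dwelling from shifted 5' ends

`rdo()` computes per-codon **ribosome dwelling occupancy**: the mean 5'P
depth 17 nt upstream of each sense codon's occurrences, divided by the
mean depth over *all* eligible codon occurrences, so the
position-weighted mean occupancy is exactly 1. Two details matter:

* Codons starting at positions < 17 have no upstream position inside the
  CDS and contribute nothing; the terminal stop codon is excluded
  (occupancy is defined over the 61 sense codons).
* Library-size normalization cancels in the ratio, so raw and normalized
  tracks give identical RDOs (asserted by a test). This also makes RDOs
  comparable across samples of different depth.

When a fractional CDS window is requested (e.g. first vs second half), a
codon is eligible only if **both** its start and its offset source
position fall inside the window — boundary-straddling codons are excluded
rather than ambiguously assigned.

`differential_rdo()` takes log2 ratios of occupancies between samples, and
`tai_analysis()` relates them to a codon-optimality scale (tAI): a Pearson
correlation test over the 61 sense codons plus a one-sided Wilcoxon
rank-sum comparison of the 15 least vs 15 most optimal codons, under the
alternative that non-optimal codons dwell more. The statistical wrappers
(`welch_t()`, `wilcoxon_rank_sum()`, `pearson_test()`) delegate to the
stock R tests and only standardize the result container.

# Metagene profiles, frames and windows

`metagene_anchored()` averages depth-per-million at fixed offsets from the
start or stop codon, after an optional +17 nt A-site shift; with the shift
applied, co-translational signal peaks at offsets ≡ 0 (mod 3), i.e. codon
starts. `metagene_scaled()` bins each CDS to a fixed number of
length-fraction bins and normalizes by overall mean depth, exposing the
5'→3' positional ramp of decay intermediates. `frame_fractions()` reports
the percentage of 5' ends per reading-frame phase, and `window_ratio()`
compares the proportion of a gene's reads inside fractional CDS windows
between the soluble and total pools (genes below `min_reads` in either
library are excluded).

# PAR-CLIP cross-linking density

PAR-CLIP reads out protein–RNA cross-link sites as T-to-C transitions.
`parclip_density()` normalizes a region's transition count by its number
of T bases and scales per million total transitions in the sample, making
densities comparable across regions of different T content and libraries
of different depth; regions with no T bases get NA with a flag. The
upstream step of calling high-confidence transitions from raw alignments
is deliberately *not* reimplemented — the package consumes transition
counts, which is the defined quantity the density depends on.

`relative_crosslink()` compares a factor of interest to a reference factor
(e.g. RNA polymerase II) by regressing log2 density on log2 density over
regions where both are positive and classifying each region by its
residual: more than `log2(fold_cutoff)` above the fit is `"higher"`, below
is `"lower"`. This separates "cross-links a lot because it is transcribed
a lot" from genuinely enriched binding.

# ChEC promoter signal

`promoter_windows()` builds strand-aware windows 400 bp upstream to 100 bp
downstream of each gene's +1 nucleosome position (501 nt unless clipped at
a contig edge, in which case the window is flagged). `count_mnase_cuts()`
turns sequencing reads into per-window cut counts; since it is ambiguous
whether a given protocol's cut sites are best represented by read 5' ends
only or by both fragment ends, the default counts 5' ends of primary
alignments and an `ends = "both"` switch is exposed.

`chec_signal()` computes window RPKMs for the MNase-fusion sample and the
free-MNase control, their log2 ratio with a 0.5-RPKM pseudocount (the
pseudocount value is a documented choice, not derived from data), and a
**mode-centered** LFC: most promoters carry only background cleavage, so
the mode of the LFC distribution estimates the background offset.

`estimate_mode()` fits a log-normal distribution to `2^LFC` — strictly
positive by construction, which makes the fit well-defined even when many
LFCs are negative — and returns `log2` of the analytic mode
`exp(mu − sigma²)`. A kernel-density argmax is available both as an
explicit method and as an automatic fallback when the ML fit degenerates.
For reference, `log2` of a standard log-normal sample has mode
`−1/ln 2 ≈ −1.4427`, which the estimator recovers within ~0.1 at n = 10⁴.
Rather than hard-coding a significance threshold for "bound" promoters,
the centered-LFC scale is returned and any quantile cutoff can be applied
downstream.

# The synthetic-data generator

`sim_config()` + `simulate_experiment()` generate a complete
multi-condition experiment — genome FASTA, GFF3, 5'P and RNA 5'-end tracks,
counts, and ground-truth tables — from a single seed. The generative model,
gene by gene:

* **Transcriptome.** One single-exon CDS per contig (ATG + internal codons
  from a configurable usage distribution + TAA), alternating strands, plus
  dedicated `SPIKE_*` contigs for the spike-in species. Single-exon
  geometry keeps the generator simple; splice-aware coordinate mapping is
  exercised separately by hand-built multi-exon fixtures.
* **Abundance and solubility.** Log-normal expression; solubility
  `s_g ∈ (0.2, 0.8)` (or an explicit planted grid via `s_values`). The
  total pool contains all molecules; the soluble library is a **binomial
  thinning** by `s_g` — the simplest model in which total is a superset of
  soluble. Planted red/green genes move `s_g` by a configurable fold in
  opposite directions under the two depletions.
* **5'P ends.** Each decay intermediate is placed co-translationally with
  probability π (`periodic_fraction`, exposed per fraction rather than
  fixed — the in-vivo mixture of co-translational and other decay routes
  is not identifiable a priori): an A-site codon is drawn with weight
  `exp(−a·tAI)` times a linear positional ramp (one-parameter stand-in for
  delayed decay onset: less signal early in the CDS, more late), and the
  end placed 17 nt upstream. Otherwise the end is uniform. Spike-in genes
  are never periodic and are condition-invariant.
* **Counts.** Molecule counts are negative-binomial with dispersion
  `nb_dispersion` (default 0.01, representing tight replicate agreement of
  a controlled experiment — roughly the technical-plus-minimal-biological
  variability of good yeast replicates at moderate expression; raise it to
  stress-test estimators under noisier biology).
* **No sequencing-error model.** Base-call errors are orthogonal to every
  estimator under test; PAR-CLIP background is a flat rate parameter
  instead.

All randomness flows through per-library seeds derived from the master
seed, and every routine restores the caller's RNG state, so a fixed config
gives **byte-identical outputs** (the emitted manifest of md5 digests is
compared across runs in the test suite). `gene_params()` regenerates the
exact ground-truth parameters from the config, and the `truth_*` tables
are serialized beside the data.

Companion generators `simulate_chec()` (Poisson cut counts over promoter
windows with a planted bound subset) and `simulate_parclip()` (Poisson
transitions with planted higher/lower cross-linking subsets) provide
ground truth for the ChEC and PAR-CLIP estimators.

## Generator realism and limits

The generator is built for *verifiability*, not for mimicking every
feature of real libraries: genes are single-exon, UTRs are absent (tracks
cover the CDS only), RNA-Seq reads are represented by their 5' ends,
fragment-length and GC biases are not modeled, and 5'P ends upstream of
the CDS (e.g. from the first 5 codons' protected positions) are not
generated. Consequences worth knowing: a start-anchored metagene of
simulated data has no signal at negative offsets, and the shifted profile
concentrates all periodic mass on codon starts within the CDS.

# A small worked example

```{r example}
cfg <- sim_config(n_genes_target = 60, n_genes_spike = 10,
                  conditions = c("WT", "not1d", "not4d"),
                  condition_deg = list(WT = c(soluble = 1, total = 1),
                                       not1d = c(soluble = 0.6, total = 1.2),
                                       not4d = c(soluble = 1.8, total = 1.2)),
                  seed = 1L)
sim <- simulate_experiment(cfg)
sol <- solubility(sim$counts)
by_cond <- split(sol, sol$condition)
d1 <- ratio_of_ratios(by_cond$not1d, by_cond$WT)
d4 <- ratio_of_ratios(by_cond$not4d, by_cond$WT)
inter <- ratio_of_ratios(by_cond$not1d, by_cond$not4d)
table(classify_categories(d1, d4, inter)$category)
```

```{r frames}
ts <- sim$tracksets_5p[["WT_total_5P_rep1"]]
round(frame_fractions(ts, sim$catalog), 1)
```

```{r rdo}
occ <- rdo(ts, sim$catalog)
head(occ[order(-occ$occupancy), ], 3)
```

# Command-line interface

`system.file("scripts", "fivepsol.R", package = "fivepsol")` is a thin CLI
over the same functions: subcommands `simulate`, `count`, `solubility`,
`degradation`, `interaction`, `classify`, `rdo`, `metagene`, `frames`,
`windows`, `parclip`, `chec` and `report`, each writing TSVs plus a run
manifest recording the package version, all parameters, and md5 digests of
inputs and outputs. Exit codes are 0 (ok), 1 (user error), 2 (internal
error); logs go to stderr and results to files only.
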