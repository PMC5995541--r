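---
title: "Calling cotranslational clients from proximity-specific ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling cotranslational clients from proximity-specific ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboprox)
```

## The measurement and its model

Proximity-specific ribosome profiling compares two footprint libraries per
bait and replicate: a streptavidin **pulldown** of ribosomes biotinylated by
a membrane-anchored BirA fusion, and the total monosome **input**. The
underlying assumption is that, up to library depth, the expected pulldown
count at a codon is the input count times a position-dependent labeling
efficiency; everything the package computes is a ratio estimator of that
efficiency profile.

Because single-codon counts are noisy, the estimator works on boxcar
windows: at codon $i$ the enrichment is

$$E(i) = \frac{W_p(i) / N_p}{W_x(i) / N_x},$$

with $W_p, W_x$ the pulldown and input footprint sums over $i \pm h$ codons
(edge-truncated) and $N_p, N_x$ the total mapped reads of each library. The
reads-per-million constant cancels and is omitted. Specific engagement by
the test bait is separated from generic ER localization by dividing by the
same quantity computed for a reference bait — a tail-anchored general-ER
fusion that shares the targeting ramp but not client engagement. The
per-gene statistic is the **maximum** of this ratio-of-ratios over defined
positions: it asks whether any region of the nascent chain is
preferentially labeled, without assuming where.

Clients are genes whose maximum is in the top decile of eligible genes in
*every* biological replicate. Replicates are kept separate through ranking
and intersected only at the end, so a single noisy library cannot promote a
gene.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `window_half_width` | 50 | codons | 101-codon window; smooths footprint noise at the scale of a protein domain |
| `read_length_nt` | 25 | nt | synthetic read length for the mappability filter |
| `mappability_threshold` | 0.80 | fraction | genes must exceed it strictly; removes paralog artifacts |
| `expression_cutoff` | 0.02 | reads/codon/million | strict; removes genes too shallow to rank |
| `localization_ratio_min` | 1 | — | strict RPKM pulldown/input bound in ≥ 1 pair; gene length cancels |
| `client_percentile` | 90 | percent | "top 10%" in every replicate |
| `n_bootstrap` | 10,000 | subsets | composition resampling depth |
| `ci_percentiles` | (5, 95) | percent | null band for composition ratios |
| `proteome_log2_threshold` | 0.5 | log2 | inclusive down/up-in-both boundary |

## Numerical and semantic choices

* **Edge handling.** Windows are truncated at gene boundaries rather than
  discarding the first and last $h$ codons, so profiles keep the gene's
  length and TMDs near termini remain visible.
* **Zero denominators.** A position whose input window is empty has an
  undefined enrichment (`NA`), never an infinity and never a pseudocount;
  the zero-window eligibility filter removes such genes from ranking, so a
  pseudocount would only distort genes that are excluded anyway. Likewise a
  position where the reference bait's enrichment is zero or undefined has
  an undefined ratio-of-ratios.
* **Percentile rule.** With $n$ eligible genes the client threshold is the
  order statistic at rank $\lfloor n p / 100 \rfloor + 1$ and every gene at
  or above it qualifies. This realizes "top 10%" counting semantics
  deterministically: 10 genes yield exactly the top one, and a fully tied
  set qualifies in its entirety.
* **Ranking universe.** Percentiles are computed among eligible genes
  (after all three filters), since ineligible genes have no reliable
  statistic; `rank_among_all = TRUE` switches to ranking among all genes
  with a defined maximum for comparison.
* **Strictness.** Mappability, expression and localization bounds are
  strict (`>`); the client percentile and the proteome log2 boundary are
  inclusive (`>=`). Boundary cases are pinned by tests.
* **Composition bootstrap.** Residues are pooled across spans (long TMDs
  weigh more), subsets are drawn without replacement with size equal to the
  number of client TMD *spans*, and a property absent from the whole pool
  has an undefined ratio rather than a division by zero. A fixed seed
  reproduces the band bit-for-bit.
* **Residue classes.** The five classes overlap by design (F is aromatic
  and hydrophobic; Y aromatic and polar; G and P carry no class). The table
  ships as `inst/extdata/aa_properties.tsv` so alternative conventions
  (e.g. histidine as charged) are a one-line edit.
* **TMD merging.** Predicted spans overlapping a curated span of the same
  gene (≥ 1 shared residue) are dropped in favor of the curated span;
  spans on excluded genes (mitochondrial, dubious, pseudogenes) are removed
  first.

## What the simulator emulates — and what it does not

The generator plants the structure the analysis assumes, so recovery is a
meaningful test of the statistics rather than of alignment upstream:

* Input coverage is flat per codon at `input_depth × expression factor`,
  with Poisson (optionally negative binomial) noise, independent across
  replicates. Expression factors are log-normal (`sdlog` 0.75, a spread
  typical of expressed transcriptomes) and 5% of non-TMD genes are
  essentially silent, so the expression and zero-window filters do real
  work rather than passing everything.
* Every ER bait's pulldown carries a logistic targeting ramp centered 60
  codons after the first TMD (width 20 codons, amplitude 3): the smooth
  rise reflects the gradual hand-off of translating messages to the ER
  rather than a hard switch. Client genes additionally multiply their
  pulldown mean by `client_peak_gain` (default 4) from 20 codons after the
  end of their TMD cluster — under the test bait only. Clients are drawn
  from multipass genes (clusters of 2–5 TMDs with 3–12 codon loops, first
  TMD starting at codon 30–80), with an expected client fraction of 0.2 of
  TMD genes.
* All simulated libraries report a common sequencing depth as their total;
  this is the depth-matched-library idealization, and it makes the
  infinite-depth (analytic) mode exact: the recovered maximum
  ratio-of-ratios of a planted client equals the planted gain to floating
  precision, a closed-form anchor the tests assert.
* Simulated protein sequences use a globular background alphabet with
  hydrophobic-rich TMD spans; client TMDs are salted with charged/aromatic
  residues at rate `client_tmd_charge_boost` so the composition bootstrap
  has a planted signal. These sequences are generated independently of the
  uniform-nucleotide CDS used for mappability — the pipeline never
  translates the CDS, and keeping the two independent avoids building a
  codon model the analysis does not need.
* The proteome table shifts clients by −1 log2 in both knockdowns with
  noise SD 0.2, and marks a 10% minority of clients as translationally
  driven.

Passing tests on this generator show that the statistics recover planted
structure under calibrated noise. They do not show robustness to features
real data have and the generator omits: codon-level pausing and ligation
bias, rRNA contamination, 3′ ramp artifacts, multi-mapping beyond the CDS
universe, batch effects between replicates, and proteome missingness —
real SILAC tables lack many proteins, whereas the simulator observes all.

## Problem sizes and determinism

The test suite exercises the oracle equivalences on hundreds of small
random instances, end-to-end recovery on ten studies of 500 genes at depth
20 reads/codon, and bootstrap calibration with 500 null experiments at
1,000 resamples — sizes chosen to estimate each property with comfortable
margins while keeping the suite quick to run routinely. Every stochastic
stage takes an explicit seed, derived stage seeds come from one base
integer, and identical seeds give byte-identical output files.

## Known limitations

* Mappability is assessed against the sense strand of the CDS pool only,
  exact matches only; genome-wide multi-mapping and mismatch tolerance are
  out of scope.
* Counts are consumed already assigned to codons; P-site offsetting of raw
  reads is upstream of the package.
* Client membership is a ranking, not a significance test: no FDR is
  attached, and the decile rule calls ~10% of eligible genes per replicate
  whatever the data. The intersection across replicates, not a test, is
  what controls false calls.
* "Down in both knockdowns" is a fold-change rule; with replicated
  proteomes a moderated test would be preferable, but a threshold is the
  honest reading of a two-sample SILAC design.
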