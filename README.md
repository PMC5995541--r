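# riboprox

Identification of cotranslationally engaged client proteins from
proximity-specific ribosome profiling, with companion tools for
transmembrane-domain (TMD) composition analysis and dual-knockdown SILAC
proteome client calling.

## The problem

Proximity-specific ribosome profiling tags ribosomes translating near a
membrane-anchored biotin ligase (BirA) fusion, purifies them, and sequences
their footprints alongside the total (input) pool. For a bait such as a
subunit of the ER membrane protein complex (EMC), genes whose nascent chains
are engaged by the bait show localized pulldown enrichment shortly after the
ribosome synthesizes the engaging element — typically a cluster of TMDs.
`riboprox` turns per-codon footprint counts into ranked client calls:

* **Windowed enrichment.** For each codon *i* of each gene, with window sums
  over `i ± 50` codons (101 codons total, edge-truncated) and per-sample
  depth normalization,

  `E(i) = [W_pulldown(i) / N_pulldown] / [W_input(i) / N_input]`

  where `W` is the windowed footprint count and `N` the sample's total
  mapped reads. Positions with an empty input window are undefined, never
  infinite.

* **Ratio of ratios.** Enrichment for the test bait divided by enrichment
  for a general-ER reference bait (a tail-anchored fusion), position by
  position; the per-gene statistic is the maximum over defined positions,
  which captures "has any region engaged specifically by the test bait".

* **Eligibility filters.** Genes must (1) have > 80% of CDS positions
  uniquely mappable by synthetic 25-nt reads against the CDS pool,
  (2) exceed 0.02 reads/codon/million in every input library and contain no
  empty 101-codon window in any library, and (3) have
  RPKM(pulldown)/RPKM(input) > 1 in at least one sample pair. All bounds
  are strict.

* **Client calling.** Among eligible genes, clients are genes whose maximum
  ratio-of-ratios is in the top 10% in **every** biological replicate
  (nearest-rank threshold, ties included).

Around the core sit: a metagene average aligned to the start of the first
TMD (targeting ramp ~60 codons downstream, client-specific late rise), a
merger of predicted and curated TMD annotations (curated wins on overlap),
bootstrap resampling of amino-acid property composition of client TMDs
(10,000 random same-size TMD subsets, 5th–95th percentile band), and a
dual-knockdown SILAC caller (down-in-both at |log2| ≥ 0.5, inclusive).
A seeded simulator generates transcriptomes, footprint profiles and
proteome tables with planted clients so every stage is testable offline.

## Worked example

```r
library(riboprox)

cfg <- pipeline_config(rng_seed = 42)   # all thresholds at their defaults
res <- run_pipeline(cfg)                # simulates a study, then analyzes it
#> simulating dataset (seed 42)
#> mappability filter: 500/500 genes pass
#> expression filter: 486 genes pass
#> localization filter: 483 genes pass
#> 470 eligible genes; 41 clients called
#> 40 proteins down in both knockdowns

head(res$calls[res$calls$is_client,
               c("gene_id", "replicate_id", "max_value", "percentile_rank")], 4)
#> # A tibble: 4 × 4
#>   gene_id replicate_id max_value percentile_rank
#>   <chr>   <chr>            <dbl>           <dbl>
#> 1 g0001   rep1              4.01            92.1
#> 2 g0010   rep1              4.19            94.7
#> 3 g0016   rep1              4.36            98.7
#> 4 g0030   rep1              4.23            95.5
```

Each client row gives the gene's maximum positional ratio-of-ratios in one
replicate (the simulator plants a 4-fold client peak; recovered maxima
cluster just above 4) and its percentile rank among eligible genes; a gene
is a client only if it ranks at or above the 90th percentile in both
replicates. TMD composition of the called clients, with the resampled null
band:

```r
res$property_enrichment
#> # A tibble: 5 × 6
#>   property    fraction_clients fraction_all ratio ci_low ci_high
#>   <chr>                  <dbl>        <dbl> <dbl>  <dbl>   <dbl>
#> 1 ALIPHATIC             0.536        0.568  0.944  0.979    1.02
#> 2 AROMATIC              0.161        0.143  1.12   0.941    1.06
#> 3 CHARGED               0.0724       0.0430 1.68   0.882    1.12
#> 4 HYDROPHOBIC           0.710        0.736  0.965  0.986    1.01
#> 5 POLAR                 0.169        0.167  1.01   0.949    1.05
```

The charged-residue ratio (1.68) sits well outside its null band — the
simulator salts client TMDs with charged/aromatic residues, and the
bootstrap detects exactly that planted excess.

A thin command-line wrapper is available after install as `exec/riboprox`
(`riboprox simulate --seed 7 --out-dir out/`,
`riboprox run-all --seed 7 --out-dir out/`); every output table carries a
`# config:` header echoing the thresholds used.

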