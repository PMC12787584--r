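# pioneerscan

Chromatin-state targeting analysis for pioneer transcription factors.

When a transcription factor is expressed ectopically (e.g. in fibroblasts),
its ChIP-seq binding sites land on very different kinds of silent chromatin:
DNase-accessible regulatory elements, nuclease-resistant "closed" chromatin
with low- or high-turnover nucleosomes, and broad H3K9me3/H3K27me3
heterochromatin domains. Beyond called peaks, a factor also leaves
reproducible low-level ChIP signal — *sampling* — at a large share of its
genomic motif instances. `pioneerscan` implements this analysis stack as a
tested, reusable R package for epigenomics analysts:

- **Accessibility partitioning** — each peak's preexisting DNase signal
  (mean RPM over the peak) splits the cistrome at a cutoff *t* (default
  0.05 RPM): accessible iff DNase > *t*. H2B-turnover labels (high/low) come
  from the central 100 bp the same way.
- **Heterochromatin local-density subtypes** — for peaks inside
  H3K9me3/H3K27me3 domains, the ratio
  *r* = center / (flank + ε), with the center mean over ±0.5 kb and flanks
  at ±5 kb, classifies sites as `high` (*r* ≥ 1.5, focal enrichment),
  `moderate` (flank-level signal), or `low` (*r* ≤ 0.67, gaps inside broad
  domains).
- **Motif sampling cistrome** — genome-wide PWM hits (log-odds in bits,
  s(w) = Σᵢ log₂ pᵢ(wᵢ)/qᵢ(wᵢ), both strands) are classified per instance:
  `bound` iff overlapping a consensus peak; otherwise `sampled` iff the
  central-100-bp IP signal exceeds the 95th percentile of the same signal
  over the motif set shifted +10 kb (the background null); else
  `unsampled`. Low-coverage instances (≤ 75% of the window covered) are
  excluded. Transition tables track class flows between conditions.
- **Peak-set comparison** — replicate-consensus construction, retained% and
  gained% between conditions (denominator: the first condition's consensus
  count, so gained can exceed 100%), and gained/shared/lost against an
  external reference set.
- **Binned motif enrichment** — peaks cut into 10 equal-size DNase bins;
  per motif and bin a one-sided binomial test of foreground hit frequency
  against the other bins, BH-adjusted; reported when −log₁₀(adj p) > 2 and
  foreground frequency > 5%.
- **Chromatin-state overlap enrichment** — fold(s, c) =
  (bases of class c in state s / class bases) ÷ (state bases / genome size).
- **Synthetic genomes with planted truth** — a generator that plants
  chromatin states, repressive domains with internal gaps, and motif
  instances with known classes, so every stage above is verifiable by
  parameter recovery.

## Worked example

```r
library(pioneerscan)

spec  <- synthetic_spec(seed = 1)          # 4 chromosomes x 2 Mb, 1000 motifs
g     <- generate_synthetic_genome(spec)
peaks <- consensus_peaks(g$peaks)          # peaks present in both replicates

# 1. accessibility of the binding sites
calls <- classify_accessibility(peaks, g$tracks$dnase)
attr(calls, "closed_fraction")
#> [1] 0.7333333

# 2. motif sampling against the shifted-motif background
res <- classify_motifs(g$motifs, g$tracks$ip, peaks)
res
#> sampling_result: 1000 motifs ( 1000 unfiltered )
#>   background threshold (RPM): 0.04922 over 999 background motifs
#>   bound 3.0% | sampled 31.2% | unsampled 65.8%

# 3. heterochromatin targeting subtype
doms <- intersect_domains(peaks, g$truth$domains)
ld   <- local_density(doms$H3K9me3, g$tracks$h3k9me3, mark = "H3K9me3")
factor_subtype_summary(ld)
#> heterochromatin local-density subtype fractions:
#>         high moderate low
#> H3K9me3    0        1   0
#> majority subtype: H3K9me3=moderate
```

The `closed_fraction` is the share of peaks at or below 0.05 RPM DNase
(here 73%, reflecting the planted state mix among bound motifs). The
sampling result recovers the planted class fractions (3% / 31% / 66%)
within fractions of a percentage point: the background threshold of
~0.049 RPM is the 95th percentile of central signal over the +10 kb shifted
motifs. The heterochromatin summary classifies the three K9-domain peaks of
this run as `moderate` (domain-level signal at the site, ratio ≈ 1).

All the numbers above are printed by the code as shown; real ChIP-seq
inputs enter the same functions through `read_bed()` /
`read_bedgraph()` / `read_jaspar()`.

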