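---
title: "pioneerscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pioneerscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`pioneerscan` classifies where an ectopically expressed transcription factor
engages chromatin: which of its ChIP-seq peaks sit on preexisting
DNase-accessible versus resistant chromatin, how its heterochromatin targets
relate to local H3K9me3/H3K27me3 density, and which of its genomic motif
instances are bound, sampled, or unsampled. The package consumes standard
plain-text formats — BED3–6 and narrowPeak intervals, 4-column bedGraph
signal, JASPAR-style PWM text, and a labeled chromatin-state segmentation
BED — and exposes each analysis as an ordinary R function returning a
classed S3 result.

Two coordinate conventions run through everything:

* **0-based, half-open intervals** (the BED convention). An interval
  `[start, end)` covers `end - start` bases; two intervals overlap when they
  share at least one base under this convention, which matches `bedtools`
  defaults. Overlap queries are delegated to `GenomicRanges`/`IRanges`.
* **Binned signal tracks with a coverage mask.** A `signal_track` stores one
  float vector per chromosome at a fixed bin width plus a parallel logical
  mask that is `TRUE` where at least one read informed the bin. Uncovered
  bins hold a fill value of 0 that is *never* treated as data: interval
  means count uncovered bases as 0 in the numerator but keep them in the
  denominator, and every classification that depends on sparse coverage
  (the sampling analysis) carries the covered fraction alongside the mean.

Signal subtraction (`subtract_input`) retains negative values rather than
clipping: the coverage-track chain (genome coverage → RPM → IP − input)
does not clip, and the sampling analysis depends on the behavior of
near-zero signal. Strand is carried but ignored by all signal operations.

# Signal extraction

`average_over_interval` is the workhorse: the covered-weighted base sum over
the interval divided by interval length. `central_window_mean(width = 100)`
applies it to the window centered on `floor((start + end) / 2)`; at
chromosome edges the window is clipped and the denominator reduced, keeping
edge means unbiased. `signal_matrix` builds reference-point matrices
(center or summit) with `missing_as_zero` semantics, and `metaprofile`
takes column means. All of these are verified against per-base brute-force
oracles to 1e-9 in the test suite.

Peak-width standardization (`standardize_widths`) recenters every peak on
its midpoint and fixes the width at the rounded mean width of the set
(round-half-up — the convention had to be chosen; it is stated here rather
than hidden). It runs before binned motif enrichment so that foreground and
background sequences are length-matched.

# Accessibility classification

A peak is `accessible` when its full-peak DNase mean strictly exceeds the
cutoff (default **0.05 RPM**) and `resistant` otherwise. The strict
inequality matters: the underlying split predicates (`> cutoff` on one side,
`< cutoff` on the other) assign an exact tie to neither class, and a total
classifier must decide — ties go to `resistant`, the conservative choice
when the claim of interest is closed-chromatin targeting. The cutoff is a
parameter throughout; its default reflects empirical practice on
RPM-normalized DNase tracks, and the package deliberately does not attempt
to re-derive it. Motif instances are split the same way over their central
100 bases.

Turnover (6h H2B pulse) has no established absolute RPM cutoff, so
`classify_turnover` defaults to the peak-set median of central-window
turnover means, overridable. A median cutoff reproduces a high/low
dichotomy without inventing an absolute value; it presumes the peak set
genuinely mixes the two regimes (with a grossly unbalanced mix, supply an
explicit cutoff).

Binned motif enrichment sorts peaks by DNase level into `n_bins = 10`
equal-size bins — remainder peaks are appended to the final, most
accessible, bin (a deterministic and documented choice) — and tests each
motif's foreground hit frequency (fraction of peak sequences with ≥ 1 PWM
hit at the PWM's score threshold) against all other bins pooled as
background, with a one-sided exact binomial test (`stats::binom.test`).
P-values are Benjamini–Hochberg adjusted across all (motif, bin) pairs
(`stats::p.adjust`); the procedure is named here because "adjusted" alone
underdetermines it. Log2 enrichment uses a continuity term
ε = 1/(2·bin size). A motif is reported when −log₁₀(adj p) > 2 **and**
foreground frequency > 5%.

# Heterochromatin local-density subtypes

Factors targeting repressive domains fall into three qualitative groups:
sites where the mark is focally enriched over the flanking domain, sites as
enriched as their flanks, and sites of local depletion exploiting small
gaps inside broad domains. The package operationalizes this with explicit
geometry and thresholds, because a reproducible pipeline needs a pure
function where the original grouping was visual:

* center = mean mark signal over ±0.5 kb of the peak center (1 kb window);
* flank = pooled mean of two 2 kb windows centered at ±5 kb;
* ratio = center / (flank + ε) with ε = 1% of the track's median nonzero
  value, so classification is exactly invariant under rescaling the track
  and ratios stay finite at domain edges;
* subtype = `high` if ratio ≥ 1.5, `low` if ratio ≤ 0.67, else `moderate`.

The 1.5/0.67 pair is symmetric on the log scale and separates the planted
three-way synthetic fixture cleanly; all four numbers are config-exposed
defaults, not claims about a canonical biological boundary. Domains are
merged per mark (bookended intervals joined) before intersection, and a
peak may carry both marks. `factor_subtype_summary` breaks per-mark
majority ties deterministically as high > moderate > low.

# The motif-sampling cistrome

`scan_pwm` scores every genomic window on both strands as the log-odds sum
(bits) of window bases against the PWM probabilities over the background
composition; windows containing `N` never match, and opposite-strand hits
over the same window deduplicate to the higher score (ties to `+`).
Count matrices are converted with a per-cell pseudocount so zero counts
stay scoreable. Exactness is enforced by an exhaustive all-windows oracle
in the tests.

`classify_motifs` then assigns every instance one of four labels:

1. `filtered` — covered fraction of the central 100 bp ≤ 0.75. The filter
   exists to exclude low-coverage and unmappable regions; the package
   retains instances with covered fraction *above* 0.75 (the reading
   consistent with that purpose).
2. `bound` — overlaps ≥ 1 consensus peak. Peak overlap takes precedence
   over any signal threshold: a peak-overlapping motif is bound even if its
   central signal happens to fall below the sampling threshold.
3. `sampled` — central signal strictly above the background threshold.
4. `unsampled` — the rest.

The background threshold is the **0.95 quantile** of central signal over
the motif set shifted +10 kb (itself coverage-filtered). No published
numeric rule separates "sampled" from "unsampled"; the shifted-background
quantile operationalizes "specific low-level sampling at motifs, none at
shifted sites", and the quantile is a parameter. Two consequences are
tested as invariants: raising the quantile can only shrink the sampled set,
and bound calls are unaffected by it. Shifted instances that land inside
peaks are retained in the background distribution (no exclusion is
applied); with realistic motif densities this inflates the threshold
negligibly, but at several-fold higher density the 95th percentile can
jump into the signal regime — a documented failure mode, visible in the
generator when motif spacing is pushed far below ~5 kb per motif.

Class fractions are reported over unfiltered motifs and sum to 1.
`transition_table` cross-tabulates classes between two conditions over the
identical motif list, counting only motifs unfiltered in both.

# Peak-set comparison

`consensus_peaks` keeps a first-replicate peak iff it overlaps ≥ 1 base
(configurable) of at least one peak in *every* other replicate, anchored to
replicate-1 coordinates. `compare_conditions` classifies loci as `shared`
(detected in ≥ 1 replicate of each condition), or `unique` to a condition
(in all of its replicates, in none of the other's). Percentages use the
**first condition's consensus count as denominator** — the only convention
under which a "gained" percentage above 100% is meaningful — and the
package states this prominently rather than leaving the denominator
implicit. Overlapping loci from the two conditions are merged keeping
condition A's coordinates so Venn totals do not double-count.

# Chromatin-state overlap enrichment

`overlap_enrichment` computes, for state *s* and class *c*,
fold(s, c) = (bases of *c* in *s* / total bases of *c*) ÷ (bases of *s* /
genome size), in bases rather than motif counts so the statistic is
insensitive to motif length heterogeneity. The segmentation must tile the
genome; gaps are an error listing the uncovered spans. Two identities are
enforced in tests: a single-state segmentation gives fold 1 for every
class, and the state-fraction-weighted mean fold equals 1 per class (total
probability). Training the segmentation is out of scope — it is an input.

# The synthetic genome generator

`generate_synthetic_genome` builds the ground-truth world every recovery
test runs against. Default conditions (chosen once, as a realistic
desk-scale miniature of a fibroblast epigenome, and not revisited):

| parameter | default | rationale |
|---|---|---|
| genome | 4 chromosomes × 2 Mb, 10-b bins | whole pipeline in seconds; room for ≥ 1000 motifs and multi-kb domains |
| state mix | open 0.25, closed 0.45, K9 0.15, K27 0.15 | silent chromatin dominates a fibroblast genome |
| repressive domains | 2 per mark per chromosome (~150 kb) | "broad domain" regime, wide enough for internal structure |
| gaps | Poisson(2) per domain, 2 kb wide, signal ×0.1 | small local depletions strictly inside domains |
| motif classes | bound 0.03, sampled 0.31, unsampled 0.66 | the regime of a factor binding few, sampling many motifs |
| IP bumps | Gaussian, σ = 200 b; amplitudes 5 (bound) / 0.5 (sampled) RPM; noise σ 0.05 | σ ≈ the 300–500 bp ChIP fragment footprint; 10:1 and 10:1 separations |
| DNase | open 2.0, closed 0.01 RPM (25% relative noise) | clean separation around the 0.05 cutoff |
| turnover | high 1.5, low 0.05 RPM | mirrors the DNase dichotomy |

Class and state assignment use largest-remainder apportionment followed by
a seeded shuffle, so truth-level fractions are *exact* (1000 motifs at
0.03/0.31/0.66 give exactly 30/310/660) and any recovery error is
attributable to the pipeline, not the generator. Motifs are planted ≥ 1 kb
apart inside their target state with a 1 kb margin from state boundaries;
the PWM consensus is written into a seeded i.i.d. background sequence.
Peaks are emitted at bound motifs only, as two pseudo-replicates with
configurable dropout. Heterochromatin test sites (high / flat / gap) are
planted on an 8 kb grid at least 6.5 kb from domain edges so the ±5 kb
flank geometry never leaves the domain; fitting ≥ 100 sites per subtype
therefore needs larger repressive fractions (0.4/0.4) than the default
mix, which is what the heterochromatin recovery experiment uses. All
randomness derives from the single seed; a fixed seed reproduces the
bundle byte for byte.

What the generator does **not** emulate — and hence what passing recovery
tests do not show about real data: mappability structure (tracks are fully
covered, so the 75% coverage filter is exercised only by constructed
fixtures), fragment-length and GC biases, correlated replicate noise,
motif-density hotspots, partial/degenerate motif matches under nucleosomes,
and any coupling between motif class and sequence context beyond state
membership. Recovery results bound implementation error, not biological
error.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design: the
default 4 × 2 Mb genome for sampling recovery (1000 motifs), 2 × 1 Mb
genomes for accessibility recovery (400 motifs, 200 peaks), 300 planted
heterochromatin sites for subtype recovery, and thousand-instance oracle
comparisons for the signal primitives at 1e-9 tolerance. Determinism is
checked at the byte level on written TSV/bedGraph output. Remaining
numerical conventions, collected in one place: window centers use
`floor((start + end) / 2)`; clipped windows reduce the denominator;
accessibility ties go to `resistant`; subtype summary ties go
high > moderate > low; equal-size bin remainders go to the most accessible
bin; PWM strand ties go to `+`; round-half-up for width standardization.

# Known limitations

* The three-way heterochromatin classifier and the 0.95 sampling quantile
  are operationalizations of qualitative groupings; their defaults separate
  the synthetic fixtures cleanly but are not biological constants, and both
  are exposed as parameters.
* The shifted-motif background assumes +10 kb is far enough to be
  signal-free; in dense cistromes this should be checked (the package
  reports the background threshold for inspection).
* bedGraph is the native signal dialect; bigWig input should be converted
  upstream.
* Fractions such as the share of motifs sampled depend on sequencing depth
  and the peak caller feeding the consensus set; the package classifies
  relative to its inputs and makes no depth correction.
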