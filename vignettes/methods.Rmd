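---
title: "Methods: chromatin-domain analysis on synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-domain analysis on synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`hetdomain` analyses gene regulation inside heterochromatin-like
chromosomal domains: compact, repeat-rich regions in which silencing
marks (HP1a, H3K9 di-/trimethylation) cover actively transcribed genes.
The pipeline consumes four kinds of evidence — probe-level enrichment
tracks (M = log2 ChIP/input), stranded run-on read densities, promoter
sequences, and per-gene expression — and produces domain-resolved
summaries: enriched regions, combinatorial chromatin states, metagene
profiles, polymerase pausing statistics, promoter sequence features, and
mutant-versus-wildtype contrasts.

All computations assume a genome partitioned into labelled domains
(`euchromatin`, `pericentric_heterochromatin`, `chr4`,
`chr4_proximal`); genes belong to the domain containing their TSS
(half-open containment, so a TSS on a boundary start belongs to the
interval beginning there). Internally every coordinate is 0-based,
half-open; GFF3 converts at the file boundary. Interval-valued track
records (bedGraph, WIG with a span) are reduced to point probes at the
interval midpoint (floor) — array probes are treated as point
measurements, and a single convention avoids off-by-one drift. An
unstranded gene is treated as plus-strand wherever orientation matters.

# Track-level statistics

**Smoothing** is a centered moving average over probes within ± half the
window (default 500 bp). It preserves constants and is
shift-equivariant; no kernel weighting is applied because probe spacing
is the resolution limit of the platform the pipeline models.

**Enriched-region calling.** The M-value distribution of a smoothed
track is mostly null with an enriched right tail. The null is a Gaussian
centred on the half-sample mode with a robust SD estimated from the left
half of the distribution (1.4826 × the median absolute deviation of the
left-of-mode values), so the enriched tail cannot inflate it. Per-probe
upper-tail p-values undergo Benjamini–Hochberg step-up control at the
target FDR (default 1e-3); significant probes within 1,000 bp merge into
one region, and regions carried by fewer than 3 significant probes are
discarded (array-resolution guards; both configurable). A constant track
has zero left-spread and is reported as zero regions rather than an
error. Tracks with fewer than 10 probes cannot support the null fit and
raise an error.

**Replicate consistency** follows two published rules: replicates pass
if region lists overlap by more than 75% (fraction of regions in either
replicate with any genomic overlap in the other; a base-pair Jaccard
variant sits behind `by = "bp"` because the original phrasing does not
say which), or if the top 40% of regions by score share more than 80%.

**Cross-condition normalization.** The mutant scaling factor is the
ratio of the raw median absolute deviations of lagged probe differences,
`median|d_WT − median(d_WT)| / median|d_mut − median(d_mut)|`,
`d_i = x_{i+1} − x_i` computed within chromosomes. Lagged differencing
cancels additive offsets and slow spatial structure, so the statistic
estimates the probe-noise scale; a constant mutant track (zero MAD) is a
hard error rather than an infinite factor. Pol II tracks are instead
quantile-normalized (reference = mean of sorted vectors, ties averaged —
the standard deterministic choice, delegated to
`limma::normalizeQuantiles`), because mutant Pol II redistributes rather
than rescales.

# Chromatin states

Bins (500 bp) with complete mark data are z-scored per mark and
clustered by K-means (`k_initial = 10`, 10 restarts, fixed seed).
Clusters are then merged iteratively — highest correlated centroid pair
first — while any pairwise Pearson correlation exceeds the merge
threshold (0.8). Correlations are taken between centroids mapped back to
the original M-value scale: on the standardized scale the centroids of a
single homogeneous population scatter symmetrically around the origin
with arbitrary pairwise correlations, and the intended collapse to one
state could never occur; on the original scale the shared mark signature
dominates and homogeneous data collapse correctly. Merging by pattern
correlation is only meaningful with at least three marks (two-mark
centroid correlations are always ±1), which the documentation flags.
Final states are ordered by their silencing-mark centroid (a mark
matching "H3K9me2" by default) and named A, B, …, giving reproducible
labels whose biological identity is reported, not assumed.

# Metagene and feature-class profiles

Expression classification: RPKM tables use log10(RPKM+1) > 0.6 (cell
lines) or > 0.4 (larvae); FPKM tables use log2(FPKM+1) > 1.4. Metagene
profiles scale each gene body onto 60 bins (50 bp at the 3-kb reference
scale) with ±2 kb flanks sampled at 50 bp; minus-strand genes are
orientation-reversed; bins are filled with the mean of their probes and
empty bins are linearly interpolated between neighbours (sparse-array
pragmatics; flank sampling by bin means rather than point interpolation
was an open choice, decided for symmetry with the body bins). Genes with
fewer than two body probes are skipped with a message. The SEM is
computed across genes at each position, matching the per-figure
convention of averaging genes, and a single gene reports SEM 0 by
convention. Per-gene heatmap matrices keep TSS/TES ± 500 bp unscaled and
therefore admit only genes ≥ 1 kb.

Feature-class means summarise three classes per domain — active TSS
(± 500 bp), active gene body (gene minus the TSS window), silent region
(everything else in the domain) — reporting both the gene-weighted mean
with SEM across genes (the figure-style summary; silent regions use
contiguous segments as the replication unit) and the probe-weighted mean
with probe counts. Ratio estimates such as mutant retention factors use
the probe-weighted means pooled across classes: when a mutant effect
applies domain-wide, that pooled ratio is the precision-weighted
estimator, whereas gene-weighted TSS means rest on an order of magnitude
fewer probes per gene and are correspondingly noisier.

# Polymerase pausing

Two pausing indices are implemented. The run-on definition is the mean
per-bp density over the first 500 bp from the TSS (gene strand only —
run-on signal is stranded, antisense reads are ignored) divided by the
mean over the next ⌈0.25·(L−500)⌉ bp. It is computed by exact
summation, is invariant to uniform scaling of the track, and handles
the limits explicitly: x/0 → ∞ (paused at any threshold), 0/0 →
undefined, and an undefined PI removes the gene from the
polymerase-associated denominator rather than counting it as
not-paused. The ChIP definition is the maximum enrichment in TSS ±
300 bp divided by the median over the body (600 bp downstream of the
TSS to the gene end). Ratios are taken on the linear intensity scale
(2^M) by default because log-scale ratios can be negative and the
source convention does not state a scale; the log-scale and mean-based
body summaries remain available behind arguments ("medium enrichment"
is read as median, the likely intended word). Default thresholds: 10
(run-on) and 4 (ChIP). Genes shorter than 500 bp and genes overlapping
any other gene (either strand, any overlap — both partners removed) are
excluded before PI computation.

Domain contrasts use a label permutation over polymerase-associated
genes with the statistic fraction(A) − fraction(B) and the add-one
two-sided p-value `(1 + #{|null| ≥ |obs|}) / (1 + n_perm)`, which is
valid (conservative) under the null for any n_perm ≥ 100. TSS peak
offsets are strand-oriented positions of the maximal probe in TSS ±
500 bp, ties resolved to the smallest signed offset (a flat window
deterministically reports the upstream edge); the condition comparison
is the difference in mean offsets. Method overlap first reduces
transcript-level run-on results to gene level by maximal PI, then
intersects top-N lists.

# Promoter sequence features

IUPAC motif scanning is per-position character-class matching on the
forward strand of the TSS-oriented window (pause button KCGRWCG in
TSS ± 60 bp; TRL/GAGA "GAGAG", inverted TRL "CTCTC" and Inr "TCAGTY" in
TSS ± 200 bp — consensus strings are configuration, since only the
factors, not exact patterns, are fixed by convention). An inverted motif
is its own explicit pattern rather than a reverse-complement scan,
mirroring how inverted-site counts are reported separately. `N` never
matches. Overlapping hits are all reported (regex lookahead).

Melting temperatures use two-state nearest-neighbor thermodynamics with
the unified dinucleotide parameter set, terminal initiation corrections,
the entropic salt correction ΔS + 0.368·(n−1)·ln[Na+], and
Tm = 1000·ΔH/(ΔS + R·ln(Ct/4)) − 273.15, at Na+ = 50 mM and total
strand concentration 50 nM (recorded as result attributes). Absolute
Tm values are parameter-set- and concentration-dependent; every
comparative statement the pipeline makes (profiles, domain contrasts)
is invariant to that choice. The 100-bp TSS-downstream profile contains
exactly 92 9-mer offsets; windows containing `N` are dropped from the
per-offset means, and sequences of the wrong length are skipped with a
message.

# Mutant comparisons

A wildtype peak counts as reduced in a mutant when no region called on
the rescaled mutant track (same FDR) covers at least half of it —
reusing the calibrated caller instead of inventing a second test.
Level changes come from feature-class means, extent changes from
enriched-bp totals per domain (base pairs, with region counts reported
alongside, since the source convention does not say which it counts).
The peak-to-repeat distance test preserves peak count and lengths and
places them uniformly (non-overlapping, stick-breaking gaps) in the
domain; p is one-sided for repeat proximity with the add-one rule.
Note a density caveat: if repeats cover a large fraction of the domain
(the assembly-level ~30% of a chr4-like arm), random placements overlap
repeats almost surely and the null median collapses to zero; the
statistic is informative on the sparser, uniquely-mappable repeat sets
such analyses are actually restricted to, and the acceptance script
demonstrates it at ~10% density. Expression contrasts use per-gene
log2((x+1)-ratio) fold changes and a paired Wilcoxon signed-rank test
per domain or supplied gene set (supporting external gene-set
contrasts); identical tables report p = 1 (a paired test on all-zero
differences is otherwise undefined), and groups under 6 pairs are
flagged unreliable.

# The synthetic-data generator

`sim_config()` encodes the study conditions: a chr4-like 1.2 Mb arm with
80 genes (median length 8,001 bp, median 6 exons, log-normal lengths),
~30% repeat density and a pericentric-like proximal 70 kb; a euchromatic
arm with 2,000 genes (median 1,907 bp, 3 exons); and a pericentric
region (120 genes, median 1,844 bp, 2 exons). Genes are packed
sequentially with uniform random gaps; repeats fill intergenic space
first and spill into introns only if the target density requires it.
Mark architecture plants per-(mark, domain, feature-class) M-value means
— gene-body HP1a/H3K9me3/POF enrichment with TSS depletion on active
chr4-like genes, classical heterochromatin in pericentric domains,
background 0 in euchromatin — plus Gaussian probe noise with SD 0.3 (the
background noise level is not fixed by any source; 0.3 gives the
~3-sigma planted blocks the region caller is calibrated against).
Mutant conditions multiply class means by retention factors (e.g.
H3K9me2 retained at 11.1% and H3K9me3 at 33.3% of wildtype on the
chr4-like arm under HP1a loss; repeat-associated HP1a retained under
POF loss; the proximal block unaffected), and the Pol II track carries a
Gaussian TSS peak whose centre shifts downstream in mutants (68/50 bp
defaults) with gene-body retention 0.3 on the chr4-like arm only.

Run-on counts are Poisson per bp at a body rate of 0.2 on active genes;
planted paused genes add Poisson(rate × 150) over a 50-bp window
starting 25 bp downstream of the TSS, calibrated so the expected PI of
a paused gene, 1 + window·multiplier/500 = 16, sits safely above the
threshold of 10 while non-paused genes sit near 1. Planted paused
fractions are 15% (euchromatin-like), 12.5% (pericentric), 2%
(chr4-like). The background rate defaults to 0 so that
polymerase-associated genes are exactly the active ones and planted
fractions are recovered on the stated denominators. Promoters are
i.i.d. at domain GC (0.35 chr4-like vs 0.45 euchromatin, which
depresses the chr4-like Tm profile); motif instances are planted at
domain rates (TRL 11% vs 24%, inverted TRL 13% vs 25%) at uniform
positions inside each motif's scan window, avoiding collisions with
previously planted instances. Observed motif fractions exceed planted
rates because the background also produces hits (a 5-mer like GAGAG has
an appreciable per-window background probability); contrasts remain
direction-correct. Mutant expression down-scales 80% of chr4-like genes
(factor U(0.3, 0.7)); the remaining 20% receive a mild up-scaling
(U(1.05, 1.6)), matching the observation that the non-decreased minority
is increased in continuous data, and all mutant values carry log-normal
measurement noise (SD 0.05 in log units) so that unaffected control
domains remain null-calibrated under the paired test.

Determinism: one master seed; each generator derives a labelled
sub-stream (seed + k), so stages are reproducible independently and
identical configurations reproduce identical output checksums.

What the generator does not emulate: read-level sequencing artefacts,
probe-specific affinity or GC bias, transposon sequence models,
diploidy, replicate structure, or spatially correlated noise. Passing
tests therefore certify the statistical machinery against known planted
structure — not performance on real arrays, whose noise is less benign.

# Problem sizes and numerical conventions

The test suite runs the generators mostly on a down-scaled genome
(~160 genes, 1.2 Mb total) and the full 2,080-gene conditions where the
claim concerns the stated sample sizes (paused-fraction recovery,
retention recovery, expression contrast); the acceptance script uses
the full conditions throughout, averaging pausing recovery over three
seeds and permutation tests over 1,000 permutations. Floating-point
conventions: probe values round-trip through text at 17 significant
digits; fraction sums are asserted to 1e-12; the scaling factor is
bit-exact under pure multiplicative change and agrees to 1e-12 under
additive offsets (offset addition perturbs the last bits of the lagged
differences). Ties: quantile normalization averages reference values
over tied ranks; TSS-peak ties take the smallest signed offset; K-means
label ties cannot occur (merging is deterministic, highest pair first,
lower index kept).

# Known limitations

The region caller assumes a unimodal null bulk; tracks that are mostly
enriched would mis-centre the null. The ChIP pausing index depends on
probe coverage near the TSS and skips sparse genes rather than
imputing. State merging with fewer than three marks is degenerate by
construction. The distance-to-repeat statistic is uninformative at high
repeat density (see above). Replicate consistency treats regions as
targets; gene-level target matching is not implemented. The CLI wrapper
is intentionally thin; orchestration beyond one-shot pipeline runs
(resumption, partial invalidation) is out of scope.
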