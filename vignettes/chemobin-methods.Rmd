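---
title: "Methods: bin-centric analysis of chemostat communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-centric analysis of chemostat communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemobin)
```

## Scope and model

chemobin analyses enrichment-culture communities through their *bins*:
sets of assembled contigs attributed to one microbial population, treated
as provisional genomes.  The package implements the computations that turn
raw sequencing summaries into bin-level ecology — compositional binning,
marker-based quality, coverage-based abundance, normalized transcriptional
activity and treatment responses, 16S rank clades, and the arithmetic of
the continuous culture the community lives in — together with a seeded
synthetic-community generator that supplies every input with known ground
truth.

## The synthetic community generator

The generator replaces raw sequencing data.  Its defaults are fixed once
and describe the study conditions the rest of the package is tested under:

* **Genomes.** Three genomes of 150 kb drawn from order-3 Markov chains.
  Tetranucleotide frequencies are the sufficient statistics of an order-3
  chain, so the compositional contrast between genomes is exactly the
  quantity the binning stage clusters on.  Each genome's transition rows
  start from its GC-target base composition (defaults 0.35 / 0.50 / 0.65, a
  spread typical of co-enriched *Clostridiales*, *Proteobacteria* and
  high-GC populations) and receive a per-context multiplicative tilt
  (log-normal, sd 0.2) that gives genomes of similar GC distinguishable
  higher-order signatures.
* **Abundances.** Defaults 4/7, 2/7, 1/7: one dominant population plus
  progressively rarer ones, the shape such enrichments typically take.
* **Contigs.** Log-normal lengths (meanlog `log(8000)`, sdlog 0.35,
  floor 1000 bp) tiled without overlap; fragments below the floor are
  discarded but recorded, so kept + discarded lengths always partition the
  genome — a conservation law the tests assert.
* **Genes and markers.** Non-overlapping gene intervals (1-based, inclusive
  ends, explicit strand — stated once here to prevent off-by-one drift) are
  laid along each contig; marker identities `m001`–`m139` are assigned to
  random gene slots so realized per-genome copy counts equal the plan
  exactly.  Marker *detection* is out of scope: the quality module consumes
  hit tables, whether from this generator or an external HMM search
  exported to the same schema.
* **Read mappings.** Reads are assigned to contigs with probability
  proportional to abundance × contig length; the mapper's summary table is
  emitted directly (read id, contig, aligned length, identity).  Identities
  default to Beta(197, 3) — mostly ≥ 0.98 with a realistic tail that the
  mapping filter removes.  No sequencing-error model, no FASTQ, no real
  alignment.
* **Transcript counts.** Negative-binomial, mean = baseline × condition
  multiplier.  The NB is the standard overdispersed count model; dispersion
  is parameterized as the `size` (shape) parameter, so large values recover
  the Poisson limit.  Defaults: baseline means log-normal with a floor of
  50 counts (planted effects stay identifiable above shot noise),
  dispersion 10, 20 % of genes planted with a 2× "stress" multiplier —
  emulating the oxidative/general stress regulons that respond to oxidant
  pulses.
* **16S identity ladders.** Equal-length gap-free sequence sets whose
  pairwise identities hit an ultrametric target matrix to within 0.5
  percentage points.  The implementation evolves a random ancestor down the
  target tree, substituting a calibrated number of sites per branch;
  substituted site sets are globally disjoint and every substitution
  changes the base, so realized mismatch counts are exact up to rounding
  (≤ 100/L points).  This replaces rejection sampling with a deterministic
  construction satisfying the same tolerance.  Non-ultrametric targets are
  rejected rather than approximated, and targets below 30 % identity are
  refused (random sequences already agree at ~25 % of sites).

What the generator does *not* emulate — sequencing error, strain
heterogeneity, chimeric contigs, rRNA depletion artefacts, compositional
bias of library preparation — bounds what green tests mean: they certify
the computations, not robustness to real-data pathologies.

## Tetranucleotide binning

Profiles use canonical 4-mers: each 4-mer is pooled with its reverse
complement under the lexicographic minimum, giving
(256 − 16)/2 + 16 = 136 classes and strand-invariant profiles (assembly
strand is arbitrary).  Windows slide by 1 bp; windows containing non-ACGT
characters are skipped.  Sequences shorter than 4 bp get an all-zero
profile and are excluded from clustering rather than erroring.

Clustering is PCA (centred, 5 components by default) followed by k-means
(`nstart = 25`) when the bin count is known, or a Gaussian mixture with BIC
model selection (`mclust`) when it is not.  Contigs below the 1000 bp
length floor are marked `unassigned`: 4-mer statistics of short contigs are
too noisy to place.  Contigs are processed in lexicographic id order and
bins relabelled by first occurrence, which makes the partition stable under
input permutation and under reverse-complementing any subset of contigs.
No attempt is made to reproduce any published bin boundaries; the binning
contract is recovery of the generator's ground truth (≥ 90 % majority-vote
agreement on the default community), which the acceptance suite measures.

Bin statistics follow the usual conventions: N50 by the largest-first
cumulative rule, GC over concatenated members.

## Bin quality

Two quotients over a fixed universe of 139 conserved single-copy genes:

* completeness = 100 × (distinct markers detected) / 139,
* contamination = 100 × (markers in > 1 copy) / (markers detected).

Both are reported to one decimal, rounded half-up to match the usual table
formatting.  Contamination with zero detected markers is undefined and
returned as `NA`, never 0.  Monotonicity (a new marker never lowers
completeness; an extra copy never lowers contamination) is asserted as a
property test.

## Abundance

Mappings are filtered at identity ≥ 0.98 and aligned length ≤ 500 bp — the
defaults of the mapping step this emulates.  Coverage per bin is **summed
aligned bases** over bin size, not read counts, so unequal read lengths
contribute proportionally; relative abundance is coverage normalized to 1
over the assigned bins.  Reads on unassigned contigs are excluded from the
denominator and reported.  The estimator is checked against planted weights
within three delta-method standard errors at 100,000 reads.

## Transcriptional activity

For gene *g* in bin *B* and one sample,

$$a_g = \frac{r_g / L_g}{R_B / L_B}$$

with \(r_g\) mapped reads, \(L_g\) coding length and \(R_B, L_B\) the bin's
coding totals.  The **length-weighted** mean of \(a_g\) over a bin is then
identically 1 in every sample — the normalization contract asserted to
1e-9.  The unweighted mean equals 1 only for equal gene lengths; the two
coincide in the equal-length case but the weighted form is what the
quotient forces, so it is the documented and tested invariant.  Non-coding
features are excluded from both the numerator set and the bin totals.  A
bin/sample with zero mapped coding reads yields `NA` activities (flagged
missing), and activities are invariant to scaling all counts in a
bin/sample — sequencing depth cancels.

Display capping replaces values above 3.0 by 3.0 with a "≥" flag, leaving
the underlying table untouched; it is idempotent.

Treatment responses are `log2((after + ε)/(before + ε))`: +1 means
transcription doubled after the treatment, −2 a fourfold decrease.  ε = 0
whenever both sides are positive (ratios of positive activities are never
distorted); ε defaults to 0.5 — the standard half-count offset — when a
zero is present, and both-zero pairs are `NA`.  With ε = 0 the response is
antisymmetric under swapping the conditions.  Responses are computed per
culture and averaged across replicate cultures.  Because activities are
renormalized within each bin, a planted fold change on a gene subset also
shifts its bin's baseline; effect recovery is therefore measured as the
stress-minus-background contrast of median responses, which the tests
require within ±0.2 of the planted log2 effect.  No differential-expression
statistics (tests, FDR) are computed — the analysis is descriptive.

For cross-bin comparison of a gene category, within-bin activities are
weighted by the bin's relative abundance and expressed as percentage shares
summing to 100 across bins.  The exact published form of this
standardization is not written out anywhere we could follow; the
product-then-percentage reading implemented here is one consistent
interpretation and is flagged as such.

## Rank-threshold clades

Pairwise identity is matches over compared columns, excluding columns where
either sequence has a gap from both numerator and denominator; a pair with
no comparable columns is `NA`.  A single hierarchical clustering (average
linkage by default, on distance 100 − identity) is cut at the five rank
thresholds — genus 94.5, family 86.5, order 82.0, class 78.5, phylum
75.0 % identity — so nesting of the partitions is guaranteed by
construction and clade counts are monotone.  The linkage of the original
clustering tool is not published; average linkage is the package's choice,
configurable to single or complete.  Sequences are sorted by id before
clustering, making merge tie-breaks and labels permutation-stable.  For
≤ 8 sequences the partitions are verified against a brute-force
agglomeration oracle.  Published clade counts for any particular reference
alignment are not an acceptance surface — they depend on that alignment and
tool.

## Chemostat arithmetic

With working volume V and medium flow F, the dilution rate is D = F/V; at
steady state D equals the community growth rate, so doubling time is
ln 2 / D (reported in hours).  A pulse of feed (ml min⁻¹ × min × mM)
delivers a dose in mmol; spread over V it sets the peak concentration.  By
default the few millilitres of feed added during a pulse are neglected
(a 2.4 % effect for the reference configuration, whose printed dose/peak
pair matches the uncorrected quotient); an exact volume-corrected divisor
is available via `feed_volume_ml`.  Note that 0.17 l day⁻¹ over 0.4 l gives
D = 0.425 day⁻¹, slightly above the 0.36–0.4 day⁻¹ band reported for the
reference cultures — consistent with a working volume somewhat above the
nominal 0.4 l.  Both numbers are surfaced; the package does not guess a
reconciliation.  `washout_curve()` is the inert-solute reference
(c(t) = c₀·e^(−Dt)); biological consumption is deliberately not modelled,
so observed decay faster than washout indicates consumption.

## Worked example

```{r example, eval = FALSE}
spec <- community_spec(seed = 42)          # 3 genomes, 150 kb, GC .35/.50/.65
out <- run_pipeline(pipeline_config(spec, n_reads = 20000), "demo_out")
out$quality        # completeness 100, contamination 0 for full marker plans
out$abundance      # recovers 4/7, 2/7, 1/7 within sampling error
head(out$response) # log2 after/before per gene
```

## Problem sizes and numerical choices

The test and acceptance suites run on 3 × 60–150 kb genomes, 100,000 reads
for abundance recovery, 1,000 genes × 2 replicate cultures for effect
recovery, and 1,300-column identity ladders — sizes at which every planted
signal is comfortably identifiable and a full run takes seconds.  All
stochastic steps draw from seeded generators; identical configuration and
seed give byte-identical outputs, which the pipeline manifest (md5 per
artifact) makes checkable.  Percentages are rounded half-up to one decimal
only in reports; fractions are stored at full precision with `.` as the
missing-value sentinel in all TSV output.

## Limitations

* Binning uses composition only — no coverage-aided or multi-sample
  binning, no assembly, no taxonomy of bins.
* The generator's clean genomes make binning easier than real metagenomes;
  the ≥ 90 % recovery bar certifies the implementation, not field
  performance.
* Marker detection, 16S reconstruction, alignment and tree inference are
  consumed, not performed.
* The chemostat module is arithmetic, not a kinetic community model.
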