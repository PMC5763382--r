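# chemobin

Bin-centric analysis of sulfate-reducing/fermentative enrichment cultures —
and of any chemostat community studied through metagenome bins and
metatranscriptomes.

Communities enriched in continuous culture are usually analysed through
their **bins**: sets of assembled contigs attributed to one population and
treated as a provisional genome.  chemobin implements that analysis as a
tested, reusable pipeline:

* **Compositional binning.** Contigs are profiled by canonical
  tetranucleotide frequencies (each 4-mer pooled with its reverse
  complement; 136 classes), projected on principal components and
  clustered; per-bin size, contig count, N50 and GC are reported.
* **Bin quality.** Against a universe of 139 conserved single-copy genes
  (CSCGs): completeness = 100 · (markers detected)/139 and
  contamination = 100 · (markers in > 1 copy)/(markers detected).
* **Relative abundance.** Read mappings filtered at identity ≥ 0.98 and
  aligned length ≤ 500 bp; coverage = aligned bases / bin size; abundances
  are coverages normalized to 1.
* **Transcriptional activity.** Per gene *g* in bin *B*:
  `a_g = (r_g/L_g) / (R_B/L_B)` — read density over the bin's coding read
  density — so the length-weighted mean activity of every bin is exactly
  1.0 in every sample and bins are comparable across treatments.  Display
  capping at ≥ 3.0, and log2 after/before treatment responses (+1 =
  transcription doubled, −2 = fourfold decrease), plus abundance-weighted
  cross-bin activity shares.
* **16S rank clades.** One hierarchical clustering of a pairwise-identity
  matrix cut at genus 94.5 / family 86.5 / order 82.0 / class 78.5 /
  phylum 75.0 % identity, giving nested partitions and clade counts.
* **Chemostat arithmetic.** Dilution rate D = flow/volume, doubling time
  ln 2/D, pulse dose (ml·min⁻¹ × min × mM → mmol), peak concentration
  dose/volume, and inert-solute washout c₀·e^(−Dt).
* **Synthetic communities.** A seeded generator (order-3 Markov genomes
  with controlled GC, log-normal contigs, planted gene/marker layouts,
  abundance-proportional read maps, negative-binomial before/after counts
  with planted stress effects, and 16S-like identity ladders) supplies
  every input with known ground truth, so the whole pipeline is testable
  without external sequencing data.

## Worked example

```r
library(chemobin)

spec <- community_spec(seed = 42)   # 3 genomes, 150 kb, GC 0.35/0.50/0.65
gen  <- generate_genomes(spec)
frag <- fragment_contigs(gen$genomes, spec$contig_length_law, seed = 43)

asn <- cluster_contigs(frag$contigs, min_length = 5000, n_bins = 3, seed = 42)
bin_stats(frag$contigs, asn)
#>     bin  size_mb n_contigs n50_kb gc_percent
#> 1 bin_1 0.139643        15  9.415   34.01746
#> 2 bin_2 0.144303        17  7.972   49.28449
#> 3 bin_3 0.150000        17  9.164   64.30267
```

The three bins recover the three genomes: sizes ≈ 0.14–0.15 Mb of the
150 kb genomes (contigs under the 5 kb floor stay `unassigned`), and GC
34/49/64 % matches the planted 35/50/65 % targets.

```r
plan <- marker_plan(3, missing = list(genome_01 = marker_ids()[1:21]))
pg   <- plant_genes_and_markers(frag$contigs, frag$truth, plan, seed = 44)
quality_report(pg$marker_hits)
#>         bin n_detected n_multicopy completeness contamination
#> 1 genome_01        118           0         84.9             0
#> 2 genome_02        139           0        100.0             0
#> 3 genome_03        139           0        100.0             0
```

118 of 139 markers present gives 84.9 % completeness; no duplicated marker,
0 % contamination.

```r
rmap  <- simulate_read_map(frag$contigs, frag$truth, spec$abundances,
                           n_reads = 20000, seed = 45)
sizes <- tapply(frag$truth$length, frag$truth$genome_id, sum)
cov   <- bin_coverage(filter_mappings(rmap),
                      data.frame(contig_id = frag$truth$contig_id,
                                 bin = frag$truth$genome_id),
                      setNames(as.numeric(sizes), names(sizes)))
relative_abundance(cov)
#>     sample       bin abundance
#> 1 sample_1 genome_01 0.5808242
#> 2 sample_1 genome_02 0.2793465
#> 3 sample_1 genome_03 0.1398293
```

Estimated abundances 0.58/0.28/0.14 recover the planted 4/7, 2/7, 1/7
(0.571/0.286/0.143) within sampling error.

```r
pulse_dose(1.4, 20, 7)              # 0.196 mmol per nitrate pulse (~0.2)
post_pulse_concentration(0.2, 0.4)  # 0.5 mM peak in a 0.4 l culture
doubling_time(0.4)                  # 41.6 h at D = 0.4 per day
```

`run_pipeline(pipeline_config(spec), "outdir")` executes all stages end to
end and writes every table plus a manifest with seed, parameters and md5
checksums; identical configurations give byte-identical outputs.

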