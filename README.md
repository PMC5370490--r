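# numtquant

Quantification of nuclear mitochondrial DNA insertions (NUMTs) from matched
tumor / blood-derived-normal paired-end alignments.

## The problem

Fragments of mitochondrial DNA integrate into the nuclear genome
continuously — in the germline and, at an elevated rate, in tumors
("numtogenesis"). In paired-end whole-genome data a NUMT insertion leaves a
simple footprint: a discordant read pair with one mate mapped to the
mitochondrial contig and the other to a nuclear chromosome. Because junction
breakpoints are rarely resolvable, the nuclear mate's coordinate serves as a
proxy for the insertion site.

`numtquant` is for genomicists who want to measure somatic NUMT load in
matched tumor/normal cohorts: it extracts the chimeric pairs, normalizes
them into comparable abundances, computes tumor-versus-normal fold changes
over nested genomic partitions, runs the cohort statistics, and maps which
parts of the mitochondrial genome the fragments come from.

## The metric

For sample *j* (tumor *t* or healthy *h*) and genomic interval *i*, with
*N<sub>ij</sub>* NUMT pairs and *M<sub>ij</sub>* mapped reads:

- proportion: *P<sub>ij</sub>* = *N<sub>ij</sub>* / *M<sub>ij</sub>*
- paired difference: *ΔP<sub>i</sub>* = *P<sub>it</sub>* − *P<sub>ih</sub>*
- fold ratio: *R<sub>i</sub>* = *P<sub>it</sub>* / *P<sub>ih</sub>*
- direction: *S<sub>i</sub>* = *ΔP<sub>i</sub>* / |*ΔP<sub>i</sub>*| (0 at no
  change)
- rescaled fold change: *R′<sub>i</sub>* = *R<sub>i</sub><sup>S<sub>i</sub></sup>* · *S<sub>i</sub>*

The rescaling repairs the asymmetry of ratios: a doubling (R = 2) maps to
+2, a halving (R = 0.5) to −2, and no change to 0, so |R′| ≥ 1 or R′ = 0.
Nuclear intervals come in five nested partitions — genome (`gen`),
chromosome (`chr`), arm (`arm`), cytoband (`cyt`), 2.5-Mb window (`win`) —
and mitochondrial intervals in three (`mtg`, `mst`, `mgn`). Genome-level
normalization excludes sex-chromosome reads; for sparse partitions, samples
sharing a plate barcode are pooled and the healthy baseline is the plate
mean proportion.

## Worked example

The package ships a cohort simulator with full ground truth, so a complete
analysis runs in memory:

```r
library(numtquant)

sim   <- simulate_cohort(sim_config(seed = 7, n_participants = 6,
                                    background_pairs = 20000))
quant <- quantify_cohort(sim, levels = c("gen", "chr", "mgn"))
coh   <- numt_cohort(quant)
summary(coh)
#> Cohort of 6 matched participants ( 6 with defined fold change )
#>   mean per-sample fold change: 4.612 (median 3.985; ratio of cohort means 4.237)
#>   paired t on log2 proportions:
#>     one-tailed p = 9.92e-05; two-tailed p = 0.000198
#>   tumor-on-blood regression: slope -0.230, R^2 0.194, p 0.383

truth_compare(quant$pairs, sim)
#> <numt_recovery> sensitivity 1.0000 (598/598), 0 false detection(s)

hist <- mito_breakpoint_histogram(quant$pairs, sim$partitions$mito$mgn)
head(rank_hotspots(hist), 2)
#>   interval_id tumor_count healthy_count count
#> 1         ND1         264            54   318
#> 2         CO1         139            44   183
```

The simulator implanted chimeric pairs at a tumor/healthy rate ratio of
4.42; the recovered mean per-sample fold change is 4.6 with the paired test
strongly rejecting equality, every implanted pair was re-detected, and the
mtDNA breakpoints concentrate in the implanted ND1/CO1 hotspot mixture.

For real data, point `quantify_cohort()` at a sample table
(`sample_id`, `participant`, `genome_type`, `path`) of coordinate-sorted
BAM/SAM files with a `genome_build()` and partitions built from your
cytoband table and mitochondrial gene BED. A command-line wrapper is
installed at `inst/scripts/numt-cli.R` with subcommands
`simulate | extract | quantify | cohort | hotspots`.

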