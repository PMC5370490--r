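---
title: "Quantifying somatic NUMT load: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic NUMT load: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(numtquant)
```

## What is being measured

A nuclear mitochondrial DNA segment (NUMT) arises when a fragment of mtDNA
integrates into a nuclear chromosome. In paired-end sequencing of a genome
carrying such an insertion, fragments spanning the junction produce
discordant read pairs: one mate maps to the mitochondrial contig, the other
to the nuclear neighborhood of the insertion. `numtquant` counts those
chimeric pairs as insertion observations. Two deliberate approximations
follow the nature of this evidence:

* **Pair-level counting.** One chimeric pair is one observation; counting
  both mates would only multiply every count by two and cancel in every
  ratio. Mapped reads (the normalizer M) are counted per read, as
  sequencing depth usually is.
* **Proxy coordinates.** Junction breakpoints are not assembled. The
  nuclear mate's leftmost aligned coordinate stands in for the insertion
  site and the mitochondrial mate's for the mtDNA breakpoint. Since mate
  pairs sit within a few hundred bases of each other, the proxy error is
  negligible at the partition scales used (arms, cytobands, 2.5-Mb
  windows, mitochondrial genes).

Matched design is essential: every human genome carries hundreds of
germline NUMTs, many absent from the reference, which generate chimeric
pairs in tumor and blood alike. The tumor-versus-matched-normal contrast
absorbs that germline signal, leaving the somatic excess.

## The abundance model

For interval $i$ and genome type $j \in \{t, h\}$, with $N_{ij}$ chimeric
pairs and $M_{ij}$ mapped reads,

$$P_{ij} = \frac{N_{ij}}{M_{ij}}, \qquad
  \Delta P_i = P_{it} - P_{ih}, \qquad
  R_i = P_{it} \cdot P_{ih}^{-1},$$

$$S_i = \frac{\Delta P_i}{|\Delta P_i|}, \qquad
  R_i' = R_i^{S_i} \cdot S_i .$$

$R$ is asymmetric around 1 (a doubling is 2, a halving 0.5), so $R'$
rescales deficits onto the same footing as excesses: $R' = R$ when the
tumor has more, $R' = -1/R$ when the healthy genome has more, and $R' = 0$
at exact equality. Consequently $|R'| \ge 1$ or $R' = 0$, the sign carries
the direction, and swapping the tumor and healthy inputs maps $R' \to -R'$
exactly. At $\Delta P_i = 0$ the sign formula is $0/0$; the implementation
adopts $S_i = 0$, hence $R_i' = 0$, which is the only convention consistent
with collapsing "no change" to zero.

Partitions are nested: nuclear genome, chromosomes, arms, cytobands,
2.5-Mb windows; mitochondrial genome, replication strand, gene. Genome-level
$M$ excludes sex-chromosome reads so that male and female genomes are
normalized over the same sequence; genome-level $N$ keeps sex-chromosome
insertions (they are real observations). These two choices give the tested
additivity identities: genome $N$ equals the sum of chromosome $N$, genome
$M$ the sum over autosomes only.

**Zero healthy denominators.** In a whole genome $P_{ih} = 0$ is rare, but
in a 2.5-Mb window most healthy genomes have no NUMT pair at all. Matched
per-interval ratios are therefore only supported at gen/chr/arm scale
(records with $P_{ih} = 0 < P_{it}$ are omitted and logged). For cytobands
and windows the pooled mode is the supported path: tumor counts on a plate
are summed *before* normalization ($\sum N / \sum M$), while the healthy
baseline $\bar P_{ih}$ is the arithmetic mean of the member proportions,
zeros included. The asymmetry (pool-then-normalize on the tumor side, mean
of proportions on the healthy side) mirrors the baseline's definition as an
average reference level rather than a mega-sample.

## Cohort statistics

* **Paired t-test on log proportions** — per-participant log fold changes,
  one-sample t. The statistic is identical for any log base (a base change
  scales all differences by one positive constant; the package tests this
  invariance). Both one-tailed (tumor-excess) and two-tailed variants are
  exposed and labelled; no default silently chooses a tail. Zero-variance
  differences return a flagged degenerate result instead of an infinite
  statistic.
* **Welch t** for two-group contrasts (tumor site, sex); **Mann–Whitney U**
  for vital status, exact when the smaller group has ≤ 8 observations and
  no ties, tie-corrected normal approximation otherwise (verified against
  full enumeration in tests).
* **Tumor-on-blood regression** — OLS of $\log_2 P_{\mathrm{gen},t}$ on
  $\log_2 P_{\mathrm{gen},h}$, asking whether blood NUMT load predicts
  tumor NUMT load.
* **Arm-level aneuploidy check** — OLS of $R'_{\mathrm{arm}}$ on arm mapped
  reads, untransformed: a systematic slope would mean the NUMT signal rides
  on copy-number dosage.
* **GC association** — Pearson and Spearman correlation of
  $R'_{\mathrm{win}}$ with window GC fraction (GC tracks gene density and
  open chromatin, the hypothesized landing preference).
* **Giemsa summaries** — cytoband $R'$ distributions within the five stain
  groups gneg, gpos25–gpos100; acen/gvar/stalk bands are excluded as they
  are not Giemsa intensity classes. The exceedance count defaults to the
  4.2-fold threshold used for calling strongly amplified bands.

No multiple-testing correction is applied by default; `adjust_window_p()`
offers Benjamini–Hochberg for window-level scans as an opt-in extension.

## Read-level processing choices

* **Formats.** SAM/BAM ingestion goes through Rsamtools (SAM text is
  converted on the fly); coordinates stay 1-based as stored in SAM, while
  partitions are 0-based half-open as in BED, with the containment rule
  $\mathrm{start} \le p - 1 < \mathrm{end}$ tested explicitly.
* **QC filters.** Duplicate-flagged reads are dropped by default (a
  coordinate-signature marker exists for unflagged inputs); secondary and
  supplementary records are dropped (keeping them double-counts pairs);
  the MAPQ floor defaults to 0 — no threshold — because repeat-mediated
  false chimeras versus sensitivity is a trade the user should make
  knowingly.
* **Orphan mates.** A chimeric pair is reconstructed from either mate's
  mate-fields and deduplicated by query name, so filtering that removes one
  mate does not lose the pair.
* **Unplaced contigs.** Partitions contain only canonical chromosomes plus
  the mitochondrial contig; reads and pairs elsewhere enter neither N nor M.
* **Mitochondrial annotation.** The bundled table is an rCRS-style
  construction: 13 protein genes, 2 rRNAs, and the D-loop (two arcs sharing
  one id, since the control region wraps the origin of the circular
  genome). Real ATP8/ATP6 and ND4L/ND4 overlaps are trimmed at the
  downstream gene's start so the gene partition is disjoint. Strand `+`
  maps to the heavy strand by convention; the mapping is configurable
  because strand labelling differs between annotation sources.

## The simulator: what it emulates and what it does not

`simulate_cohort()` generates the statistical structure the analysis
assumes, on a toy genome (three autosomes + X totalling 29 Mb, mito
16,569 bp):

* background concordant pairs uniform per base over nuclear contigs, mate
  gap $\mathcal N(150, 30^2)$ truncated at 0 — the short gap is what makes
  the mate coordinate a usable insertion proxy;
* chimeric pairs per genome $\sim$ Poisson(rate × mapped reads), rate
  $\lambda_h$ in healthy and $\rho\,\lambda_h$ in tumor genomes, with
  optional per-sex $\rho$;
* mtDNA breakpoints from a gene-hotspot mixture (default 50% ND1, 30% CO1,
  20% uniform) with optional tumor-only hotspot genes;
* nuclear landing windows weighted by $w \propto \text{width} \cdot
  e^{\beta \cdot \mathrm{GC}}$ ($\beta = 0$: uniform per base), with the
  FASTA generated to match the per-window GC targets;
* a duplicate-flagged clone fraction (default 5%) and plate/covariate
  metadata (sex, disease site, vital status, stage, age, race at
  frequencies of a 57-participant colorectal cohort).

One root seed drives everything; per-sample streams are derived by hashing
the sample id, so adding participants never reshuffles existing samples,
and file output is byte-identical across reruns.

**Scaling.** The defaults are the package's study conditions: 20
participants, $10^5$ background pairs per genome, $\rho = 4.42$. Real
whole genomes carry $\sim 10^9$ reads with healthy NUMT proportions around
$2.6 \times 10^{-6}$; at desk scale that rate would leave a healthy genome
with under one expected chimeric pair and every matched ratio undefined.
The default healthy rate is therefore $\lambda_h = 5 \times 10^{-4}$ per
mapped read, chosen once by power analysis so a healthy genome carries
$\approx 100$ expected pairs — comparable information content per genome to
the real setting — while the quantities under test ($P$ ratios, $R'$,
test calibration) are scale-free in the rate. With $\approx 100$ pairs per
genome the per-sample ratio estimator's relative error is $\sqrt{2/100}
\approx 14\%$, so a 20-participant cohort pins the cohort mean to a few
percent.

What the simulator does **not** model: sequencing error and base
qualities, alignment ambiguity and mapping errors near repeats, reference
germline NUMTs, copy-number variation of the normalizer, and contamination.
Passing recovery tests therefore demonstrates the pipeline's bookkeeping
and statistical machinery, not robustness to alignment artifacts in real
tumor genomes — on real data, the MAPQ filter and duplicate policy are the
levers for that.

## Validation design

The test suite pairs every operation with an independent oracle: chimeric
extraction against a hand-parsed, query-name-grouped scan of the SAM text;
interval counting against a per-interval loop; OLS against the normal
equations; the exact Mann–Whitney p against full enumeration of group
assignments. Cohort-scale checks re-derive the implanted truth: the mean
per-sample fold change recovers $\rho$ over a grid
$\{1, 2, 4.42, 8\}$ within three Monte-Carlo standard errors (20
participants, $10^5$ background pairs); the paired log t-test holds its
nominal 5% type-I error within ±1% over 2,000 null cohorts of 20
(simulated at the count level); the implanted ND1/CO1 mixture ranks those
genes top-2 in at least 48 of 50 replicates; $\beta > 0$ landing bias
yields a significant positive $R'_{\mathrm{win}}$–GC correlation over 500
windows while $\beta = 0$ stays inside the 95% null band. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Numerical and degenerate-input conventions

* Proportions with $M = 0$ are undefined and dropped; $M = 0$ with $N > 0$
  is an input inconsistency and an error.
* `rescale_ratio()` requires $R > 0$ and is exactly invertible on
  $|R'| \ge 1$.
* Hotspot ranking breaks count ties by genomic order, making every report
  deterministic; breakpoints in unannotated inter-gene gaps go to a
  catch-all bin so totals are conserved.
* Windows default to `step = size` (tiling); overlapping windows are
  allowed but break the sum-to-chromosome identities, so they are opt-in.
* Metadata without a plate column falls back to one global pool, with a
  warning.

## Known limitations

* Breakpoints are proxies; nothing here resolves junctions to base
  precision or assembles inserted fragments.
* Matched mode at sub-arm scales is intentionally unsupported (undefined
  ratios are omitted, not imputed); use pooled mode.
* The Mann–Whitney exact path is limited to small groups without ties,
  as designed.
* Survival is compared only as a two-group vital-status contrast; no
  time-to-event modelling.
* The simulator's toy genome has no repeats, so MAPQ-based filtering is
  exercised mechanically, not adversarially.
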