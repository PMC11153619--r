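---
title: "Detecting sex-determining regions from two-pool sequencing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-determining regions from two-pool sequencing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsex)
library(data.table)
```

## The problem

In many amphibians the sex chromosomes are homomorphic: X and Y (or Z and W)
recombine over almost their whole length and differ only in a small
non-recombining block. Individual-level genotyping then struggles to find the
sex-determining region (SDR), because almost no marker is fully sex-linked and
the few that are may be missed by sparse per-individual coverage. Pooled
whole-genome sequencing of many phenotypically sexed individuals ("pool-sex")
converts sex linkage into two robust pool-level signals:

* **Allele balance.** At a site where every male carries one X and one Y
  allele and every female two X alleles, the male pool's alternate-read
  fraction sits near 0.5 and the female pool's near 0 (or 1). A ZW system
  shows the mirrored pattern.
* **Coverage.** Sequence present only on the Y haplotype is covered at half
  the diploid rate in the male pool and at (near) zero in the female pool,
  after each pool's coverage is expressed relative to its diploid peak.

`poolsex` implements both scans, the positional clustering that turns
per-site signals into a ranked genome-wide candidate list, a cross-species
intersection of male-specific amplicon SNPs, and a simulator that plants a
known SDR so that the whole pipeline can be scored against truth.

## The allele-balance screen

Each pool at each biallelic site contributes a strand-resolved quadruple
(ref-fwd, ref-rev, alt-fwd, alt-rev). The total depth is the sum of the
quadruple — deliberately not the caller's `DP` field, so that the depth used
by the filter is exactly the depth underlying the allele fraction. With
alternate fraction $f$ and total depth $D$, the class is

* `LOW_DEPTH` if $D < 15$;
* `HOM_REF` if $f \le 0.07$, `HOM_ALT` if $f \ge 0.93$;
* `HET` if $0.45 \le f \le 0.55$;
* `AMBIGUOUS` otherwise.

All bounds are inclusive (comparisons carry a $10^{-9}$ slack so that exact
rational fractions such as $7/100$ land on the intended side of their binary
floating-point thresholds). The XY screen retains sites with a `HET` male
pool and a homozygous female pool — `HOM_ALT` counts, since the reference
assembly may carry the Y allele — and both pools must pass `min_depth`; the
ZW screen interchanges the sexes. `AMBIGUOUS` or `LOW_DEPTH` in either pool
drops the site. INDELs and MNPs are screened identically to SNPs and their
type is carried through for optional filtering.

### Why clusters, not sites, are the unit of detection

At pool depth $D \sim \mathrm{Poisson}(40)$ a truly sex-linked site has
alternate reads $\sim \mathrm{Binomial}(D, 0.5)$ in the heterogametic pool,
and the probability of landing inside the 45–55% window is only about 0.52
(`sum(dbinom(18:22, 40, 0.5))` is 0.57 at $D = 40$ exactly). Roughly half of
the truly divergent sites are therefore invisible to the screen at these
depths — by design, because the window must be tight enough to reject the
vastly more numerous background SNPs. Detection rests on the spatial
concentration of the surviving sites: background false positives (retention
probability below $10^{-2}$ per background SNP, empirically far lower) are
scattered, while the SDR's survivors pile into one interval. The package's
retention tests assert agreement with this closed-form expectation rather
than a fixed recovery percentage, and the recovery criterion is that the
rank-1 cluster overlaps the true SDR and gathers at least 90% of the
screen-passing planted sites.

## Distance clustering and ranking

Candidate positions are clustered per contig by single linkage on the gap
between consecutive 1-based point positions: $p_{i+1}$ joins $p_i$'s cluster
iff $p_{i+1} - p_i \le$ `max_gap` (default 9000 bp). The merge rule is
applied to point positions, not interval gaps, which fixes the off-by-one
ambiguity of interval-merging tools; the boundary case (gap exactly
`max_gap`) merges, and is tested explicitly. `max_gap = 0` leaves every
distinct position its own cluster; `max_gap = Inf` gives one cluster per
contig. Duplicate positions (a SNP and an INDEL at the same coordinate) are
collapsed for clustering but both rows stay in the candidate table.

Clusters are ranked by member count, with ties broken by span (descending)
then genomic position, so the ordering is total and deterministic.
Singletons are kept by default (`min_cluster_size = 1`): even small clusters
are informative for the between-mode contrast, and suppression is a flag,
not a baked-in choice. The XY and ZW scans always run on the same variant
set and are reported side by side; the ratio of top counts is the
heterogamety diagnostic.

## The coverage scan

The two pools' bedgraph tracks are combined onto the common refinement of
their breakpoints (absent coverage = 0, each input's total mass preserved).
Each track is normalized by its **modal coverage peak**: the integer
coverage value occupying the largest total base span, zero excluded, ties
broken toward the smaller value (a deterministic rule for an otherwise
ambiguous histogram mode). The mode is computed per track over the whole
genome, not per contig — the diploid peak is a genome-wide property and
sex-linked sequence is a negligible fraction of span. Normalization is
independent per track, so unequal pool sequencing depths cancel. An all-zero
track has no diploid peak and is a fatal error.

A base is selected iff its male normalized coverage lies in the inclusive
window $[0.25, 0.75]$ and its female normalized coverage is strictly below
$0.05$ (the strict female bound follows the printed operator; with binned
integer coverage the boundary is rarely populated either way). Selection is
pointwise, so re-chunking the bedgraph intervals cannot change the result.
Selected bases are merged into maximal runs, runs are clustered with the
same 9000-bp point-gap rule as the SNP scan (the coverage-specific gap is a
separate parameter, defaulting to the shared value), and each cluster is
scored by its count of selected bases — gaps are never counted — and ranked
with the SNP-scan tie rules.

The scan deliberately stays a thresholding method: no GC correction,
mappability masking, or segmentation model. Read-quality filtering (e.g.
restricting to uniquely mapped reads) belongs upstream; the bedgraph is
taken as given.

## Cross-species amplicon intersection

Deep amplicon sequencing of sexed individuals from several species gives
per-sample allele fractions at thousands of sites. Each sample is classified
with the same window rule as the pools; the per-individual default raises
`min_depth` to 30 reads, appropriate for target-enrichment depths, while the
fraction windows are unchanged — one classifier, one set of semantics. The
per-individual thresholds are all exposed as arguments.

A site is male-specific for a species when every informative male is `HET`
and every informative female homozygous (strict quorum; a tolerance for a
stated number of discordant samples per sex is available). `LOW_DEPTH`
samples leave the quorum rather than failing the site, because enrichment
coverage is uneven across amplicons; a site with no informative sample in
either sex is excluded and counted. Per-species sets are intersected by
shared reference coordinates (no liftover), stratified by the number of
supporting species $k$, and filtered at a minimum sharing level. The
diagnostic expectation — and the acceptance check on synthetic panels — is
that $k = n$ sites concentrate in the anciently shared block while
species-private SNPs never rise above $k = 1$.

## The simulator

`simulate_poolsex()` emulates the statistical structure the scans consume,
at the study conditions: two pools of 22 diploid individuals, Poisson read
depth with mean 40 per pool, per-base miscall rate 0.002, background SNPs at
$2 \times 10^{-3}$ per bp with population frequencies uniform on
$[0.05, 0.5]$, one fully sex-linked 66-kb block carrying 100 fixed divergent
sites, and a 55-kb Y-specific insertion on its own contig with 1% spurious
female coverage. Per background site, each pool draws its allele count as
$\mathrm{Binomial}(2n, p)$, then reads as $\mathrm{Binomial}(D,\,
q(1-\varepsilon) + (1-q)\varepsilon)$ with a fair strand split; divergent
sites fix $q = 0.5$ in the heterogametic pool and $0$ in the other; the ZW
system mirrors everything. Sites with no alternate read in either pool are
not written to the VCF — a caller would not emit them — but the truth files
record every planted site, so recovery is always measured against truth.

Coverage is emitted at a 100-bp bin resolution (per-bin Poisson read mass,
bin-averaged, rounded to integer depth), which keeps tracks small; the scan
operates identically on binned tracks because selection is pointwise. The
default test genome is one 10-Mb contig plus the insertion contig — a
desk-scale stand-in for a multi-gigabase amphibian genome that preserves
every rate the scans see (module tests use a 1-Mb variant with smaller
planted features for speed; the recovery studies in the tests and the
acceptance script use the 10-Mb default over 20 seeds). The RNG is R's
Mersenne-Twister, seeded explicitly; a seed is mandatory and the same seed
reproduces byte-identical output files.

What the simulator does **not** model, and what passing tests therefore do
not show about real data: linkage disequilibrium between background sites
(irrelevant to per-site screening plus positional clustering, but real
clusters of correlated FPs are possible near structural variation); mapping
artifacts, repeats and collapsed duplications (a major real-world source of
spurious half-coverage); population structure within pools (the real pools
mixed two closely related taxa); and recombination dynamics at the
pseudo-autosomal boundary. The amplicon panel generator
(`make_amplicon_panel()`) likewise plants clean fixed differences; real
panels add paralogy and allele-specific amplification bias.

## Numerical and interface choices

* **Coordinates.** VCF positions are 1-based; BED and bedgraph are 0-based
  half-open. All cluster arithmetic runs on 1-based point positions and is
  converted only when writing BED (`start - 1`), a round-trip that is tested
  for all positions.
* **Depth dialects.** `read_pool_vcf()` prefers a per-sample `DP4`
  quadruple and falls back to a per-sample `AD` pair with strands pooled as
  forward — the two encodings the upstream callers plausibly produce.
  Multiallelic records are skipped (the screen is a two-allele frequency
  test), and both skip reasons are counted and reported.
* **Degenerate inputs.** Zero total depth classifies as `LOW_DEPTH`;
  empty variant tables, empty cluster lists (ratio reported `NA`) and empty
  bedgraph files flow through; overlapping or negative-valued bedgraph
  intervals are fatal, as they indicate a malformed track rather than a
  modelling question.
* **Determinism.** Every ranking has a total tie order; every writer emits
  sorted rows and a comment header with the package version and parameters;
  the simulator is a pure function of its config (seed included).

## Limitations

The pipeline inherits the method's descriptive character: cluster sizes are
ranked, not tested against a genome-wide null, so the output is a candidate
ordering rather than calibrated significance. Thresholds are the published
operating point for ~40x pools of 22 + 22 individuals; materially different
depths or pool sizes shift the retention probability (the closed-form
expectation above generalizes directly) and may warrant re-tuning the
heterozygosity window. Cross-species intersection assumes a shared reference
coordinate system and will miss male-specific SNPs that fail to genotype in
any one species' samples.
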