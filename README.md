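# poolsex

Discovery of sex-determining regions from two-pool ("pool-sex") whole-genome
sequencing of phenotypically sexed individuals — for population and
evolutionary genomicists working on species with homomorphic sex chromosomes,
where the non-recombining region is too small for individual-level markers to
find reliably.

## The method

Two pools (all males, all females) are sequenced and their variants called
against one reference. `poolsex` then runs two complementary genome scans and
a cross-species fine-mapping step:

1. **Allele-balance screen.** At each biallelic site, each pool's
   strand-resolved depths (DP4: ref-fwd, ref-rev, alt-fwd, alt-rev) give an
   alternate fraction *f* over total depth *D* = sum of the quadruple. A pool
   is homozygous when *f* ≤ 0.07 or *f* ≥ 0.93, heterozygous when
   0.45 ≤ *f* ≤ 0.55, and both pools need *D* ≥ 15. The XY screen keeps
   sites heterozygous in males and homozygous in females; the ZW screen
   interchanges the sexes.
2. **Distance clustering.** Candidate positions within 9000 bp of their
   neighbor merge into clusters, ranked by member count; the ratio of the
   top XY to the top ZW count diagnoses the heterogametic system.
3. **Coverage scan.** Each pool's per-base coverage track is normalized by
   its modal (diploid) peak; bases with male normalized coverage in
   [0.25, 0.75] and female normalized coverage < 0.05 are Y-hemizygous
   candidates, clustered and scored by male-specific covered bases.
4. **Cross-species intersection.** Deep amplicon allele fractions of sexed
   individuals from several species are classified with the same windows
   (min depth 30 per individual); sites heterozygous in all males and
   homozygous in all females of a species are intersected across species and
   stratified by sharing level *k*.

A built-in simulator (`simulate_poolsex()`, `make_amplicon_panel()`) plants a
known sex-determining block, divergent sites and a Y-specific insertion, so
every stage can be scored against truth.

## Worked example

The `analysis/` directory holds the four-step workflow. Step 1 simulates the
study conditions (10-Mb genome, 22 + 22 pools, Poisson depth 40, a 66-kb
sex-linked block with 100 divergent sites, a 55-kb Y insertion), steps 2–4
analyze it:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_snp_scan.R
Rscript analysis/03_coverage_scan.R
Rscript analysis/04_amplicon_intersect.R
```

Step 2 prints:

```
Read 20260 biallelic variants; skipped: multiallelic 0, no_depth 0
XY mode:  38 candidates, dropped: low_depth 0, not_het_in_heterogametic 18060, not_hom_in_homogametic 2162
ZW mode:  1 candidates, dropped: low_depth 0, not_het_in_heterogametic 18070, not_hom_in_homogametic 2189
Top XY cluster: chr1:5000990-5065644 with 38 SNPs (span 64655 bp)
Top ZW cluster: 1 SNPs -> XY/ZW fold = 38.0
Rank-1 XY cluster overlaps the planted sex-determining region: TRUE
```

Of the ~20,000 background SNPs, essentially none survive either screen, while
38 of the 100 planted divergent sites pass the male 45–55% heterozygosity
window (binomial read sampling at depth ~40 admits about half of the truly
sex-linked sites — detection relies on their clustering, not on per-site
retention) and they all fall in one cluster on the planted block. The ZW
scan of the same genome peaks at a single scattered SNP: a strong XY verdict.
Step 3 recovers the planted Y insertion:

```
Modal coverage peaks: female 40 | male 40 (diploid => 1.0)
Top coverage cluster: Y_hap:1-55000 with 55000 male-specific bases
Rank-1 cluster overlaps the planted Y insertion: TRUE | recovered 100.0% of its length
```

and step 4 shows that, across five synthetic species sharing only the
sex-linked block, all 12 sites male-specific in every species lie inside
that block and no species-private SNP is shared by even two species.

Ranked cluster tables, candidate TSVs and BED files land under `results/`.

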