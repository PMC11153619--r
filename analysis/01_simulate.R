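#!/usr/bin/env Rscript

## Step 1 — generate the synthetic pool-seq experiment.
##
## Two pools of 22 diploid individuals (one per sex) sequenced to Poisson
## depth 40 over a 10-Mb genome carrying ~20,000 background SNPs, one fully
## sex-linked 66-kb block with 100 fixed X/Y-divergent sites, and a 55-kb
## Y-specific insertion covered at half the diploid rate in the male pool.
## Writes the two-sample VCF, both bedgraph tracks and the truth files that
## the later steps score against.

suppressMessages(library(poolsex))

seed <- 20260919L
out_dir <- "results/sim"

cfg <- sim_config(seed = seed)
sim <- simulate_poolsex(cfg)
paths <- write_sim(sim, out_dir)

cat("Simulated pool-seq experiment (seed ", seed, "):\n", sep = "")
cat("  genome:            ", paste(names(cfg$genome), cfg$genome, sep = ":",
                                   collapse = ", "),
    " + ", cfg$y_contig, ":", cfg$y_insertion_length, "\n", sep = "")
cat("  emitted variants:  ", nrow(sim$variants), "\n", sep = "")
cat("  planted SDR:       ", cfg$sdr_contig, ":", cfg$sdr_start, "-",
    cfg$sdr_end, " (", cfg$sdr_n_sites, " divergent sites)\n", sep = "")
cat("  Y insertion:       ", cfg$y_contig, ":1-", cfg$y_insertion_length,
    "\n", sep = "")
cat("  files:\n")
for (p in paths) cat("    ", p, "\n", sep = "")
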