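#!/usr/bin/env Rscript
# Build the default synthetic capture panel: a 20-kb genome carrying one
# on-target site for a 20-nt guide, 3 genuinely edited off-target sites
# (planted rates 51.4/31.7/10.5%), 5 microsatellite-noise sites with 5%
# slippage in BOTH samples, and 20 clean sites, each with paired
# control/edited read sets at 300x. Sequence data (FASTA/FASTQ) go to
# scratch/; the small truth and site tables to results/.

suppressPackageStartupMessages(library(truguide))

seed <- 7L
fx <- make_fixture(sim_config(seed = seed))

dir.create("results", showWarnings = FALSE)
write_fixture(fx, "scratch/panel")
utils::write.table(fx$truth, "results/panel_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_bed(fx$sites, "results/panel_sites.bed")

cat("panel: ", nrow(fx$truth), "sites (",
    sum(fx$truth$role == "true_offtarget"), "true off-target,",
    sum(fx$truth$role == "ssr_noise"), "SSR-noise,",
    sum(fx$truth$role == "clean"), "clean ) at",
    fx$cfg$n_reads, "reads/site, seed", seed, "\n")
cat("sequence data under scratch/panel/, tables under results/\n")
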