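#!/usr/bin/env Rscript
# T7 endonuclease I densitometry: convert gel band intensities (uncut a,
# cut b and c) into indel percentages with the standard heteroduplex
# formula 100 * (1 - sqrt(1 - (b+c)/(a+b+c))), and tabulate the estimate
# over a grid of cut fractions.

suppressPackageStartupMessages(library(truguide))

bands <- data.frame(
  sample = c("uncut_only", "half_cut", "mostly_cut", "fully_cut"),
  a = c(100, 50, 10, 0),
  b = c(0, 25, 45, 50),
  c = c(0, 25, 45, 50))
bands$indel_pct <- t7e1_indel_pct(bands$a, bands$b, bands$c)
dir.create("results", showWarnings = FALSE)
utils::write.table(bands, "results/t7e1_examples.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(bands, row.names = FALSE)

grid <- data.frame(cut_fraction = seq(0, 1, by = 0.1))
grid$indel_pct <- vapply(grid$cut_fraction, function(f)
  t7e1_indel_pct(1 - f, f / 2, f / 2), numeric(1))
utils::write.table(grid, "results/t7e1_curve.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nestimate rises with the cut fraction but saturates below it:\n")
print(grid, row.names = FALSE)
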