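#!/usr/bin/env Rscript
# Stage 4: lysosome morphometry.
#
# Converts per-condition imaging summaries (lysosomes per cell, mean
# lysosomal area in um^2) into spherical per-lysosome volumes
# (A = pi r^2, V = 4/3 pi r^3), total cellular lysosomal volume, and fold
# changes over the drug-free control.  The bundled table is synthetic demo
# data shaped like imaging-analyzer output.
#
# Usage: Rscript analysis/04_morphometry.R [--table FILE] [--control DMSO]

suppressPackageStartupMessages(library(memtitrate))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
table_path <- get_arg("--table",
                      system.file("extdata", "lysosome_counts_synthetic.tsv",
                                  package = "memtitrate"))
control <- get_arg("--control", "DMSO")

tab <- read_lysosome_table(table_path)
out <- fold_change(tab, control)
dir.create("results", showWarnings = FALSE)
write_lysosome_table(out, "results/morphometry.tsv")

message("per-condition lysosomal volumes (um^3) and fold change vs ", control, ":")
for (i in seq_len(nrow(out)))
  message(sprintf("  %-8s r = %.3f um  V = %6.3f um^3  total = %8.2f um^3  fold = %5.2f",
                  out$condition[i], out$radius[i], out$per_lysosome_volume[i],
                  out$total_volume_per_cell[i], out$fold_change[i]))
message("wrote results/morphometry.tsv")
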