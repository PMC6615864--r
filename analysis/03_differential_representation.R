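#!/usr/bin/env Rscript
# Differential representation: t0 CPM filter, TMM, common + tagwise NB
# dispersions, per-hairpin GLM likelihood-ratio tests for the PDS-t0,
# PhenDC3-t0 and DMSO-t0 contrasts, BH FDR. Writes the per-hairpin table.

suppressMessages(library(dropscreen))

lib <- read_library("results/library.tsv", "tsv")
cm <- read_counts("results/counts.tsv")
ss <- read_samplesheet("results/samplesheet.csv")

dr <- run_differential(cm, ss, lib = lib)
utils::write.table(dr, "results/differential.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

disp <- attr(dr, "dispersions")[["1"]]
cat(sprintf("hairpins tested: %d of %d (t0 CPM >= 0.5 in all replicates)\n",
            length(unique(dr$hairpin_id)), nrow(cm)))
cat(sprintf("common dispersion %.4f; tagwise range [%.4f, %.4f]\n",
            disp$common, min(disp$tagwise), max(disp$tagwise)))
for (ctr in unique(dr$contrast)) {
  d <- dr[dr$contrast == ctr, ]
  cat(sprintf("%-15s %5d hairpins at FDR<=0.05 and log2FC<0 (median log2FC of those: %.2f)\n",
              ctr, sum(d$FDR <= 0.05 & d$log2FC < 0),
              median(d$log2FC[d$FDR <= 0.05 & d$log2FC < 0])))
}
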