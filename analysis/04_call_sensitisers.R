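#!/usr/bin/env Rscript
# Gene-level sensitiser calling ("50% or 3 hairpins" at FDR <= 0.05,
# median log2FC <= -1), ligand-specific set logic against the DMSO arm,
# and recovery scored against the simulation's planted truth.

suppressMessages(library(dropscreen))

lib <- read_library("results/library.tsv", "tsv")
dr <- utils::read.delim("results/differential.tsv")
truth <- utils::read.delim("results/truth.tsv")

calls <- classify_screen(dr, lib)
utils::write.table(calls, "results/gene_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

truth_g <- truth[!duplicated(truth$gene), ]
dmso <- calls$gene[calls$contrast == "DMSO.tF-t0" &
                     calls$class %in% c("sensitiser", "depleted")]
sets <- list()
for (arm in c("PDS", "PhenDC3")) {
  sens <- calls$gene[calls$contrast == paste0(arm, ".tF-t0") &
                       calls$class == "sensitiser"]
  lg <- ligand_specific(sens, dmso)
  sets[[arm]] <- lg
  planted <- truth_g$gene[truth_g$class == paste0("sensitiser_", arm)]
  tp <- length(intersect(lg, planted))
  cat(sprintf("%-8s %3d ligand-specific sensitisers; sensitivity %.2f, false-discovery %.3f\n",
              arm, length(lg), tp / length(planted),
              (length(lg) - tp) / max(length(lg), 1)))
}
combo <- combine_and_intersect(list(screen = sets))
cat(sprintf("common to both ligands: %d; union: %d\n",
            length(combo$both_ligands_per_screen$screen),
            length(union(sets$PDS, sets$PhenDC3))))
jsonlite::write_json(
  list(PDS = sets$PDS, PhenDC3 = sets$PhenDC3,
       both = combo$both_ligands_per_screen$screen),
  "results/sensitiser_sets.json", auto_unbox = TRUE)
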