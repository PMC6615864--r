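#!/usr/bin/env Rscript
# Simulate a focused pooled shRNA dropout screen with known ground truth:
# 1000 genes x 5 hairpins, 10% planted ligand sensitisers (split between
# PDS and PhenDC3), 5% essentials, 15 population doublings at 1000x
# coverage, three replicates, NB sequencing noise. Writes the library,
# counts, sample sheet and truth table under results/.

suppressMessages(library(dropscreen))

dir.create("results", showWarnings = FALSE)
params <- screen_sim_params(n_genes = 1000, hairpins_per_gene = 5,
                            frac_sensitiser_PDS = 0.05,
                            frac_sensitiser_PhenDC3 = 0.05,
                            frac_shared = 0, frac_essential = 0.05,
                            s_lig = -0.2, doublings_total = 15,
                            coverage = 1000, seq_depth_per_hairpin = 300,
                            phi_seq = 0.05, n_replicates = 3, seed = 20260926L)
lt <- make_library(params)
sim <- simulate_screen(lt$library, lt$truth, params)

write_library(lt$library, "results/library.tsv")
write_counts(sim$counts, "results/counts.tsv")
write_samplesheet(sim$samples, "results/samplesheet.csv")
utils::write.table(lt$truth, "results/truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("library: %d hairpins / %d genes\n",
            nrow(lt$library), length(unique(lt$library$gene))))
print(table(lt$truth$class[!duplicated(lt$truth$gene)]))
cat(sprintf("counts: %d x %d, median depth per hairpin %.0f reads\n",
            nrow(sim$counts), ncol(sim$counts),
            median(unclass(sim$counts))))
cat("expected log2FC of a planted hairpin under its ligand: d*s*e =",
    sprintf("%.2f at the mean efficacy\n",
            params$doublings_total * params$s_lig *
              mean(lt$truth$efficacy)))
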