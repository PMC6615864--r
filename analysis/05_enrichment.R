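#!/usr/bin/env Rscript
# Gene-set enrichment of the called sensitisers: Fisher fold enrichment
# against a synthetic cancer-gene-like set (planted to overlap the
# sensitiser classes), a right-sided hypergeometric batch with Bonferroni,
# and EASE scores. All sets are synthetic, built from the simulation truth.

suppressMessages(library(dropscreen))

truth <- utils::read.delim("results/truth.tsv")
sets <- jsonlite::read_json("results/sensitiser_sets.json",
                            simplifyVector = TRUE)
truth_g <- truth[!duplicated(truth$gene), ]
universe <- truth_g$gene
hits <- union(sets$PDS, sets$PhenDC3)

# synthetic "cancer census"-like set: half drawn from planted sensitisers,
# half from the rest, sized to ~3.3% of the universe
set.seed(1)
planted <- truth_g$gene[grepl("^sensitiser", truth_g$class)]
k <- round(0.033 * length(universe))
census <- c(sample(planted, min(k %/% 2, length(planted))),
            sample(setdiff(universe, planted), k - min(k %/% 2, length(planted))))

res <- fisher_enrichment(hits, universe, census)
cat(sprintf("census-like set: a=%d of n=%d hits (K=%d, N=%d): fold %.2f, p = %.2e\n",
            res$a, res$n, res$K, res$N, res$fold, res$p))
cat(sprintf("EASE score (jackknifed Fisher): %.2e\n",
            ease_score(res$a, res$n, res$K, res$N)))

collection <- list(
  census_like = census,
  planted_PDS = truth_g$gene[truth_g$class == "sensitiser_PDS"],
  planted_PhenDC3 = truth_g$gene[truth_g$class == "sensitiser_PhenDC3"],
  essentials = truth_g$gene[truth_g$class == "essential"],
  random = sample(universe, 40))
batch <- hypergeom_rightsided_batch(hits, universe, collection, "bonferroni")
utils::write.table(batch, "results/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(batch[, c("set", "a", "K", "fold", "p", "p_adj")], digits = 3)
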