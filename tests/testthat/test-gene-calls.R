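test_that("the '50% or 3 hairpins' disjunction and fc cut are applied literally", {
  # 5 hairpins, 3 significant, median of significant = -1.3 -> sensitiser
  s <- fake_slice(fdr = c(0.01, 0.02, 0.03, 0.5, 0.9),
                  log2fc = c(-1.3, -1.5, -1.1, -0.2, 0.1))
  expect_equal(call_gene(s)$class, "sensitiser")
  expect_equal(call_gene(s)$n_sig_depleted, 3L)

  # 4 hairpins, 2 significant (50%), median exactly -1.0: both boundaries inclusive
  s2 <- fake_slice(fdr = c(0.05, 0.05, 0.6, 0.7),
                   log2fc = c(-1.0, -1.0, 0, 0))
  expect_equal(call_gene(s2)$class, "sensitiser")

  # 6 hairpins, only 2 significant: 2 < 3 and 2/6 < 50% -> not called
  s3 <- fake_slice(fdr = c(0.01, 0.01, 0.5, 0.5, 0.5, 0.5),
                   log2fc = c(-2, -2, 0, 0, 0, 0))
  expect_equal(call_gene(s3)$class, "not_called")

  # depleted but above the fc cut
  s4 <- fake_slice(fdr = c(0.01, 0.01, 0.01), log2fc = c(-0.5, -0.6, -0.4))
  expect_equal(call_gene(s4)$class, "depleted")

  # significant hairpins must be depleted, not just significant
  s5 <- fake_slice(fdr = c(0.01, 0.01, 0.01), log2fc = c(2, 2.5, 3))
  expect_equal(call_gene(s5)$class, "not_called")
  expect_error(call_gene(fake_slice(numeric(0), numeric(0))), "empty")
})

test_that("the median can be taken over significant or all hairpins", {
  s <- fake_slice(fdr = c(0.01, 0.01, 0.01, 0.9, 0.9),
                  log2fc = c(-2, -2, -2, 0, 0))
  expect_equal(call_gene(s, median_over = "significant")$median_log2FC, -2)
  expect_equal(call_gene(s, median_over = "all")$median_log2FC, -2)
  s2 <- fake_slice(fdr = c(0.01, 0.01, 0.01, 0.9, 0.9),
                   log2fc = c(-2, -1.5, -2.5, -0.1, -0.1))
  expect_equal(call_gene(s2, median_over = "all")$median_log2FC, -1.5)
})

test_that("adding a significant depleted hairpin never demotes a sensitiser", {
  set.seed(71)
  n_sensitiser <- 0L
  for (i in 1:50) {
    n <- sample(3:8, 1)
    s <- fake_slice(fdr = runif(n, 0, 0.2), log2fc = runif(n, -3, 1))
    before <- call_gene(s)
    s_plus <- rbind(s, data.frame(FDR = 0.001, log2FC = -3))
    after <- call_gene(s_plus)
    if (before$class == "sensitiser") {
      n_sensitiser <- n_sensitiser + 1L
      expect_equal(after$class, "sensitiser")
    }
  }
  expect_gt(n_sensitiser, 0L)  # the property was actually exercised
})

test_that("classify_screen composes call_gene and reports untested genes", {
  p <- screen_sim_params(n_genes = 12, seed = 91)
  lt <- make_library(p)
  sim <- simulate_screen(lt$library, lt$truth, p)
  dr <- run_differential(sim$counts, sim$samples, lib = lt$library)
  calls <- classify_screen(dr, lt$library)
  # single-gene slice equals a direct call_gene on the same rows
  g <- calls$gene[1L]
  ctr <- calls$contrast[1L]
  direct <- call_gene(dr[dr$gene == g & dr$contrast == ctr, ])
  expect_equal(calls[calls$gene == g & calls$contrast == ctr,
                     c("n_hairpins", "n_sig_depleted", "class")],
               direct[, c("n_hairpins", "n_sig_depleted", "class")],
               ignore_attr = TRUE)

  # a gene fully removed upstream appears as untested
  dr_cut <- dr[dr$gene != "GENE0003", ]
  class(dr_cut) <- class(dr)
  calls_cut <- classify_screen(dr_cut, lt$library)
  expect_true(all(calls_cut$class[calls_cut$gene == "GENE0003"] == "untested"))
})

test_that("planted sensitisers and essentials classify arm-specifically", {
  p <- screen_sim_params(n_genes = 40, frac_sensitiser_PDS = 0.05,
                         frac_sensitiser_PhenDC3 = 0, frac_shared = 0,
                         frac_essential = 0.05, seed = 101)
  lt <- make_library(p)
  sim <- simulate_screen(lt$library, lt$truth, p)
  dr <- run_differential(sim$counts, sim$samples, lib = lt$library)
  calls <- classify_screen(dr, lt$library)
  truth <- lt$truth[!duplicated(lt$truth$gene), ]
  sens_gene <- truth$gene[truth$class == "sensitiser_PDS"]
  ess_gene <- truth$gene[truth$class == "essential"]
  pds_called <- calls$gene[calls$contrast == "PDS.tF-t0" &
                             calls$class == "sensitiser"]
  dmso_called <- calls$gene[calls$contrast == "DMSO.tF-t0" &
                              calls$class %in% c("sensitiser", "depleted")]
  expect_true(all(sens_gene %in% pds_called))
  expect_true(all(ess_gene %in% dmso_called))       # essentials drop everywhere
  expect_false(any(sens_gene %in% dmso_called))     # ligand-specific
  expect_true(all(ess_gene %in% pds_called))
  # subtracting DMSO leaves only the ligand-specific sensitisers
  lg <- ligand_specific(pds_called, dmso_called)
  expect_setequal(intersect(lg, c(sens_gene, ess_gene)), sens_gene)
})

test_that("ligand_specific is a set difference and idempotent", {
  expect_setequal(ligand_specific(c("a", "b", "c"), "b"), c("a", "c"))
  expect_setequal(ligand_specific(c("a", "b"), character(0)), c("a", "b"))
  expect_length(ligand_specific(c("a", "b"), c("a", "b", "c")), 0L)
  once <- ligand_specific(c("a", "b", "c"), "b")
  expect_identical(ligand_specific(once, "b"), once)
})

test_that("Venn regions satisfy inclusion-exclusion on random sets", {
  set.seed(77)
  for (i in 1:20) {
    pool <- paste0("g", 1:30)
    sets <- list(A = sample(pool, sample(0:20, 1)),
                 B = sample(pool, sample(0:20, 1)),
                 C = sample(pool, sample(0:20, 1)))
    v <- venn_counts(sets)
    expect_equal(sum(v), length(Reduce(union, sets)))
  }
})

test_that("cross-screen combination reproduces the screen set arithmetic", {
  # 89 PDS-unique + 161 PhenDC3-unique + 40 shared = 290 sensitisers in total
  pds <- paste0("p", 1:129)     # 89 unique + 40 shared
  phen <- c(paste0("q", 1:161), paste0("p", 90:129))
  screens <- list(focused = list(PDS = pds, PhenDC3 = phen))
  res <- combine_and_intersect(screens)
  shared <- res$both_ligands_per_screen$focused
  expect_length(shared, 40L)
  expect_equal(length(union(pds, phen)), 290L)
  expect_length(setdiff(pds, phen), 89L)
  expect_length(setdiff(phen, pds), 161L)

  # overlap percentage against a stated reference set
  ov <- overlap_percent(paste0("g", 1:308), paste0("g", 1:758))
  expect_equal(ov$n_overlap, 308L)
  expect_equal(ov$percent, 40.6, tolerance = 0.02)

  # key genes: present for both ligands in all screens
  three <- list(
    gw_A375 = list(PDS = c("BRCA1", "TOP1", "X1"), PhenDC3 = c("BRCA1", "TOP1", "X2")),
    gw_HT1080 = list(PDS = c("BRCA1", "TOP1", "X3"), PhenDC3 = c("BRCA1", "TOP1")),
    focused = list(PDS = c("BRCA1", "TOP1"), PhenDC3 = c("BRCA1", "TOP1", "X4")))
  expect_setequal(combine_and_intersect(three)$key_genes, c("BRCA1", "TOP1"))
  expect_error(combine_and_intersect(list()), "non-empty")
})
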