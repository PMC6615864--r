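test_that("simulated libraries have the requested shape and are deterministic", {
  p <- screen_sim_params(n_genes = 10, hairpins_per_gene = 5, seed = 5)
  lt <- make_library(p)
  expect_equal(nrow(lt$library), 50L)
  expect_true(all(nchar(lt$library$guide_seq) == 22L))
  expect_false(anyDuplicated(lt$library$guide_seq) > 0)
  expect_equal(sort(unique(lt$truth$gene)), sort(unique(lt$library$gene)))
  expect_true(all(lt$truth$efficacy >= 0 & lt$truth$efficacy <= 1))

  lt2 <- make_library(screen_sim_params(n_genes = 10, seed = 5))
  expect_identical(lt, lt2)

  p0 <- screen_sim_params(n_genes = 10, frac_sensitiser_PDS = 0,
                          frac_sensitiser_PhenDC3 = 0, frac_shared = 0,
                          frac_essential = 0, seed = 5)
  expect_true(all(make_library(p0)$truth$class == "neutral"))
  expect_error(screen_sim_params(frac_sensitiser_PDS = 0.9,
                                 frac_essential = 0.5), "sum")
})

test_that("screen simulation is seed-deterministic and matched to its sheet", {
  p <- screen_sim_params(n_genes = 20, seed = 8)
  lt <- make_library(p)
  s1 <- simulate_screen(lt$library, lt$truth, p)
  s2 <- simulate_screen(lt$library, lt$truth, p)
  expect_identical(unclass(s1$counts), unclass(s2$counts))
  expect_equal(ncol(s1$counts), 4L * p$n_replicates)
  expect_identical(colnames(s1$counts), s1$samples$sample_id)
  expect_silent(validate_design(s1$counts, s1$samples))
})

test_that("with no selection the simulated screen is null", {
  # near-noiseless regime: no selection, near-Poisson sequencing, deep reads
  p <- screen_sim_params(n_genes = 20, frac_sensitiser_PDS = 0,
                         frac_sensitiser_PhenDC3 = 0, frac_shared = 0,
                         frac_essential = 0, phi_seq = 0,
                         seq_depth_per_hairpin = 5000,
                         coverage = 5000, seed = 2)
  lt <- make_library(p)
  sim <- simulate_screen(lt$library, lt$truth, p)
  cpm_t0 <- rowMeans(cpm(sim$counts)[, grep("^t0", colnames(sim$counts))])
  cpm_pds <- rowMeans(cpm(sim$counts)[, grep("^PDS", colnames(sim$counts))])
  lfc <- log2(cpm_pds / cpm_t0)
  expect_lt(max(abs(lfc)), 0.2)
  expect_lt(abs(mean(lfc)), 0.03)
})

test_that("planted dropout effects match the d * s * e closed form", {
  # expected log2FC of a sensitiser hairpin under its ligand is d * s * e_h
  p <- screen_sim_params(n_genes = 60, frac_sensitiser_PDS = 0.2,
                         frac_sensitiser_PhenDC3 = 0, frac_shared = 0,
                         frac_essential = 0, seed = 13)
  lt <- make_library(p)
  expect_equal(lt$truth$expected_log2FC_PDS,
               with(lt$truth, ifelse(class == "sensitiser_PDS",
                                     15 * -0.2 * efficacy, 0)))
  sim <- simulate_screen(lt$library, lt$truth, p)
  planted <- lt$truth$class == "sensitiser_PDS"
  cpm_all <- cpm(sim$counts)
  obs <- rowMeans(log2(cpm_all[, grep("^PDS", colnames(cpm_all))] + 0.5)) -
    rowMeans(log2(cpm_all[, grep("^t0", colnames(cpm_all))] + 0.5))
  # centre on the neutral hairpins: dropouts free up library share for the
  # rest of the pool, a composition shift that TMM removes downstream and
  # that the per-hairpin closed form deliberately ignores
  obs <- obs - median(obs[!planted])
  expect_lt(abs(mean(obs[planted]) - mean(lt$truth$expected_log2FC_PDS[planted])),
            0.15)
})

test_that("simulated FASTQ files invert through the quantifier", {
  lib <- toy_library(n_genes = 4L, k = 5L, len = 22L, seed = 77)
  cm <- toy_counts(H = 20L, n = 2L, lambda = 40, seed = 3,
                   sample_ids = c("a", "b"))
  rownames_cm <- lib$hairpin_id
  m <- unclass(cm); rownames(m) <- rownames_cm
  cm <- count_matrix(m)
  dir <- tempfile()
  paths <- simulate_fastq(cm, lib, dir, error_rate = 0, seed = 4)
  q <- quantify(paths, lib, mode = "exact")
  expect_identical(unclass(q$counts), unclass(cm))

  # empty column -> empty FASTQ -> all-zero column with warning
  m0 <- m; m0[, 2L] <- 0L
  cm0 <- count_matrix(m0)
  paths0 <- simulate_fastq(cm0, lib, tempfile(), error_rate = 0, seed = 4)
  expect_warning(q0 <- quantify(paths0, lib), "no reads")
  expect_true(all(unclass(q0$counts)[, 2L] == 0L))
})

test_that("sequencing errors reduce the exact match rate as (1-e)^L", {
  lib <- toy_library(n_genes = 10L, k = 5L, len = 22L, seed = 21)
  m <- matrix(400L, 50L, 1L, dimnames = list(lib$hairpin_id, "s1"))
  cm <- count_matrix(m)
  paths <- simulate_fastq(cm, lib, tempfile(), error_rate = 0.001, seed = 6)
  q <- quantify(paths, lib, mode = "exact")
  expect_lt(abs(q$stats$s1$match_rate - (1 - 0.001)^22), 0.005)
})

test_that("dose-response and binding simulators hit their model identities", {
  d <- simulate_dose_response(logIC50 = -6, hill = 1, doses = 10^-6,
                              sigma_noise = 0)
  expect_equal(d$response, 50)  # midpoint at the IC50
  d2 <- simulate_dose_response(top = 90, bottom = 10, logIC50 = -5, hill = 2,
                               doses = 10^seq(-8, -2, length.out = 9),
                               sigma_noise = 0)
  fit <- fit_4pl(d2$dose, d2$response)
  expect_equal(fit$logIC50, -5, tolerance = 1e-6)
  expect_equal(fit$hill, 2, tolerance = 1e-6)

  b <- simulate_binding_curve(Bmax = 2, Kd = 71.1,
                              concentrations = c(0, 71.1), sigma_noise = 0)
  expect_equal(b$signal, c(0, 1))  # y(0) = 0, y(Kd) = Bmax/2
})
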