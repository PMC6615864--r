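test_that("CPM is counts scaled to per-million library size", {
  cm <- count_matrix(matrix(c(5L, 0L), 2, 1,
                            dimnames = list(c("h1", "h2"), "s1")))
  x <- cpm(cm, lib.sizes = 1e7)
  expect_equal(unname(x[, 1]), c(0.5, 0))
  cm2 <- count_matrix(matrix(1e6L, 1, 1, dimnames = list("h1", "s1")))
  expect_equal(unname(cpm(cm2)[1, 1]), 1e6)
  expect_error(cpm(cm, lib.sizes = 0), "zero library size")
})

test_that("the t0 CPM filter applies the all-replicates rule inclusively", {
  ss <- toy_design()
  # 10 hairpins x 12 samples; t0 columns built to hit specific CPM values
  set.seed(1)
  m <- matrix(rpois(120, 100), 10, 12,
              dimnames = list(sprintf("h%02d", 1:10), ss$sample_id))
  t0_cols <- ss$sample_id[ss$timepoint == "t0"]
  for (j in t0_cols) m[, j] <- 100L
  # make library size 2e6 per t0 sample => CPM = count / 2
  m[1L, t0_cols] <- 1L  # CPM 0.5 boundary -> kept
  pad <- 2e6 - colSums(m[, t0_cols])
  m[10L, t0_cols] <- m[10L, t0_cols] + as.integer(pad)
  cm <- count_matrix(m)
  expect_equal(unname(cpm(cm)[1L, t0_cols[1]]), 0.5)
  kept <- filter_low_counts(cm, ss, threshold = 0.5)
  expect_true("h01" %in% rownames(kept))  # >= is inclusive

  # failing in a single t0 replicate removes the hairpin
  m2 <- m
  m2[2L, t0_cols[3L]] <- 0L
  kept2 <- filter_low_counts(count_matrix(m2), ss, 0.5)
  expect_false("h02" %in% rownames(kept2))

  # three planted failures -> 7 rows remain
  m3 <- m
  m3[c(3L, 5L, 7L), t0_cols] <- 0L
  expect_equal(nrow(filter_low_counts(count_matrix(m3), ss, 0.5)), 7L)

  ss_noref <- ss[ss$timepoint != "t0", ]
  expect_error(filter_low_counts(cm, ss_noref), "no t0")
})

test_that("TMM factors are 1 for identical or depth-scaled columns", {
  m <- matrix(rpois(40, 200), 20, 2,
              dimnames = list(sprintf("h%02d", 1:20), c("a", "b")))
  m[, 2] <- m[, 1]
  f <- tmm_factors(count_matrix(m))
  expect_equal(unname(as.numeric(f)), c(1, 1))
  # doubling one column's depth changes no M value after library scaling
  m2 <- m
  m2[, 2] <- 2L * m[, 1]
  f2 <- tmm_factors(count_matrix(m2))
  expect_equal(unname(as.numeric(f2)), c(1, 1))
})

test_that("TMM factors match the straight-line oracle and are depth invariant", {
  set.seed(17)
  for (i in 1:10) {
    H <- 50L; n <- 4L
    m <- matrix(rnbinom(H * n, mu = 150, size = 5) + 1L, H, n,
                dimnames = list(sprintf("h%02d", 1:H), paste0("s", 1:n)))
    m[1:5, 2] <- m[1:5, 2] * 8L  # a few genuinely changed hairpins
    cm <- count_matrix(m)
    f <- tmm_factors(cm, ref = "s1")
    expect_equal(unname(as.numeric(f)), oracle_tmm(m, 1L), tolerance = 1e-12)
    expect_equal(exp(mean(log(as.numeric(f)))), 1, tolerance = 1e-12)
    # uniform depth scaling of one sample leaves the factors essentially
    # unchanged (M values are exactly invariant; the precision weights are
    # only asymptotically so)
    m_sc <- m
    m_sc[, 3] <- m[, 3] * 3L
    f_sc <- tmm_factors(count_matrix(m_sc), ref = "s1")
    expect_equal(as.numeric(f_sc), as.numeric(f), tolerance = 0.01)
  }
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(4)
  m <- matrix(rnbinom(200, mu = 300, size = 8) + 1L, 50, 4,
              dimnames = list(sprintf("h%02d", 1:50), paste0("s", 1:4)))
  m[1:6, 2] <- m[1:6, 2] * 6L
  f_edger <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1L)
  f_ours <- tmm_factors(count_matrix(m), ref = "s1")
  expect_equal(unname(as.numeric(f_ours)), unname(f_edger), tolerance = 1e-8)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0, 1)), c(0, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_warning(bh_adjust(c(0.1, NaN)), "NaN")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("the NB GLM reduces to Poisson at phi = 0 and has closed-form one-group fits", {
  set.seed(8)
  y <- rpois(6, 40)
  X <- cbind(1, rep(c(0, 1), each = 3))
  off <- log(runif(6, 0.5e4, 2e4))
  fit <- fit_nb_glm(y, X, off, phi = 0)
  ref <- glm(y ~ X[, 2] + offset(off), family = poisson())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$deviance, unname(ref$deviance), tolerance = 1e-6)

  # one-group design: fitted mean = (sum y / sum exp(offset)) * exp(offset);
  # exact for Poisson with any offsets and for NB with equal offsets
  fit1 <- fit_nb_glm(y, matrix(1, 6, 1), off, phi = 0)
  expect_equal(fit1$fitted, sum(y) / sum(exp(off)) * exp(off),
               tolerance = 1e-6)
  fit1b <- fit_nb_glm(y, matrix(1, 6, 1), rep(0, 6), phi = 0.1)
  expect_equal(fit1b$fitted, rep(mean(y), 6), tolerance = 1e-6)

  # all-zero response hits the degenerate guard
  fit0 <- fit_nb_glm(rep(0L, 6), X, off, phi = 0.1)
  expect_true(fit0$degenerate)
  expect_equal(fit0$fitted, rep(0, 6))
})

test_that("coefficients and LR statistics match the brute-force grid oracle", {
  y <- c(10L, 12L, 9L, 3L, 2L, 4L)
  is_g2 <- rep(c(FALSE, TRUE), each = 3)
  X <- cbind(g1 = as.numeric(!is_g2), g2 = as.numeric(is_g2))
  off <- rep(0, 6)
  fit <- fit_nb_glm(y, X, off, phi = 0.1)
  orc <- oracle_nb_grid2(y, is_g2, off, 0.1)
  expect_equal(unname(fit$coefficients), c(orc$b1, orc$b2), tolerance = 1e-3)

  lrt <- lrt_contrast(y, X, matrix(1, 6, 1), off, phi = 0.1,
                      contrast = c(-1, 1))
  orc0 <- oracle_nb_grid1(y, off, 0.1)
  expect_equal(lrt$LR, 2 * (orc$loglik - orc0$loglik), tolerance = 1e-3)
})

test_that("LRT behaves at the null and for doubled counts", {
  y <- rep(20L, 6)
  X <- cbind(g1 = rep(c(1, 0), each = 3), g2 = rep(c(0, 1), each = 3))
  res <- lrt_contrast(y, X, matrix(1, 6, 1), rep(0, 6), phi = 0.1,
                      contrast = c(-1, 1))
  expect_lt(res$LR, 1e-6)
  expect_gt(res$p, 0.999)

  y2 <- c(20L, 21L, 19L, 40L, 42L, 38L)
  res2 <- lrt_contrast(y2, X, matrix(1, 6, 1), rep(0, 6), phi = 0.05,
                       contrast = c(-1, 1))
  expect_equal(res2$log2FC, 1, tolerance = 0.05)
  expect_error(lrt_contrast(y2, X, cbind(rep(1, 6), c(1, rep(0, 5))),
                            rep(0, 6), 0.05), "nested")
})

test_that("relabelling samples within a group leaves all statistics unchanged", {
  p <- screen_sim_params(n_genes = 15, seed = 33)
  lt <- make_library(p)
  sim <- simulate_screen(lt$library, lt$truth, p)
  dr1 <- run_differential(sim$counts, sim$samples)
  # swap the two PDS endpoint replicates (same group, different labels)
  perm <- colnames(sim$counts)
  i <- match(c("PDS_tF_r1", "PDS_tF_r2"), perm)
  perm[i] <- perm[rev(i)]
  m <- unclass(sim$counts)[, perm]
  colnames(m) <- colnames(sim$counts)
  dr2 <- run_differential(count_matrix(m), sim$samples)
  expect_equal(dr1$LR, dr2$LR, tolerance = 1e-10)
  expect_equal(dr1$p, dr2$p, tolerance = 1e-10)
  expect_equal(dr1$log2FC, dr2$log2FC, tolerance = 1e-10)
})

test_that("a planted strong dropout is detected by the full pipeline", {
  # hairpin 1 loses ~8x in the PDS arm only
  ss <- toy_design()
  set.seed(12)
  base <- rnbinom(40, mu = 400, size = 10)
  m <- matrix(rep(base, 12) + rpois(480, 30), 40, 12,
              dimnames = list(sprintf("h%02d", 1:40), ss$sample_id))
  pds <- grep("^PDS", colnames(m))
  m[1L, pds] <- as.integer(round(m[1L, pds] / 8))
  dr <- run_differential(count_matrix(m), ss)
  row <- dr[dr$hairpin_id == "h01" & dr$contrast == "PDS.tF-t0", ]
  expect_lt(row$FDR, 0.05)
  expect_lt(row$log2FC, -2)
  other <- dr[dr$hairpin_id == "h01" & dr$contrast == "DMSO.tF-t0", ]
  expect_gt(other$p, 0.05)
})
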