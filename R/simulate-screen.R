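#' Parameters for the pooled-screen simulator
#'
#' The defaults emulate the screen design this package models: ~5 optimised
#' hairpins per gene, passaging at >= 1000 cells per hairpin, endpoint after
#' 15 population doublings with re-plating every 3 doublings, 3 biological
#' replicates, and negative-binomially overdispersed sequencing counts.
#' Ligand sensitiser genes carry a per-doubling selection coefficient
#' `s_lig` under the matching ligand only, so a fully efficacious hairpin is
#' expected to drop by `doublings_total * s_lig` log2 units (-3 at the
#' defaults), comfortably past the log2FC <= -1 sensitiser threshold.
#'
#' @param n_genes number of genes in the simulated library.
#' @param hairpins_per_gene hairpins targeting each gene (default 5).
#' @param frac_sensitiser_PDS,frac_sensitiser_PhenDC3 fraction of genes whose
#'   knockdown is deleterious only under the respective ligand.
#' @param frac_shared fraction sensitising to both ligands.
#' @param frac_essential fraction under negative selection in every arm.
#' @param s_lig per-doubling selection coefficient of sensitiser genes under
#'   the matching ligand (negative; default -0.2).
#' @param s_ess per-doubling selection of essential genes in all arms.
#' @param efficacy_beta length-2 shape of the Beta distribution of
#'   per-hairpin knockdown efficacy e_h in \[0, 1\]. The default Beta(5, 2)
#'   (mean ~0.71) reflects a vendor-optimised library in which most hairpins
#'   knock down well but some are weak.
#' @param sigma_lib sd of the log baseline hairpin abundance (log-normal).
#' @param coverage cells maintained per hairpin at every passage (default
#'   1000, the representation floor of the screens modelled here).
#' @param doublings_total total population doublings before the endpoint.
#' @param doublings_per_passage doublings between re-plating bottlenecks.
#' @param seq_depth_per_hairpin mean sequencing reads per hairpin.
#' @param phi_seq negative-binomial overdispersion of sequencing counts
#'   (0 gives Poisson sequencing noise).
#' @param n_replicates independent infection replicates.
#' @param seed integer RNG seed.
#' @return a `screen_sim_params` list.
#' @export
screen_sim_params <- function(n_genes = 100,
                              hairpins_per_gene = 5,
                              frac_sensitiser_PDS = 0.05,
                              frac_sensitiser_PhenDC3 = 0.05,
                              frac_shared = 0.02,
                              frac_essential = 0.05,
                              s_lig = -0.2,
                              s_ess = -0.2,
                              efficacy_beta = c(5, 2),
                              sigma_lib = 1,
                              coverage = 1000,
                              doublings_total = 15,
                              doublings_per_passage = 3,
                              seq_depth_per_hairpin = 300,
                              phi_seq = 0.05,
                              n_replicates = 3,
                              seed = 1L) {
  p <- as.list(environment())
  fr <- c(p$frac_sensitiser_PDS, p$frac_sensitiser_PhenDC3,
          p$frac_shared, p$frac_essential)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("class fractions must lie in [0,1] and sum to at most 1")
  }
  if (p$coverage <= 0) stop("coverage must be positive")
  if (p$doublings_total <= 0) stop("doublings_total must be positive")
  if (p$doublings_per_passage <= 0) stop("doublings_per_passage must be positive")
  if (length(p$efficacy_beta) != 2L || any(p$efficacy_beta <= 0)) {
    stop("efficacy_beta must be two positive shape parameters")
  }
  structure(p, class = "screen_sim_params")
}

.random_guides <- function(n, len = 22L) {
  if (log(n) > len * log(4)) stop("cannot draw ", n, " distinct ", len, "-mers")
  draw <- function(k) {
    apply(matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE),
                 nrow = k), 1L, paste, collapse = "")
  }
  g <- unique(draw(n))
  while (length(g) < n) g <- unique(c(g, draw(n - length(g))))
  g[seq_len(n)]
}

#' Simulate an shRNA library with known ground truth
#'
#' Genes are assigned to classes (neutral, essential, PDS-only sensitiser,
#' PhenDC3-only sensitiser, sensitiser to both) according to the fractions in
#' `params`; each hairpin receives a knockdown efficacy `e_h ~ Beta(a, b)`.
#' The truth table records each gene's class, each hairpin's efficacy and the
#' expected log2 fold change per arm,
#' `doublings_total * e_h * s` (0 for neutral genes and under vehicle).
#'
#' @param params a [screen_sim_params].
#' @return list with elements `library` (an [shrna_library]) and `truth`
#'   (data frame with one row per hairpin: gene, class, efficacy, and
#'   `expected_log2FC_<arm>` columns).
#' @export
make_library <- function(params) {
  stopifnot(inherits(params, "screen_sim_params"))
  set.seed(params$seed)
  G <- params$n_genes
  k <- params$hairpins_per_gene
  H <- G * k

  n_cls <- c(sensitiser_PDS = round(params$frac_sensitiser_PDS * G),
             sensitiser_PhenDC3 = round(params$frac_sensitiser_PhenDC3 * G),
             sensitiser_both = round(params$frac_shared * G),
             essential = round(params$frac_essential * G))
  if (sum(n_cls) > G) stop("class fractions allocate more genes than exist")
  classes <- c(rep(names(n_cls), n_cls), rep("neutral", G - sum(n_cls)))
  classes <- sample(classes)

  genes <- sprintf("GENE%04d", seq_len(G))
  gene_of <- rep(genes, each = k)
  class_of <- rep(classes, each = k)
  hid <- paste0(gene_of, ".sh", rep(seq_len(k), G))
  guides <- .random_guides(H)
  eff <- stats::rbeta(H, params$efficacy_beta[1L], params$efficacy_beta[2L])

  d <- params$doublings_total
  s_arm <- function(cls, arm) {
    s <- numeric(length(cls))
    s[cls == "essential"] <- params$s_ess
    if (arm == "PDS") {
      s[cls %in% c("sensitiser_PDS", "sensitiser_both")] <- params$s_lig
    } else if (arm == "PhenDC3") {
      s[cls %in% c("sensitiser_PhenDC3", "sensitiser_both")] <- params$s_lig
    }
    s
  }
  truth <- data.frame(hairpin_id = hid, gene = gene_of, class = class_of,
                      efficacy = eff,
                      expected_log2FC_DMSO = d * eff * s_arm(class_of, "DMSO"),
                      expected_log2FC_PDS = d * eff * s_arm(class_of, "PDS"),
                      expected_log2FC_PhenDC3 = d * eff * s_arm(class_of, "PhenDC3"),
                      stringsAsFactors = FALSE)
  list(library = shrna_library(hid, guides, gene_of, pool = "1"),
       truth = truth)
}

.seq_counts <- function(q, depth_total, phi) {
  mu <- depth_total * q
  if (phi > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
  } else {
    stats::rpois(length(mu), mu)
  }
}

#' Simulate a pooled dropout screen
#'
#' Generative model, per replicate: (1) baseline proportions are log-normal;
#' (2) an initial multinomial bottleneck draws `coverage * H` infected cells;
#' the reference sample (t0) is sequenced from this pool, before any
#' treatment-specific selection; (3) each arm (DMSO, PDS, PhenDC3) then grows
#' from that pool, cell counts scaling by `2^(dd * (1 + e_h * s))` over the
#' `dd` doublings of each passage, with a multinomial re-plating bottleneck
#' back to `coverage * H` cells after every passage, until `doublings_total`;
#' (4) sequencing draws gamma-Poisson (NB) counts with mean
#' `seq_depth_per_hairpin * H * q_h` and dispersion `phi_seq`.
#'
#' @param lib,truth output of [make_library].
#' @param params the [screen_sim_params] used to build the library.
#' @return list with `counts` (a [count_matrix]) and `samples`
#'   (a [sample_sheet]); columns are t0 plus one endpoint per arm, for each
#'   replicate.
#' @export
simulate_screen <- function(lib, truth, params) {
  stopifnot(inherits(params, "screen_sim_params"),
            identical(lib$hairpin_id, truth$hairpin_id))
  set.seed(params$seed + 1L)
  H <- nrow(lib)
  C <- params$coverage * H
  if (C > .Machine$integer.max) stop("coverage * H exceeds integer range")
  depth_total <- params$seq_depth_per_hairpin * H

  arms <- c("DMSO", "PDS", "PhenDC3")
  sel <- cbind(DMSO = truth$expected_log2FC_DMSO,
               PDS = truth$expected_log2FC_PDS,
               PhenDC3 = truth$expected_log2FC_PhenDC3) /
    (params$doublings_total * pmax(truth$efficacy, 1e-12))
  # per-doubling growth modifier f = e_h * s for each arm
  f <- sel * truth$efficacy

  p0 <- exp(stats::rnorm(H, 0, params$sigma_lib))
  p0 <- p0 / sum(p0)

  d_steps <- rep(params$doublings_per_passage,
                 params$doublings_total %/% params$doublings_per_passage)
  rem <- params$doublings_total %% params$doublings_per_passage
  if (rem > 0) d_steps <- c(d_steps, rem)

  cols <- list()
  meta <- list()
  for (r in seq_len(params$n_replicates)) {
    n0 <- as.numeric(stats::rmultinom(1L, C, p0))
    id0 <- sprintf("t0_r%d", r)
    cols[[id0]] <- .seq_counts(n0 / C, depth_total, params$phi_seq)
    meta[[id0]] <- c("t0", "none", r)
    for (a in arms) {
      growth <- 1 + f[, a]
      n <- n0
      for (dd in d_steps) {
        x <- n * ifelse(growth > 0, 2^(dd * growth), 0)
        if (sum(x) <= 0) stop("population collapsed in arm ", a)
        n <- as.numeric(stats::rmultinom(1L, C, x / sum(x)))
      }
      id <- sprintf("%s_tF_r%d", a, r)
      cols[[id]] <- .seq_counts(n / C, depth_total, params$phi_seq)
      meta[[id]] <- c("tF", a, r)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- lib$hairpin_id
  md <- do.call(rbind, meta)
  ss <- sample_sheet(sample_id = names(cols), pool = "1",
                     timepoint = md[, 1L], treatment = md[, 2L],
                     replicate = as.integer(md[, 3L]))
  list(counts = count_matrix(m), samples = ss)
}
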