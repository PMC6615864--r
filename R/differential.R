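#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; NaN inputs
#' propagate with a warning.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return FDR-adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) warning("NaN p-value(s) propagate NaN FDR")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential representation analysis of a pooled screen
#'
#' The full per-pool statistical pipeline: t0 CPM filter, TMM
#' normalization, common + tagwise NB dispersion estimation, per-hairpin
#' NB GLM likelihood-ratio tests for each endpoint-versus-t0 contrast, and
#' BH FDR within each pool x contrast. Pools are processed independently
#' and the per-pool tables concatenated.
#'
#' @param cm a [count_matrix].
#' @param ss the matching [sample_sheet].
#' @param lib optional [shrna_library]; adds a `gene` column.
#' @param contrasts character vector of endpoint group labels (see
#'   [sample_groups()]) to test against `t0`; default: every non-t0 group
#'   present.
#' @param cpm_threshold t0 CPM filter threshold.
#' @param prior_df tagwise-dispersion shrinkage weight.
#' @param prior_count prior count for fold-change reporting.
#' @return data frame of class `differential_result`: one row per
#'   hairpin x contrast with `hairpin_id`, `gene`, `pool`, `contrast`,
#'   `logCPM`, `log2FC`, `LR`, `p`, `FDR` and a `degenerate` flag. The
#'   per-pool dispersions are attached as the `dispersions` attribute.
#' @export
run_differential <- function(cm, ss, lib = NULL, contrasts = NULL,
                             cpm_threshold = 0.5, prior_df = 10,
                             prior_count = 0.5) {
  validate_design(cm, ss)
  ss <- ss[ss$sample_id %in% colnames(cm), , drop = FALSE]
  out <- list()
  disp <- list()
  for (pool in unique(ss$pool)) {
    ssp <- ss[ss$pool == pool, , drop = FALSE]
    cmp <- count_matrix(unclass(cm)[, ssp$sample_id, drop = FALSE])
    cmf <- filter_low_counts(cmp, ssp, threshold = cpm_threshold)
    f <- tmm_factors(cmf)
    eff_lib <- lib_sizes(cmf) * as.numeric(f)
    offsets <- log(eff_lib)
    groups <- factor(sample_groups(ssp))
    if (is.null(contrasts)) {
      test_groups <- setdiff(levels(groups), "t0")
    } else {
      test_groups <- intersect(contrasts, levels(groups))
      if (!length(test_groups)) {
        stop("none of the requested contrast groups are present in pool ",
             pool)
      }
    }

    phi_common <- estimate_common_dispersion(cmf, groups, offsets)
    phi_tag <- estimate_tagwise_dispersion(cmf, groups, offsets,
                                           prior_df = prior_df)
    disp[[pool]] <- list(common = phi_common, tagwise = phi_tag)

    Y <- unclass(cmf)
    mean_cpm <- rowMeans(sweep(Y, 2L, eff_lib, "/")) * 1e6
    logCPM <- log2(mean_cpm + 0.25)

    for (g in test_groups) {
      sel <- groups %in% c("t0", g)
      Ys <- Y[, sel, drop = FALSE]
      gs <- droplevels(factor(groups[sel], levels = c("t0", g)))
      os <- offsets[sel]
      full <- .nb_fit_oneway(Ys, gs, os, phi_tag)
      red <- .nb_fit_oneway(Ys, rep("all", sum(sel)), os, phi_tag)
      LR <- pmax(red$deviance - full$deviance, 0)
      p <- stats::pchisq(LR, df = 1L, lower.tail = FALSE)
      prior <- prior_count * exp(os) / mean(exp(os))
      aug <- .nb_fit_oneway(sweep(Ys, 2L, prior, "+"), gs, os, phi_tag)
      log2FC <- (aug$beta[, 2L] - aug$beta[, 1L]) / log(2)
      degen <- rowSums(Ys) == 0
      out[[paste(pool, g)]] <- data.frame(
        hairpin_id = rownames(Y),
        gene = if (is.null(lib)) NA_character_ else
          lib$gene[match(rownames(Y), lib$hairpin_id)],
        pool = pool,
        contrast = paste0(g, "-t0"),
        logCPM = logCPM,
        log2FC = log2FC,
        LR = LR,
        p = p,
        FDR = bh_adjust(p),
        degenerate = degen,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dispersions") <- disp
  class(res) <- c("differential_result", "data.frame")
  res
}
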