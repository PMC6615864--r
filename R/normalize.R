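#' Remove hairpins with low baseline abundance
#'
#' A hairpin is kept iff its CPM is at least `threshold` in every t0
#' (reference) sample; endpoint samples are never consulted, so a complete
#' dropout at tF cannot remove a hairpin from the analysis. The boundary is
#' inclusive: 5 counts in a 10M-read library is CPM 0.5 and passes the
#' default filter.
#'
#' @param cm a [count_matrix].
#' @param ss the matching [sample_sheet].
#' @param threshold CPM threshold applied at t0 (default 0.5).
#' @return the filtered [count_matrix] (library sizes recomputed from the
#'   retained rows is deliberately NOT done: sizes stay those of the full
#'   sequencing run, carried in the `full_lib_sizes` attribute).
#' @export
filter_low_counts <- function(cm, ss, threshold = 0.5) {
  t0 <- ss$sample_id[ss$timepoint == "t0"]
  t0 <- intersect(t0, colnames(cm))
  if (!length(t0)) stop("no t0 samples: the abundance filter is defined at t0")
  x <- cpm(cm)[, t0, drop = FALSE]
  keep <- rowSums(x >= threshold) == length(t0)
  out <- count_matrix(unclass(cm)[keep, , drop = FALSE])
  attr(out, "full_lib_sizes") <- lib_sizes(cm)
  out
}

# Single-sample TMM factor against a reference column, on the raw counts.
# Implements the weighted trimmed mean of M-values: drop hairpins zero in
# either sample, doubly trim by 30% per tail of M and 5% per tail of A, and
# average M with inverse-delta-method weights.
.tmm_pair <- function(obs, ref, n_obs, n_ref,
                      trim_m = 0.3, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]
  ref <- ref[keep]
  if (length(obs) < 2L) return(NA_real_)
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  M <- log2(p_o / p_r)
  A <- 0.5 * log2(p_o * p_r)
  # inverse-variance weights; v is the delta-method variance of M
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  w <- 1 / v
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (sum(keep2) < 2L || sum(w[keep2]) == 0) return(NA_real_)
  2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values between-sample normalization. Unless
#' given, the reference is the sample whose upper quartile of
#' library-scaled counts is closest to the mean upper quartile. Per
#' non-reference sample: hairpins zero in either sample are dropped,
#' log-ratios M and average log-abundances A are doubly trimmed (30% per
#' tail of M, 5% per tail of A), and the factor is 2 to the
#' inverse-variance-weighted mean of the surviving M values (delta-method
#' variances). Factors
#' are rescaled to geometric mean 1, so they are invariant to uniform depth
#' scaling of any sample.
#'
#' @param cm a filtered [count_matrix] with at least two samples.
#' @param ref optional reference sample id.
#' @param trim_m,trim_a per-tail trim fractions for M and A.
#' @return named numeric vector of factors (class `norm_factors`, with the
#'   reference sample id in the `ref` attribute).
#' @export
tmm_factors <- function(cm, ref = NULL, trim_m = 0.3, trim_a = 0.05) {
  m <- unclass(cm)
  if (ncol(m) < 2L) stop("TMM needs at least two samples")
  N <- lib_sizes(cm)
  if (is.null(ref)) {
    uq <- apply(sweep(m, 2L, N, "/"), 2L, stats::quantile, probs = 0.75)
    ref <- colnames(m)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref %in% colnames(m)) stop("unknown reference sample: ", ref)
  f <- rep(1, ncol(m))
  names(f) <- colnames(m)
  for (j in colnames(m)) {
    if (j == ref) next
    fj <- .tmm_pair(m[, j], m[, ref], N[j], N[ref], trim_m, trim_a)
    if (is.na(fj)) {
      warning("too few shared hairpins for TMM in sample ", j,
              "; factor set to 1")
      fj <- 1
    }
    f[j] <- fj
  }
  f <- f / exp(mean(log(f)))
  structure(f, ref = ref, class = "norm_factors")
}
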