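# NB dispersion estimation by Cox-Reid adjusted profile likelihood over a
# one-way layout (the only design the screen pipeline uses: group means
# plus log-library-size offsets).

# APL_g(phi) for every hairpin: NB log-likelihood at the phi-specific
# fitted group means minus half the log-determinant of the Fisher
# information of the coefficients (diagonal for a one-way layout).
.apl_matrix <- function(Y, groups, offsets, phi) {
  fit <- .nb_fit_oneway(Y, groups, offsets, phi)
  fit$loglik - fit$cr_adj
}

.default_phi_grid <- function(lo = 1e-4, hi = 10, n = 11L) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# Parallel golden-section maximization over per-row bracketed intervals in
# log-phi space. f(phi_vec) must return one value per row.
.golden_max_vec <- function(f, lo, hi, iter = 25L) {
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  c_ <- b - gr * (b - a)
  d_ <- a + gr * (b - a)
  fc <- f(exp(c_)); fd <- f(exp(d_))
  for (i in seq_len(iter)) {
    go_left <- fc >= fd
    b <- ifelse(go_left, d_, b)
    a <- ifelse(go_left, a, c_)
    c_ <- b - gr * (b - a)
    d_ <- a + gr * (b - a)
    fc <- f(exp(c_))
    fd <- f(exp(d_))
  }
  exp((a + b) / 2)
}

#' Estimate the common NB dispersion
#'
#' Maximizes the summed Cox-Reid adjusted profile log-likelihood over all
#' hairpins, on a log-spaced dispersion grid refined by golden-section
#' search.
#'
#' @param cm a [count_matrix] (or integer matrix), hairpins x samples.
#' @param groups factor of sample groups (one-way layout).
#' @param offsets log effective library sizes; default log column sums.
#' @param grid dispersion grid searched before refinement.
#' @return the common dispersion (scalar).
#' @export
estimate_common_dispersion <- function(cm, groups,
                                       offsets = log(lib_sizes(cm)),
                                       grid = .default_phi_grid()) {
  Y <- unclass(cm)
  groups <- as.factor(groups)
  if (ncol(Y) - nlevels(groups) < 1L) {
    stop("no residual df: supply a dispersion instead of estimating one")
  }
  tot <- vapply(grid, function(p) sum(.apl_matrix(Y, groups, offsets, p)), 0)
  i <- which.max(tot)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  .golden_max_vec(function(p) sum(.apl_matrix(Y, groups, offsets, p)),
                  lo, hi)
}

#' Estimate tagwise (per-hairpin) NB dispersions
#'
#' Weighted-likelihood empirical Bayes: per hairpin, maximizes
#' `APL_g(phi) + (prior_df / residual_df) * mean_APL(phi)`, shrinking the
#' per-hairpin estimate toward the common maximizer. The mean APL across
#' hairpins is precomputed on the dispersion grid and interpolated by a
#' spline; the per-hairpin term is evaluated exactly during a parallel
#' golden-section refinement. `prior_df = 0` gives per-hairpin ML;
#' `prior_df = Inf` returns the common dispersion for every hairpin.
#'
#' @inheritParams estimate_common_dispersion
#' @param prior_df prior degrees of freedom of the shrinkage (default 10).
#' @return numeric vector of dispersions, one per hairpin.
#' @export
estimate_tagwise_dispersion <- function(cm, groups,
                                        offsets = log(lib_sizes(cm)),
                                        prior_df = 10,
                                        grid = .default_phi_grid()) {
  Y <- unclass(cm)
  G <- nrow(Y)
  groups <- as.factor(groups)
  resid_df <- ncol(Y) - nlevels(groups)
  if (resid_df < 1L) {
    stop("no residual df: supply a dispersion instead of estimating one")
  }
  apl_grid <- vapply(grid, function(p) .apl_matrix(Y, groups, offsets, p),
                     numeric(G))
  apl_grid <- matrix(apl_grid, nrow = G)
  abar <- colMeans(apl_grid)
  abar_fun <- stats::splinefun(log(grid), abar, method = "natural")
  w <- if (is.infinite(prior_df)) Inf else prior_df / resid_df

  if (is.infinite(w)) {
    i <- which.max(abar)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    phi <- .golden_max_vec(function(p) abar_fun(log(p))[1L] * rep(1, 1),
                           lo, hi)
    return(rep(phi, G))
  }

  obj_grid <- apl_grid + w * matrix(abar, G, length(grid), byrow = TRUE)
  imax <- max.col(obj_grid, ties.method = "first")
  lo <- grid[pmax(imax - 1L, 1L)]
  hi <- grid[pmin(imax + 1L, length(grid))]
  f <- function(p) .apl_matrix(Y, groups, offsets, p) + w * abar_fun(log(p))
  .golden_max_vec(f, lo, hi)
}
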