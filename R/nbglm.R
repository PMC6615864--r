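# Negative-binomial GLM machinery (log link). phi is the NB dispersion:
# var = mu + phi * mu^2; phi = 0 is the Poisson limit.

.nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-300)
  # suppressWarnings: prior-augmented (non-integer) counts use the density
  # as a quasi-likelihood when reporting fold changes
  if (phi > 0) {
    suppressWarnings(sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)))
  } else {
    suppressWarnings(sum(stats::dpois(y, mu, log = TRUE)))
  }
}

# Unit deviances summed: 2 * (loglik at saturated mu = y  -  loglik at mu)
.nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-300)
  ys <- pmax(y, 1e-300)
  if (phi > 0) {
    2 * sum(y * log(ys / mu) -
              (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  } else {
    2 * sum(y * log(ys / mu) - (y - mu))
  }
}

#' Fit a negative-binomial GLM to one hairpin's counts
#'
#' Log-link NB GLM with known dispersion, fitted by iteratively reweighted
#' least squares with step-halving; converged when the relative deviance
#' change falls below `tol` (default 1e-8) or after `max_iter` iterations.
#' At `phi = 0` this reduces exactly to a Poisson GLM.
#'
#' @param y integer counts, one per sample.
#' @param design full-rank design matrix (rows = samples).
#' @param offsets log effective library sizes (library size times TMM
#'   factor).
#' @param phi NB dispersion (scalar, >= 0).
#' @param tol,max_iter convergence controls.
#' @return list with `coefficients`, `fitted` (means on the count scale),
#'   `deviance`, `loglik`, `converged`, `degenerate` (all-zero response:
#'   fitted means 0, coefficients at the -Inf guard).
#' @export
fit_nb_glm <- function(y, design, offsets = rep(0, length(y)), phi = 0,
                       tol = 1e-8, max_iter = 50L) {
  design <- as.matrix(design)
  n <- length(y)
  stopifnot(nrow(design) == n, length(offsets) == n, phi >= 0)
  if (qr(design)$rank < ncol(design)) stop("design matrix is not full rank")
  if (all(y == 0)) {
    return(list(coefficients = rep(-Inf, ncol(design)),
                fitted = rep(0, n), deviance = 0,
                loglik = .nb_loglik(y, rep(1e-300, n), phi),
                converged = TRUE, degenerate = TRUE))
  }
  mu <- pmax(y, mean(y) / 8)
  eta <- log(mu) - offsets
  beta <- stats::lm.fit(design, eta)$coefficients
  beta[is.na(beta)] <- 0
  eta <- drop(design %*% beta) + offsets
  mu <- exp(eta)
  dev <- .nb_deviance(y, mu, phi)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offsets) + (y - mu) / mu
    fit <- stats::lm.wfit(design, z, w)
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    step <- beta_new - beta
    dev_new <- Inf
    for (h in 0:10) {
      b <- beta + step / 2^h
      eta_try <- drop(design %*% b) + offsets
      if (max(eta_try) > 700) next
      mu_try <- exp(eta_try)
      dev_try <- .nb_deviance(y, mu_try, phi)
      if (is.finite(dev_try) && dev_try <= dev + 1e-12) {
        beta <- b; eta <- eta_try; mu <- mu_try; dev_new <- dev_try
        break
      }
    }
    if (!is.finite(dev_new)) break
    if (abs(dev - dev_new) < tol * (abs(dev) + 0.1)) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  list(coefficients = beta, fitted = mu, deviance = dev,
       loglik = .nb_loglik(y, mu, phi),
       converged = converged, degenerate = FALSE)
}

# Vectorized one-way-layout NB fit across all hairpins at once.
# Y: G x n counts; groups: factor length n; offsets: length-n log effective
# library sizes; phi: scalar or length-G dispersions. Group-indicator
# designs make the Fisher information diagonal, so each group's coefficient
# updates independently and the whole matrix is fitted with elementwise ops.
# Returns Beta (G x K, log scale, -Inf guard clamped at exp(-45)),
# Mu (G x n), deviance, loglik and the Cox-Reid adjustment
# 0.5 * sum_k log(sum_{j in k} w_j).
.nb_fit_oneway <- function(Y, groups, offsets, phi, max_iter = 30L,
                           tol = 1e-8) {
  Y <- as.matrix(Y)
  G <- nrow(Y)
  n <- ncol(Y)
  groups <- as.factor(groups)
  K <- nlevels(groups)
  ind <- outer(as.character(groups), levels(groups), "==") * 1  # n x K
  O <- matrix(offsets, G, n, byrow = TRUE)
  Phi <- matrix(rep_len(phi, G), G, n)

  # closed-form start: per-group mean on the offset scale
  denom0 <- drop(exp(matrix(offsets, 1, n)) %*% ind)  # K
  B <- log(pmax((Y %*% ind) / matrix(denom0, G, K, byrow = TRUE), 1e-20))
  B <- pmax(B, -45)
  for (it in seq_len(max_iter)) {
    Eta <- O + B[, as.integer(groups), drop = FALSE]
    Mu <- exp(Eta)
    W <- Mu / (1 + Phi * Mu)
    Z <- (Eta - O) + (Y - Mu) / pmax(Mu, 1e-300)
    num <- (W * Z) %*% ind
    den <- W %*% ind
    B_new <- ifelse(den > 0, num / pmax(den, 1e-300), -45)
    B_new <- pmin(pmax(B_new, -45), 45)
    delta <- max(abs(B_new - B))
    B <- B_new
    if (delta < 1e-10) break
  }
  Eta <- O + B[, as.integer(groups), drop = FALSE]
  Mu <- exp(Eta)
  W <- Mu / (1 + Phi * Mu)
  den <- W %*% ind

  Mu_s <- pmax(Mu, 1e-300)
  Ys <- pmax(Y, 1e-300)
  size <- 1 / pmax(Phi, 1e-300)
  ll_mat <- matrix(0, G, n)
  pos <- Phi[, 1L] > 0
  # suppressWarnings: fold-change reporting refits on prior-augmented
  # (non-integer) counts, where the density is used as a quasi-likelihood
  if (any(pos)) {
    ll_mat[pos, ] <- suppressWarnings(
      stats::dnbinom(Y[pos, , drop = FALSE],
                     size = size[pos, , drop = FALSE],
                     mu = Mu_s[pos, , drop = FALSE], log = TRUE))
  }
  if (any(!pos)) {
    ll_mat[!pos, ] <- suppressWarnings(
      stats::dpois(Y[!pos, , drop = FALSE],
                   Mu_s[!pos, , drop = FALSE], log = TRUE))
  }
  dev_mat <- 2 * (Y * log(Ys / Mu_s) -
                    ifelse(Phi > 0,
                           (Y + 1 / pmax(Phi, 1e-300)) *
                             log((1 + Phi * Y) / (1 + Phi * Mu_s)),
                           Y - Mu_s))
  list(beta = B, mu = Mu,
       deviance = rowSums(dev_mat),
       loglik = rowSums(ll_mat),
       cr_adj = 0.5 * rowSums(log(pmax(den, 1e-10))))
}

#' Likelihood-ratio test between nested NB GLMs
#'
#' `LR = deviance(reduced) - deviance(full)`, clamped at zero, referred to a
#' chi-squared distribution with df equal to the rank difference of the two
#' designs. The test uses the raw counts; the reported log2 fold change
#' comes from a separate fit with a prior count added (default 0.5, scaled
#' by relative effective library size) so that zero counts never yield
#' infinite fold changes.
#'
#' @param y counts for one hairpin.
#' @param design_full,design_reduced nested design matrices.
#' @param offsets log effective library sizes.
#' @param phi NB dispersion.
#' @param contrast numeric vector over the full-design coefficients defining
#'   the reported log fold change; default: last minus first coefficient.
#' @param prior_count prior count for fold-change reporting.
#' @return list with `LR`, `df`, `p`, `log2FC`.
#' @export
lrt_contrast <- function(y, design_full, design_reduced,
                         offsets = rep(0, length(y)), phi = 0,
                         contrast = NULL, prior_count = 0.5) {
  design_full <- as.matrix(design_full)
  design_reduced <- as.matrix(design_reduced)
  r_full <- qr(design_full)$rank
  r_red <- qr(design_reduced)$rank
  if (qr(cbind(design_full, design_reduced))$rank > r_full) {
    stop("design_reduced is not nested in design_full")
  }
  df <- r_full - r_red
  if (df < 1L) stop("designs have the same rank; nothing to test")
  fit1 <- fit_nb_glm(y, design_full, offsets, phi)
  fit0 <- fit_nb_glm(y, design_reduced, offsets, phi)
  LR <- max(fit0$deviance - fit1$deviance, 0)
  p <- stats::pchisq(LR, df = df, lower.tail = FALSE)

  L <- exp(offsets)
  prior <- prior_count * L / mean(L)
  fitp <- fit_nb_glm(y + prior, design_full, offsets, phi)
  if (is.null(contrast)) {
    contrast <- numeric(ncol(design_full))
    contrast[1L] <- -1
    contrast[length(contrast)] <- 1
  }
  log2FC <- sum(contrast * fitp$coefficients) / log(2)
  list(LR = LR, df = df, p = p, log2FC = log2FC)
}
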