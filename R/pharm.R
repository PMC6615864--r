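#' Four-parameter logistic dose-response model
#'
#' `y = bottom + (top - bottom) / (1 + 10^((log10(x) - logIC50) * hill))`.
#' With `hill > 0` the response falls with dose (growth inhibition on a
#' viability scale: top at low dose, bottom at saturating dose); the
#' midpoint `(top + bottom)/2` is reached at `x = 10^logIC50`.
#'
#' @param x positive concentrations.
#' @param top,bottom asymptotes (response units, e.g. % of untreated).
#' @param logIC50 log10 of the half-maximal concentration.
#' @param hill slope.
#' @return fitted responses.
#' @export
four_pl <- function(x, top, bottom, logIC50, hill) {
  bottom + (top - bottom) / (1 + 10^((log10(x) - logIC50) * hill))
}

#' Fit a 4PL dose-response curve
#'
#' Least squares via Levenberg-Marquardt with a deterministic multi-start:
#' top/bottom initialized from the data extremes, logIC50 from the dose
#' bracketing the half-range response, hill started at +1 and -1; the
#' lowest-RSS converged fit wins (first on ties). `normalized = TRUE` fixes
#' top = 100 and bottom = 0 (response already in % of untreated).
#'
#' @param dose positive concentrations.
#' @param response responses (replicates allowed: repeat doses).
#' @param normalized fix the asymptotes at 100/0.
#' @return list of class `four_pl_fit`: `top`, `bottom`, `logIC50`, `hill`,
#'   `se` (per-parameter standard errors), `rss`, `flat` (degenerate flag).
#' @export
fit_4pl <- function(dose, response, normalized = FALSE) {
  if (any(dose <= 0)) stop("doses must be positive")
  nd <- length(unique(dose))
  if (!normalized && nd < 4L) stop("free 4PL fit needs >= 4 distinct doses")
  if (normalized && nd < 2L) stop("normalized fit needs >= 2 distinct doses")
  dat <- data.frame(x = dose, y = response)

  if (diff(range(response)) < sqrt(.Machine$double.eps)) {
    return(structure(list(top = mean(response), bottom = mean(response),
                          logIC50 = stats::median(log10(dose)), hill = 0,
                          se = c(top = NA, bottom = NA, logIC50 = NA, hill = NA),
                          rss = 0, flat = TRUE, normalized = normalized),
                     class = "four_pl_fit"))
  }

  means <- tapply(response, dose, mean)
  ds <- as.numeric(names(means))
  half <- (max(means) + min(means)) / 2
  i <- which.min(abs(means - half))
  start_l50 <- log10(ds[i])

  best <- NULL
  for (h0 in c(1, -1)) {
    fit <- tryCatch({
      if (normalized) {
        minpack.lm::nlsLM(y ~ four_pl(x, 100, 0, l50, h), data = dat,
                          start = list(l50 = start_l50, h = h0),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ four_pl(x, t, b, l50, h), data = dat,
                          start = list(t = max(response), b = min(response),
                                       l50 = start_l50, h = h0),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("4PL fit failed from every start")
  cf <- stats::coef(best$fit)
  se_all <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, length(cf)))
  if (normalized) {
    out <- list(top = 100, bottom = 0, logIC50 = unname(cf["l50"]),
                hill = unname(cf["h"]),
                se = c(top = NA, bottom = NA,
                       logIC50 = unname(se_all["l50"]), hill = unname(se_all["h"])))
  } else {
    top <- unname(cf["t"]); bot <- unname(cf["b"])
    se <- c(top = unname(se_all["t"]), bottom = unname(se_all["b"]),
            logIC50 = unname(se_all["l50"]), hill = unname(se_all["h"]))
    hill <- unname(cf["h"])
    # canonicalize so bottom <= top (flip asymptotes and slope sign)
    if (bot > top) {
      tmp <- top; top <- bot; bot <- tmp
      hill <- -hill
      se[c("top", "bottom")] <- se[c("bottom", "top")]
    }
    out <- list(top = top, bottom = bot, logIC50 = unname(cf["l50"]),
                hill = hill, se = se)
  }
  out$rss <- best$rss
  out$flat <- abs(out$hill) < 1e-6
  out$normalized <- normalized
  structure(out, class = "four_pl_fit")
}

#' Concentration producing a given percent growth inhibition
#'
#' Inverts the fitted 4PL at a viability of `100 - p`: the GI_p. For a
#' normalized fit, `p = 50` returns `10^logIC50` exactly.
#'
#' @param fit a `four_pl_fit` on a % of untreated scale.
#' @param p percent growth inhibition in (0, 100).
#' @return concentration (same units as the fitted doses).
#' @export
gi_value <- function(fit, p) {
  stopifnot(inherits(fit, "four_pl_fit"))
  if (p <= 0 || p >= 100) stop("p must lie strictly between 0 and 100")
  y <- 100 - p
  if (fit$flat) stop("flat fit: no concentration achieves ", p, "% inhibition")
  lo <- min(fit$top, fit$bottom)
  hi <- max(fit$top, fit$bottom)
  if (y <= lo || y >= hi) {
    stop(sprintf("target viability %.3g%% outside the fitted asymptotes (%.3g, %.3g)",
                 y, lo, hi))
  }
  10^(fit$logIC50 + log10((fit$top - y) / (y - fit$bottom)) / fit$hill)
}

#' Bliss-independence synergy surface
#'
#' From a viability matrix (% of untreated) whose first row and column are
#' the single-agent margins and whose `[1, 1]` cell is the untreated
#' control: fractional inhibition `I = 1 - viability/100` (clamped to
#' \[0, 1\]), Bliss expectation `I_a + I_b - I_a I_b` from the margins, and
#' synergy `S = 100 * (I_obs - I_bliss)` in percentage points (positive =
#' synergy). Replicate matrices are averaged before the computation.
#'
#' @param viability numeric matrix with dose-A rows and dose-B columns
#'   (dimnames give the doses; row 1 / column 1 = zero dose), or a list of
#'   replicate matrices to average.
#' @param tol_untreated tolerance around 100% for the untreated cell.
#' @return list of class `synergy_surface`: `inhibition`, `expected`,
#'   `synergy` matrices, `peak` (max synergy and its dose indices/names),
#'   and a `clamped` flag matrix for viability > 100%.
#' @export
bliss_surface <- function(viability, tol_untreated = 5) {
  if (is.list(viability)) {
    dims <- unique(lapply(viability, dim))
    if (length(dims) != 1L) stop("replicate matrices must share dimensions")
    viability <- Reduce(`+`, viability) / length(viability)
  }
  v <- as.matrix(viability)
  if (nrow(v) < 2L || ncol(v) < 2L) {
    stop("viability matrix must include single-agent margins")
  }
  if (abs(v[1L, 1L] - 100) > tol_untreated) {
    stop("cell [1,1] must be the untreated control (~100% viability)")
  }
  clamped <- v > 100
  I <- pmin(pmax(1 - v / 100, 0), 1)
  Ia <- I[, 1L]  # drug A alone (column 1)
  Ib <- I[1L, ]  # drug B alone (row 1)
  expected <- outer(Ia, Ib, function(a, b) a + b - a * b)
  S <- 100 * (I - expected)
  peak_idx <- which(S == max(S), arr.ind = TRUE)[1L, , drop = TRUE]
  peak <- list(synergy = max(S),
               row = unname(peak_idx[1L]), col = unname(peak_idx[2L]),
               dose_A = rownames(v)[peak_idx[1L]],
               dose_B = colnames(v)[peak_idx[2L]])
  structure(list(inhibition = I, expected = expected, synergy = S,
                 peak = peak, clamped = clamped),
            class = "synergy_surface")
}

#' Fit a one-site specific-binding curve
#'
#' Least squares on `y = Bmax * x / (Kd + x)`. Started from the signal
#' maximum and the half-saturation concentration; a negative fitted Kd
#' triggers one deterministic refit from an alternative start before the
#' fit is flagged.
#'
#' @param x non-negative concentrations.
#' @param y measured signal.
#' @return list of class `one_site_fit`: `Bmax`, `Kd`, `se`, `rss`,
#'   `degenerate` flag.
#' @export
fit_one_site <- function(x, y) {
  if (any(x < 0)) stop("concentrations must be non-negative")
  if (length(unique(x)) < 3L) stop("need >= 3 distinct concentrations")
  if (all(y == 0)) {
    return(structure(list(Bmax = 0, Kd = NA_real_,
                          se = c(Bmax = NA, Kd = NA), rss = 0,
                          degenerate = TRUE), class = "one_site_fit"))
  }
  dat <- data.frame(x = x, y = y)
  bmax0 <- max(y)
  kd0 <- {
    i <- which.min(abs(y - bmax0 / 2))
    max(x[i], min(x[x > 0]))
  }
  do_fit <- function(b0, k0) {
    tryCatch(minpack.lm::nlsLM(y ~ Bmax * x / (Kd + x), data = dat,
                               start = list(Bmax = b0, Kd = k0),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             error = function(e) NULL)
  }
  fit <- do_fit(bmax0, kd0)
  if (!is.null(fit) && stats::coef(fit)["Kd"] <= 0) {
    fit <- do_fit(bmax0, max(x) / 2)
  }
  if (is.null(fit)) stop("one-site fit failed")
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Bmax = NA_real_, Kd = NA_real_))
  structure(list(Bmax = unname(cf["Bmax"]), Kd = unname(cf["Kd"]),
                 se = c(Bmax = unname(se["Bmax"]), Kd = unname(se["Kd"])),
                 rss = sum(stats::resid(fit)^2),
                 degenerate = unname(cf["Kd"]) <= 0),
            class = "one_site_fit")
}
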