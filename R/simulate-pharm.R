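#' Simulate dose-response measurements from a 4PL curve
#'
#' Responses follow the four-parameter logistic model used by [fit_4pl()]
#' (viability as % of untreated; `hill > 0` means inhibition) with additive
#' Gaussian noise.
#'
#' @param top,bottom,logIC50,hill 4PL parameters (see [fit_4pl()]).
#' @param doses positive concentrations.
#' @param sigma_noise sd of additive Gaussian noise, on the response scale.
#' @param n_replicates replicate measurements per dose.
#' @param seed integer RNG seed.
#' @return data frame with columns `dose`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(top = 100, bottom = 0, logIC50 = -6,
                                   hill = 1, doses, sigma_noise = 0,
                                   n_replicates = 1L, seed = 1L) {
  if (any(doses <= 0)) stop("doses must be positive")
  set.seed(seed)
  d <- rep(doses, each = n_replicates)
  mu <- four_pl(d, top, bottom, logIC50, hill)
  data.frame(dose = d,
             replicate = rep(seq_len(n_replicates), length(doses)),
             response = mu + stats::rnorm(length(d), 0, sigma_noise))
}

#' Simulate a one-site saturation binding curve
#'
#' `y = Bmax * x / (Kd + x)` plus Gaussian noise, the specific-binding model
#' fitted by [fit_one_site()].
#'
#' @param Bmax saturating signal.
#' @param Kd dissociation constant, same units as `concentrations`.
#' @param concentrations non-negative ligand concentrations.
#' @param sigma_noise sd of additive Gaussian noise.
#' @param n_replicates replicate measurements per concentration.
#' @param seed integer RNG seed.
#' @return data frame with columns `conc`, `replicate`, `signal`.
#' @export
simulate_binding_curve <- function(Bmax = 1, Kd = 71.1, concentrations,
                                   sigma_noise = 0, n_replicates = 1L,
                                   seed = 1L) {
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  set.seed(seed)
  x <- rep(concentrations, each = n_replicates)
  data.frame(conc = x,
             replicate = rep(seq_len(n_replicates), length(concentrations)),
             signal = Bmax * x / (Kd + x) +
               stats::rnorm(length(x), 0, sigma_noise))
}
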