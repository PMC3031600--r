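# Synthetic tumor growth trajectories: exponential growth with
# multiplicative lognormal noise of a given coefficient of variation.

#' Growth simulation spec
#'
#' @param y0_mm3 initial volume (mm^3).
#' @param doubling_days target doubling time (days); the rate constant is
#'   `k = 0.69 / doubling_days`, matching the doubling-time convention used
#'   throughout the package.
#' @param cv coefficient of variation of the multiplicative lognormal noise
#'   (0 gives noise-free trajectories).
#' @param times_days observation times (>= 3, strictly increasing).
#' @param seed RNG seed.
#' @return object of class `growth_sim_spec`.
#' @export
growth_sim_spec <- function(y0_mm3 = 30, doubling_days = 2.06, cv = 0.1,
                            times_days = c(0, 2, 4, 6, 8), seed = 1L) {
  check_positive_scalar(y0_mm3, "y0_mm3")
  check_positive_scalar(doubling_days, "doubling_days")
  check_nonneg_scalar(cv, "cv")
  stop_if(length(times_days) < 3L, "need at least 3 timepoints")
  stop_if(any(diff(times_days) <= 0), "times must be strictly increasing")
  structure(list(y0_mm3 = y0_mm3, doubling_days = doubling_days, cv = cv,
                 times_days = as.numeric(times_days), seed = seed),
            class = "growth_sim_spec")
}

#' Generate a synthetic growth series
#'
#' `y(t) = y0 * exp(k t) * eps`, `k = 0.69 / doubling_days`, with `eps`
#' lognormal scaled to unit mean and coefficient of variation `cv`.
#'
#' @param spec a [growth_sim_spec()].
#' @return a [growth_series()].
#' @export
gen_growth <- function(spec) {
  stop_if(!inherits(spec, "growth_sim_spec"), "'spec' must be a growth_sim_spec")
  k <- 0.69 / spec$doubling_days
  mu <- spec$y0_mm3 * exp(k * spec$times_days)
  if (spec$cv > 0) {
    sdlog <- sqrt(log(1 + spec$cv^2))
    eps <- with_seed(spec$seed,
                     rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    mu <- mu * eps
  }
  growth_series(spec$times_days, mu)
}
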