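# Lognormal uncertainty in the adult hydrated SC thickness, and
# age-conditional sampling.

#' Estimate a lognormal coefficient of variation
#'
#' Estimates the coefficient of variation of a set of positive measurements
#' under a lognormal assumption: `cv = sqrt(exp(s2) - 1)` where `s2` is the
#' unbiased (n-1) sample variance of the natural logs.
#'
#' @param values numeric vector of at least two positive measurements.
#' @return The estimated coefficient of variation.
#' @export
estimate_cv_lognormal <- function(values) {
  if (length(values) < 2) stopf("need at least 2 values")
  if (any(values <= 0)) stopf("all values must be positive")
  sqrt(exp(stats::var(log(values))) - 1)
}

#' Lognormal parameters from mean and CV
#'
#' Converts an arithmetic mean and coefficient of variation into the
#' log-scale parameters of a lognormal distribution:
#' `sigma2 = ln(1 + cv^2)`, `mu = ln(mean) - sigma2 / 2`.
#'
#' @param mean arithmetic mean (> 0).
#' @param cv coefficient of variation (>= 0).
#' @return A list of class `"lognormal_spec"` with `mu` and `sigma2`.
#' @export
lognormal_from_mean_cv <- function(mean, cv) {
  if (!is_number(mean) || mean <= 0) stopf("mean must be positive")
  if (cv < 0) stopf("cv must be non-negative")
  sigma2 <- log(1 + cv^2)
  structure(list(mu = log(mean) - sigma2 / 2, sigma2 = sigma2),
            class = "lognormal_spec")
}

#' Sample age-conditional SC thickness
#'
#' Draws hydrated SC thickness values by sampling the adult lognormal
#' distribution and scaling each draw by the SC maturation ratio at the given
#' age.
#'
#' @param spec a [lognormal_from_mean_cv()] spec (log-scale `mu`, `sigma2`).
#' @param model the SC thickness [maturation_model()].
#' @param age_days postnatal age in days.
#' @param n number of draws (>= 1).
#' @param seed integer seed; draws are bit-reproducible for a fixed seed.
#' @return Numeric vector of `n` thicknesses (um).
#' @export
sample_sc_thickness <- function(spec, model, age_days, n, seed = NULL) {
  stopifnot(inherits(spec, "lognormal_spec"), n >= 1)
  ratio <- maturation_ratio(model, age_days)
  with_seed(seed, stats::rlnorm(n, spec$mu, sqrt(spec$sigma2))) * ratio
}
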