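# Pediatric Monte Carlo flux prediction from a fitted adult model.

#' Predict pediatric flux by Monte Carlo simulation
#'
#' Runs `n` simulations of the skin permeation model at a given postnatal
#' age, each with an independent draw of the hydrated SC thickness (adult
#' lognormal distribution scaled by the SC maturation ratio).  The viable
#' epidermis and dermis thicknesses scale deterministically with their
#' maturation ratios.  Returns the geometric mean and the empirical
#' 2.5th-97.5th percentile interval of the terminal flux.
#'
#' @param fit an [fit_adult()] result.
#' @param age_days postnatal age in days.
#' @param n number of Monte Carlo samples (default 100).
#' @param seed integer seed for the thickness draws.
#' @param sc_spec lognormal spec for the adult hydrated SC thickness;
#'   defaults to [lognormal_from_mean_cv()] with mean 43 um and the CV
#'   estimated from the packaged adult SC thickness measurements.
#' @param scenario exposure scenario for the pediatric runs; defaults to the
#'   adult scenario stored in the fit (same dose, duration and vehicle).
#' @param sc_multiplier extra multiplier on the sampled SC thickness (e.g.
#'   a preterm adjustment); default taken from the fit's configuration.
#' @return An object of class `"child_prediction"`: `age_days`, per-sample
#'   `flux`, `gm_flux`, `ci` (2.5/97.5 percentiles), `n`, `n_failed`,
#'   `seed`.
#' @export
predict_child <- function(fit, age_days, n = 100, seed = 1,
                          sc_spec = NULL, scenario = NULL,
                          sc_multiplier = NULL) {
  stopifnot(inherits(fit, "adult_dermal_fit"), n >= 2)
  if (is.null(sc_spec)) sc_spec <- default_sc_spec()
  if (is.null(scenario)) scenario <- fit$scenario
  if (is.null(sc_multiplier)) sc_multiplier <- fit$config$preterm_sc_multiplier

  h_sc <- sample_sc_thickness(sc_spec, fit$models$sc_thickness, age_days,
                              n, seed) * sc_multiplier
  base <- pediatric_parameters(fit$reference, fit$models, age_days)

  flux <- vapply(h_sc, function(h) {
    phys <- base
    phys$h_sc_um <- h
    out <- tryCatch(
      simulate_outputs(coef(fit), fit$compound, scenario, phys,
                       fit$config, fit$reference),
      error = function(e) NULL)
    if (is.null(out)) NA_real_ else out[["flux"]]
  }, numeric(1))

  failed <- sum(is.na(flux))
  if (failed > 0.1 * n)
    stopf("more than 10%% of Monte Carlo simulations failed (%d of %d)",
          failed, n)
  ok <- flux[!is.na(flux)]
  structure(list(age_days = age_days, flux = ok, h_sc_um = h_sc,
                 gm_flux = gmean(ok),
                 ci = stats::quantile(ok, c(0.025, 0.975), names = FALSE),
                 n = n, n_failed = failed, seed = seed),
            class = "child_prediction")
}

#' @rdname predict_child
#' @param object an `adult_dermal_fit`.
#' @param ... passed to `predict_child()`.
#' @export
predict.adult_dermal_fit <- function(object, age_days, ...) {
  predict_child(object, age_days, ...)
}

# Lognormal spec of the adult hydrated SC thickness: arithmetic mean 43 um,
# CV estimated from the packaged adult measurements.
default_sc_spec <- function() {
  cv <- estimate_cv_lognormal(load_fixture("sc_thickness_adult")$mean_um)
  lognormal_from_mean_cv(43, cv)
}

#' @export
print.child_prediction <- function(x, ...) {
  cat(sprintf(
    "<child_prediction> age %.3g d: geometric mean flux %.3g ug/cm^2/h (95%% interval %.3g-%.3g, n = %d%s)\n",
    x$age_days, x$gm_flux, x$ci[1], x$ci[2], x$n,
    if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}

#' Fold error of a prediction
#'
#' `fold_error = predicted / observed`; 1 is a perfect prediction.
#'
#' @param predicted predicted flux, ug/cm^2/h.
#' @param observed observed flux, ug/cm^2/h (> 0).
#' @return The fold error.
#' @export
fold_error <- function(predicted, observed) {
  if (any(observed <= 0)) stopf("observed flux must be positive")
  predicted / observed
}
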