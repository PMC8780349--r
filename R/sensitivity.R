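# Local sensitivity analysis of the permeation outputs with respect to the
# lumped layer parameters, and the child-vs-adult differential screen.

SENSITIVITY_PARAMS <- c("d_sc", "d_ed", "d_de", "k_sc_w", "k_ed_w", "k_de_w",
                        "h_sc", "h_ed", "h_de")

sim_outputs_from_parts <- function(coeffs, physiology, scenario, config) {
  dom <- skin_domain(coeffs, physiology, config)
  sim <- simulate_permeation(dom, scenario, config,
                             times = c(0, scenario$duration_h))
  c(yJ = terminal_flux(sim),
    yQ = sim$accumulation[length(sim$accumulation)])
}

#' Local sensitivity of the permeation outputs
#'
#' Central-difference normalized sensitivity coefficients
#' `S = (dY / Y) / (dP / P)` of the terminal flux `yJ` and final receptor
#' accumulation `yQ` with respect to the lumped layer parameters (layer
#' diffusivities, partition coefficients and thicknesses), evaluated at a
#' given postnatal age.
#'
#' @param compound a [compound()].
#' @param qspr a [qspr_set()] (nominal or fitted).
#' @param scenario an [exposure_scenario()].
#' @param age_days postnatal age in days.
#' @param config a [model_config()].
#' @param reference an [adult_reference()].
#' @param models maturation models.
#' @param parameters subset of `r paste0('"', SENSITIVITY_PARAMS, '"',
#'   collapse = ", ")` to perturb.
#' @param perturbation relative perturbation (default 0.1, i.e. +/-10%).
#' @return An object of class `"sensitivity_report"`: matrix of coefficients
#'   (rows = parameters, columns = `yJ`, `yQ`), the age and the baseline
#'   outputs.  Parameters whose perturbation is degenerate are `NA` and
#'   flagged.
#' @export
local_sensitivity <- function(compound, qspr, scenario, age_days,
                              config = model_config(),
                              reference = adult_reference(),
                              models = default_maturation_models(),
                              parameters = SENSITIVITY_PARAMS,
                              perturbation = 0.1) {
  parameters <- match.arg(parameters, SENSITIVITY_PARAMS, several.ok = TRUE)
  physiology <- pediatric_parameters(reference, models, age_days)
  coeffs <- layer_coefficients(compound, qspr, physiology, config, reference,
                               vehicle_ph = scenario$vehicle_ph)

  base <- sim_outputs_from_parts(coeffs, physiology, scenario, config)
  S <- matrix(NA_real_, length(parameters), 2,
              dimnames = list(parameters, c("yJ", "yQ")))
  skipped <- character(0)

  apply_perturb <- function(param, fac) {
    co <- coeffs; ph <- physiology
    switch(param,
           d_sc = co$d_sc <- co$d_sc * fac,
           d_ed = co$d_ed <- co$d_ed * fac,
           d_de = co$d_de <- co$d_de * fac,
           k_sc_w = co$k_sc_w <- co$k_sc_w * fac,
           k_ed_w = co$k_ed_w <- co$k_ed_w * fac,
           k_de_w = co$k_de_w <- co$k_de_w * fac,
           h_sc = ph$h_sc_um <- ph$h_sc_um * fac,
           h_ed = ph$h_ed_um <- ph$h_ed_um * fac,
           h_de = ph$h_de_um <- ph$h_de_um * fac)
    sim_outputs_from_parts(co, ph, scenario, config)
  }

  for (p in parameters) {
    if (1 - perturbation <= 0) { skipped <- c(skipped, p); next }
    up <- apply_perturb(p, 1 + perturbation)
    dn <- apply_perturb(p, 1 - perturbation)
    S[p, ] <- ((up - dn) / base) / (2 * perturbation)
  }

  structure(list(S = S, age_days = age_days, base = base,
                 perturbation = perturbation, skipped = skipped),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> age %.4g d (baseline yJ %.4g, yQ %.4g)\n",
              x$age_days, x$base[["yJ"]], x$base[["yQ"]]))
  print(round(x$S, 3))
  invisible(x)
}

#' Age-differential sensitivity screen
#'
#' Flags parameters whose normalized sensitivity coefficient differs between
#' a child-age and an adult-age report by at least `threshold` (default
#' 0.15) for either output.
#'
#' @param child,adult two [local_sensitivity()] reports over the same
#'   parameter list.
#' @param threshold flagging threshold on `|S_child - S_adult|`.
#' @return Character vector of flagged parameter names (possibly empty).
#' @export
age_differential_sensitivity <- function(child, adult, threshold = 0.15) {
  stopifnot(inherits(child, "sensitivity_report"),
            inherits(adult, "sensitivity_report"))
  if (!identical(rownames(child$S), rownames(adult$S)))
    stopf("sensitivity reports cover different parameter lists")
  d <- abs(child$S - adult$S)
  rownames(d)[apply(d, 1, function(r) any(r >= threshold, na.rm = TRUE))]
}
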