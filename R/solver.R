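# Three-layer Fickian permeation solver (method of lines).
#
# The skin is discretised into finite-volume cells; the state is the amount
# of permeant per area in each cell plus a donor state and the receptor
# accumulation.  Transport between cells is driven by differences in
# "activity" a = c / K (the water-equivalent concentration), which is
# continuous across layer interfaces, with harmonic-mean interface
# conductances.  The receptor boundary is a perfect sink (zero activity).

#' Exposure scenario
#'
#' Describes one in vitro permeation test (IVPT) run: the applied dose, its
#' duration, and the vehicle.
#'
#' @param dose_ug_cm2 applied dose per area, ug/cm^2 (> 0; 0 allowed for
#'   blank runs).
#' @param duration_h experiment duration, hours.
#' @param vehicle_ph vehicle pH, or `NA` for non-aqueous vehicles (treated as
#'   non-ionizing).
#' @param solubility_vehicle_ug_cm3 permeant solubility in the vehicle,
#'   ug/cm^3 (for aqueous buffers this is the aqueous solubility; mg/L and
#'   ug/cm^3 are numerically equal).
#' @param vehicle_thickness_um donor vehicle depth, um.
#' @param donor_regime `"auto"` (default), `"finite"` or `"saturated"`.  With
#'   `"auto"` the donor is saturated when the dose exceeds the amount the
#'   vehicle can dissolve (`solubility * depth`) and finite (well-mixed,
#'   depleting) otherwise.  A saturated donor holds the donor activity at the
#'   solubility for the whole run.
#' @param label optional scenario label.
#' @return An object of class `"exposure_scenario"`.
#' @export
exposure_scenario <- function(dose_ug_cm2, duration_h, vehicle_ph = NA_real_,
                              solubility_vehicle_ug_cm3 = NA_real_,
                              vehicle_thickness_um = 10000,
                              donor_regime = c("auto", "finite", "saturated"),
                              label = NULL) {
  donor_regime <- match.arg(donor_regime)
  if (dose_ug_cm2 < 0) stopf("dose must be non-negative")
  if (duration_h <= 0) stopf("duration must be positive")
  if (donor_regime == "saturated" && is.na(solubility_vehicle_ug_cm3))
    stopf("a saturated donor requires the vehicle solubility")
  structure(list(dose_ug_cm2 = dose_ug_cm2, duration_h = duration_h,
                 vehicle_ph = vehicle_ph,
                 solubility_vehicle_ug_cm3 = solubility_vehicle_ug_cm3,
                 vehicle_thickness_um = vehicle_thickness_um,
                 donor_regime = donor_regime, label = label),
            class = "exposure_scenario")
}

resolve_donor_regime <- function(scenario) {
  if (scenario$donor_regime != "auto") return(scenario$donor_regime)
  cap <- scenario$solubility_vehicle_ug_cm3 *
    scenario$vehicle_thickness_um / UM_PER_CM
  if (!is.na(cap) && scenario$dose_ug_cm2 > cap) "saturated" else "finite"
}

#' Build the spatial discretisation of the skin
#'
#' @param coeffs a [layer_coefficients()] object.
#' @param params an `age_parameters` object ([pediatric_parameters()]); the
#'   hydrated SC thickness is taken from it.
#' @param config a [model_config()] (supplies nodes per layer).
#' @return An object of class `"skin_domain"`: per-cell widths (cm),
#'   diffusivities (cm^2/h), partition coefficients, and layer bookkeeping.
#' @export
skin_domain <- function(coeffs, params, config = model_config()) {
  h_um <- c(sc = params$h_sc_um, ed = params$h_ed_um, de = params$h_de_um)
  if (any(h_um <= 0)) stopf("all layer thicknesses must be positive")
  n <- config$nodes[c("sc", "ed", "de")]
  h_cm <- h_um / UM_PER_CM
  dx <- rep(h_cm / n, times = n)
  layer <- rep(c("sc", "ed", "de"), times = n)
  D <- rep(c(coeffs$d_sc, coeffs$d_ed, coeffs$d_de), times = n)
  K <- rep(c(coeffs$k_sc_w, coeffs$k_ed_w, coeffs$k_de_w), times = n)
  structure(list(dx = dx, D = D, K = K, layer = layer,
                 h_um = h_um, n = n, coeffs = coeffs),
            class = "skin_domain")
}

#' Simulate an IVPT run
#'
#' Solves the three-layer diffusion problem for one exposure scenario and
#' returns the flux into the receptor `yJ(t)` (ug/cm^2/h), the receptor
#' accumulation `yQ(t)` (ug/cm^2), per-layer amounts and a mass-balance
#' ledger.
#'
#' @param domain a [skin_domain()].
#' @param scenario an [exposure_scenario()].
#' @param config a [model_config()] (integrator tolerances, output sampling).
#' @param times optional output time grid (hours); defaults to a regular grid
#'   of spacing `config$output_dt` over the scenario duration.
#' @return An object of class `"permeation_sim"`: `time`, `flux`,
#'   `accumulation`, `amounts` (matrix with columns vehicle/sc/ed/de/receptor),
#'   `mass_balance_error`, `donor_regime`.
#' @export
simulate_permeation <- function(domain, scenario, config = model_config(),
                                times = NULL) {
  regime <- resolve_donor_regime(scenario)
  N <- length(domain$dx)
  dx <- domain$dx; D <- domain$D; K <- domain$K
  wk <- dx * K
  V_v <- scenario$vehicle_thickness_um / UM_PER_CM  # cm

  # interface conductances (cm/h): g[i] couples cell i and i+1
  r_half <- (dx / 2) / (D * K)
  g_int <- 1 / (r_half[-N] + r_half[-1])
  g_top <- 1 / r_half[1]      # well-mixed donor, no donor-side resistance
  g_bot <- 1 / r_half[N]      # perfect-sink receptor

  sat_act <- scenario$solubility_vehicle_ug_cm3

  rhs <- function(t, y, parms) {
    donor <- y[1]
    u <- y[2:(N + 1)]
    a <- u / wk
    a_top <- if (regime == "saturated") sat_act else donor / V_v
    j_top <- g_top * (a_top - a[1])
    if (regime == "finite" && donor <= 0 && j_top > 0) j_top <- 0
    j_int <- g_int * (a[-N] - a[-1])
    j_bot <- g_bot * a[N]
    flux_in <- c(j_top, j_int)
    flux_out <- c(j_int, j_bot)
    list(c(if (regime == "saturated") j_top else -j_top,
           flux_in - flux_out,
           j_bot))
  }

  if (is.null(times)) {
    times <- unique(c(seq(0, scenario$duration_h, by = config$output_dt),
                      scenario$duration_h))
  }
  y0 <- c(if (regime == "finite") scenario$dose_ug_cm2 else 0, rep(0, N), 0)

  if (scenario$dose_ug_cm2 == 0 ||
      (regime == "saturated" && sat_act == 0)) {
    z <- rep(0, length(times))
    amounts <- cbind(vehicle = z, sc = z, ed = z, de = z, receptor = z)
    return(structure(list(time = times, flux = z, accumulation = z,
                          amounts = amounts, mass_balance_error = 0,
                          donor_regime = regime, scenario = scenario),
                     class = "permeation_sim"))
  }

  atol <- max(config$atol, 1e-10) *
    max(scenario$dose_ug_cm2, if (is.na(sat_act)) 0 else sat_act, 1)
  sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = "lsoda",
                      jactype = "bandint", bandup = 1L, banddown = 1L,
                      rtol = config$rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stopf("integrator failure (istate %d) in simulate_permeation",
          attr(sol, "istate")[1])
  tt <- sol[, 1]
  donor <- sol[, 2]
  U <- sol[, 3:(N + 2), drop = FALSE]
  Q <- sol[, N + 3]

  neg_tol <- 1e-6 * max(scenario$dose_ug_cm2, 1)
  if (min(U) < -neg_tol)
    stopf("negative concentrations beyond tolerance in simulate_permeation")
  U[U < 0] <- 0

  a_last <- U[, N] / wk[N]
  flux <- g_bot * a_last

  by_layer <- function(l) rowSums(U[, domain$layer == l, drop = FALSE])
  amounts <- cbind(vehicle = if (regime == "finite") donor else NA_real_,
                   sc = by_layer("sc"), ed = by_layer("ed"),
                   de = by_layer("de"), receptor = Q)

  skin_total <- amounts[, "sc"] + amounts[, "ed"] + amounts[, "de"]
  mb <- if (regime == "finite") {
    max(abs(donor + skin_total + Q - scenario$dose_ug_cm2)) /
      scenario$dose_ug_cm2
  } else {
    # donor state holds cumulative influx from the saturated boundary
    denom <- max(donor, 1e-12)
    max(abs(donor - (skin_total + Q))) / denom
  }

  structure(list(time = tt, flux = flux, accumulation = Q, amounts = amounts,
                 mass_balance_error = mb, donor_regime = regime,
                 scenario = scenario),
            class = "permeation_sim")
}

#' Terminal flux of a simulation
#'
#' The instantaneous flux into the receptor at the final output time.
#'
#' @param result a `permeation_sim`.
#' @return Terminal flux, ug/cm^2/h.
#' @export
terminal_flux <- function(result) {
  stopifnot(inherits(result, "permeation_sim"))
  result$flux[length(result$flux)]
}

#' Late-window flux slope
#'
#' Alternative "steady-state" flux estimate: the regression slope of the
#' receptor accumulation over the last fraction of the run.
#'
#' @param result a `permeation_sim`.
#' @param window fraction of the run to regress over (default last 20%).
#' @return Slope of `yQ` vs time, ug/cm^2/h.
#' @export
flux_slope <- function(result, window = 0.2) {
  stopifnot(inherits(result, "permeation_sim"))
  t_end <- max(result$time)
  keep <- result$time >= (1 - window) * t_end
  if (sum(keep) < 2) stopf("too few points in the slope window")
  unname(stats::coef(stats::lm(result$accumulation[keep] ~
                                 result$time[keep]))[2])
}

#' @export
print.permeation_sim <- function(x, ...) {
  cat(sprintf(
    "<permeation_sim> %s donor, %.4g h; terminal flux %.4g ug/cm^2/h, final Q %.4g ug/cm^2 (mass balance err %.2g)\n",
    x$donor_regime, max(x$time), terminal_flux(x),
    x$accumulation[length(x$accumulation)], x$mass_balance_error))
  invisible(x)
}

#' @export
plot.permeation_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$flux, type = "l", xlab = "time (h)",
                 ylab = "flux (ug/cm^2/h)", main = "Receptor flux", ...)
  graphics::plot(x$time, x$accumulation, type = "l", xlab = "time (h)",
                 ylab = "Q (ug/cm^2)", main = "Receptor accumulation", ...)
  invisible(x)
}
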