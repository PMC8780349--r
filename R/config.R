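#' Model configuration
#'
#' Collects the tunable constants of the dermal absorption model: stratum
#' corneum (SC) phase volume fractions, the bilayer count of the SC
#' permeability closure, viable epidermis/dermis transport constants, the
#' donor vehicle depth, and the numerical discretisation settings of the
#' permeation solver.
#'
#' @param phi_w,phi_pro,phi_lip volume fractions of the aqueous, protein
#'   (corneocyte) and lipid phases of the fully hydrated SC.  Defaults 0.60,
#'   0.325, 0.075; held age-invariant.
#' @param n_bilayers number of lamellar lipid bilayers the permeant crosses in
#'   series through the SC; scales the SC permeability closure.  Default 70.
#' @param tortuosity_factor divisor applied to the aqueous diffusivity in the
#'   viable epidermis and dermis.  Default 3.
#' @param k_ed_w,k_de_w viable epidermis/water and dermis/water partition
#'   coefficients (near-aqueous tissue).  Default 0.7 each.
#' @param ionize_lipid logical; if `TRUE` (default) only the non-ionized
#'   fraction of the permeant partitions into the SC lipid phase.  The aqueous
#'   and protein phases always see total concentration.
#' @param in_vitro_hydration logical; if `TRUE` (default) the SC is treated as
#'   fully hydrated (hydration ratio forced to 1), matching in vitro
#'   permeation-test conditions.  Set `FALSE` for in-vivo-style runs where the
#'   hydration maturation ratio scales the SC water fraction.
#' @param vehicle_thickness_um donor vehicle depth in micrometres.  In the
#'   finite-donor regime it sets the donor concentration (dose / depth); it
#'   also enters the automatic donor-regime rule (the donor saturates when
#'   the dose exceeds `solubility * depth`).  Default 10000 (1 cm, i.e. about
#'   1 mL/cm^2 — an infinite-dose-style dissolved donor).
#' @param preterm_sc_multiplier optional multiplier applied to SC thickness
#'   for preterm subjects; default 1 (preterm treated like term, postnatal
#'   age only).
#' @param nodes integer vector of grid cells per layer, named `sc`, `ed`,
#'   `de`.  Default `c(sc = 15, ed = 15, de = 30)`.
#' @param rtol,atol relative/absolute tolerances of the stiff time integrator.
#' @param output_dt output sampling interval in hours for full time series.
#'
#' @return An object of class `"pedperm_config"` (a named list).
#' @export
model_config <- function(phi_w = 0.60, phi_pro = 0.325, phi_lip = 0.075,
                         n_bilayers = 70, tortuosity_factor = 3,
                         k_ed_w = 0.7, k_de_w = 0.7,
                         ionize_lipid = TRUE, in_vitro_hydration = TRUE,
                         vehicle_thickness_um = 10000,
                         preterm_sc_multiplier = 1,
                         nodes = c(sc = 15L, ed = 15L, de = 30L),
                         rtol = 1e-6, atol = 1e-10, output_dt = 0.25) {
  if (any(c(phi_w, phi_pro, phi_lip) <= 0))
    stopf("phase fractions must be positive")
  if (n_bilayers <= 0 || tortuosity_factor <= 0)
    stopf("n_bilayers and tortuosity_factor must be positive")
  if (any(nodes < 5))
    stopf("at least 5 grid nodes per layer are required")
  structure(list(
    phi_w = phi_w, phi_pro = phi_pro, phi_lip = phi_lip,
    n_bilayers = n_bilayers, tortuosity_factor = tortuosity_factor,
    k_ed_w = k_ed_w, k_de_w = k_de_w,
    ionize_lipid = ionize_lipid, in_vitro_hydration = in_vitro_hydration,
    vehicle_thickness_um = vehicle_thickness_um,
    preterm_sc_multiplier = preterm_sc_multiplier,
    nodes = nodes, rtol = rtol, atol = atol, output_dt = output_dt
  ), class = "pedperm_config")
}

#' Adult reference skin parameters
#'
#' Reference values for adult skin against which pediatric parameters are
#' expressed as maturation ratios.  The fully hydrated SC thickness defaults
#' to 43 um; the viable epidermis default reflects the adult maximal
#' epidermis (60 um) and the dermis default a dermatomed in vitro section
#' (500 um).
#'
#' @param h_sc_hydrated_um fully hydrated adult SC thickness, um.
#' @param h_ed_um adult viable epidermis thickness, um.
#' @param h_de_um dermis thickness of the simulated skin section, um.  The
#'   default (500) describes a dermatomed in vitro preparation; set the full
#'   anatomical dermis (~2500) for in-vivo-style simulations.
#' @return A named list with class `"adult_reference"`; `hydration_ref` is 1
#'   by definition of the ratio scale.
#' @export
adult_reference <- function(h_sc_hydrated_um = 43, h_ed_um = 60,
                            h_de_um = 500) {
  if (any(c(h_sc_hydrated_um, h_ed_um, h_de_um) <= 0))
    stopf("adult thicknesses must be positive")
  structure(list(h_sc_hydrated_um = h_sc_hydrated_um,
                 h_ed_um = h_ed_um, h_de_um = h_de_um,
                 hydration_ref = 1.0),
            class = "adult_reference")
}
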