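# QSPR closures for stratum corneum transport parameters.
#
# Three uncertain SC parameters form the fittable set: the trans-bilayer
# permeability log10(ktrans), the protein/water partition coefficient
# log10(PCpro/w), and the lipid/water partition coefficient log10(Klip/w).

#' Nominal trans-bilayer permeability
#'
#' `log10 ktrans = -0.570 - 0.840 * MW^(1/3)` with ktrans in cm/s.
#'
#' @param mw_g_mol molecular weight, g/mol (>= 0).
#' @return log10 of the trans-bilayer permeability (cm/s).
#' @export
log10_ktrans_nominal <- function(mw_g_mol) {
  if (any(mw_g_mol < 0)) stopf("molecular weight must be non-negative")
  -0.570 - 0.840 * mw_g_mol^(1 / 3)
}

#' Nominal SC protein/water partition coefficient
#'
#' `log10 PCpro/w = 0.27 * log Kow + log10(5.4)`.
#'
#' @param log_kow log10 octanol/water partition coefficient.
#' @return log10 of the protein/water partition coefficient.
#' @export
log10_pc_pro_w_nominal <- function(log_kow) {
  0.27 * log_kow + log10(5.4)
}

#' Nominal SC lipid/water partition coefficient
#'
#' `log10 Klip/w = 0.81 * log Kow + log10(0.43)`.
#'
#' @param log_kow log10 octanol/water partition coefficient.
#' @return log10 of the lipid/water partition coefficient.
#' @export
log10_k_lip_w_nominal <- function(log_kow) {
  0.81 * log_kow + log10(0.43)
}

# Printed half-widths of the QSPR uncertainty ranges (log10 units).
QSPR_RANGES <- c(log10_ktrans = 1.26, log10_pc_pro_w = 0.32,
                 log10_k_lip_w = 0.434)

#' QSPR parameter set for a compound
#'
#' Evaluates the three nominal QSPRs for a compound, or wraps user-supplied
#' (fitted/sampled) values, recording provenance.  Fitted or sampled values
#' must lie within the printed uncertainty ranges around the nominal values
#' (±1.26, ±0.32, ±0.434 log10 units respectively).
#'
#' @param compound a [compound()].
#' @param log10_ktrans,log10_pc_pro_w,log10_k_lip_w optional overrides of the
#'   nominal values.
#' @param provenance one of `"nominal"`, `"fitted"`, `"sampled"`.
#' @return An object of class `"qspr_set"` with fields `log10_ktrans`,
#'   `log10_pc_pro_w`, `log10_k_lip_w`, `provenance`.
#' @export
qspr_set <- function(compound, log10_ktrans = NULL, log10_pc_pro_w = NULL,
                     log10_k_lip_w = NULL,
                     provenance = c("nominal", "fitted", "sampled")) {
  provenance <- match.arg(provenance)
  nom <- qspr_nominal_values(compound)
  val <- c(log10_ktrans = log10_ktrans %||% nom[["log10_ktrans"]],
           log10_pc_pro_w = log10_pc_pro_w %||% nom[["log10_pc_pro_w"]],
           log10_k_lip_w = log10_k_lip_w %||% nom[["log10_k_lip_w"]])
  if (provenance != "nominal") {
    lo <- nom - QSPR_RANGES
    hi <- nom + QSPR_RANGES
    tol <- 1e-8
    if (any(val < lo - tol | val > hi + tol))
      stopf("%s QSPR values must lie within the printed uncertainty ranges",
            provenance)
  }
  structure(c(as.list(val), list(provenance = provenance)),
            class = "qspr_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nominal QSPR triple as a named numeric vector.
qspr_nominal_values <- function(compound) {
  c(log10_ktrans = log10_ktrans_nominal(compound$mw_g_mol),
    log10_pc_pro_w = log10_pc_pro_w_nominal(compound$log_kow),
    log10_k_lip_w = log10_k_lip_w_nominal(compound$log_kow))
}

#' QSPR fitting box for a compound
#'
#' Lower/upper bounds of the three uncertain SC parameters: nominal values
#' plus/minus the printed uncertainty half-widths.
#'
#' @param compound a [compound()].
#' @return A list with numeric vectors `nominal`, `lower`, `upper`.
#' @export
qspr_bounds <- function(compound) {
  nom <- qspr_nominal_values(compound)
  list(nominal = nom, lower = nom - QSPR_RANGES, upper = nom + QSPR_RANGES)
}

#' Non-ionized fraction (Henderson-Hasselbalch)
#'
#' @param ph medium pH; `NA` returns 1 (treated as non-ionizing medium, e.g.
#'   a pure organic vehicle).
#' @param pka compound pKa.
#' @param ionization_class `"acidic"`, `"basic"` or `"neutral"`.
#' @return Fraction of the permeant in the non-ionized form, in \[0, 1\].
#' @export
fraction_nonionized <- function(ph, pka,
                                ionization_class = c("neutral", "acidic",
                                                     "basic")) {
  ionization_class <- match.arg(ionization_class)
  if (ionization_class == "neutral" || is.na(ph) || is.na(pka)) return(1)
  switch(ionization_class,
         acidic = 1 / (1 + 10^(ph - pka)),
         basic = 1 / (1 + 10^(pka - ph)))
}

#' Layer transport coefficients
#'
#' Converts a compound's QSPR parameter set and the skin physiology at a given
#' age into the lumped per-layer diffusion and partition coefficients used by
#' the permeation solver.
#'
#' The SC/water partition coefficient is a phase-volume-weighted sum,
#' `K_sc/w = phi_w * hydration + phi_pro * PCpro/w + phi_lip * Klip/w * f_ni`,
#' where `f_ni` is the non-ionized fraction at the vehicle pH (applied to the
#' lipid phase only, when `ionize_lipid` is set).  The SC permeability is
#' `P_sc = ktrans * Klip/w / n_bilayers`, and the SC diffusivity follows as
#' `D_sc = P_sc * h_ref / K_sc/w` with `h_ref` the *adult reference* hydrated
#' SC thickness, so that `D_sc` is an age-invariant material property and the
#' steady-state flux scales inversely with the actual SC thickness.  The
#' viable epidermis and dermis share an aqueous diffusivity from the
#' molecular-weight correlation `log10 D_aq(cm^2/s) = -4.15 - 0.655 log10 MW`,
#' divided by a tortuosity factor, and a common near-aqueous partition
#' coefficient.
#'
#' @param compound a [compound()].
#' @param qspr a [qspr_set()].
#' @param physiology an `age_parameters` object from [pediatric_parameters()].
#' @param config a [model_config()].
#' @param reference an [adult_reference()]; supplies `h_ref`.
#' @param vehicle_ph pH of the dosing vehicle (`NA` for non-aqueous vehicles).
#' @return An object of class `"layer_coefficients"`: list with `d_sc`,
#'   `d_ed`, `d_de` (cm^2/h) and `k_sc_w`, `k_ed_w`, `k_de_w`
#'   (dimensionless), all strictly positive.
#' @export
layer_coefficients <- function(compound, qspr, physiology,
                               config = model_config(),
                               reference = adult_reference(),
                               vehicle_ph = NA_real_) {
  stopifnot(inherits(qspr, "qspr_set"))
  if (any(c(physiology$h_sc_um, physiology$h_ed_um, physiology$h_de_um) <= 0))
    stopf("all layer thicknesses must be positive")
  f_ni <- if (isTRUE(config$ionize_lipid))
    fraction_nonionized(vehicle_ph, compound$pka, compound$ionization_class)
  else 1
  hydr <- if (isTRUE(config$in_vitro_hydration)) 1 else physiology$hydration_ratio

  pc_pro <- 10^qspr$log10_pc_pro_w
  k_lip <- 10^qspr$log10_k_lip_w
  ktrans_cm_h <- 10^qspr$log10_ktrans * 3600  # cm/s -> cm/h

  k_sc_w <- config$phi_w * hydr + config$phi_pro * pc_pro +
    config$phi_lip * k_lip * f_ni
  p_sc <- ktrans_cm_h * k_lip / config$n_bilayers        # cm/h
  h_ref_cm <- reference$h_sc_hydrated_um / UM_PER_CM
  d_sc <- p_sc * h_ref_cm / k_sc_w                       # cm^2/h

  d_aq_cm2_s <- 10^(-4.15 - 0.655 * log10(compound$mw_g_mol))
  d_tissue <- d_aq_cm2_s * 3600 / config$tortuosity_factor

  out <- list(d_sc = d_sc, d_ed = d_tissue, d_de = d_tissue,
              k_sc_w = k_sc_w, k_ed_w = config$k_ed_w,
              k_de_w = config$k_de_w)
  if (any(unlist(out) <= 0) || any(!is.finite(unlist(out))))
    stopf("layer coefficients must be positive and finite")
  structure(out, class = "layer_coefficients")
}
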