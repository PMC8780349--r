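#' Define a permeant compound
#'
#' Bundles the physicochemical properties that drive the QSPR transport
#' closures: molecular weight, lipophilicity, ionization behaviour and
#' solubilities.
#'
#' @param name compound name.
#' @param mw_g_mol molecular weight, g/mol (> 0).
#' @param log_kow log10 octanol/water partition coefficient.
#' @param pka acid dissociation constant; ignored for neutral compounds.
#' @param ionization_class one of `"acidic"`, `"basic"`, `"neutral"`.
#' @param sol_water_mg_L aqueous solubility, mg/L (numerically equal to
#'   ug/cm^3).
#' @param sol_vehicle_mg_mL solubility in the dosing vehicle, mg/mL, or `NA`
#'   when the vehicle is aqueous (the water solubility is then used).
#' @param melting_point_C optional melting point, deg C.
#' @return An object of class `"compound"`.
#' @examples
#' compound("phenobarbital", 232.2, 1.47, pka = 7.3,
#'          ionization_class = "acidic", sol_water_mg_L = 1110,
#'          sol_vehicle_mg_mL = 100)
#' @export
compound <- function(name, mw_g_mol, log_kow, pka = NA_real_,
                     ionization_class = c("neutral", "acidic", "basic"),
                     sol_water_mg_L = NA_real_, sol_vehicle_mg_mL = NA_real_,
                     melting_point_C = NA_real_) {
  ionization_class <- match.arg(ionization_class)
  if (!is_number(mw_g_mol) || mw_g_mol <= 0)
    stopf("molecular weight must be a positive number")
  if (!is.na(sol_water_mg_L) && sol_water_mg_L <= 0)
    stopf("solubilities must be positive when present")
  if (!is.na(sol_vehicle_mg_mL) && sol_vehicle_mg_mL <= 0)
    stopf("solubilities must be positive when present")
  if (ionization_class != "neutral" && is.na(pka))
    stopf("pka is required for acidic/basic compounds")
  structure(list(name = name, mw_g_mol = mw_g_mol, log_kow = log_kow,
                 pka = pka, ionization_class = ionization_class,
                 sol_water_mg_L = sol_water_mg_L,
                 sol_vehicle_mg_mL = sol_vehicle_mg_mL,
                 melting_point_C = melting_point_C),
            class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s: MW %.1f g/mol, log Kow %.2f, %s%s\n",
              x$name, x$mw_g_mol, x$log_kow, x$ionization_class,
              if (is.na(x$pka)) "" else sprintf(" (pKa %.2f)", x$pka)))
  invisible(x)
}

#' Read compounds from a delimited table
#'
#' Expects header columns `name, mw_g_mol, log_kow, pka, ionization_class,
#' sol_water_mg_L, sol_vehicle_mg_mL`.
#'
#' @param path CSV file path.
#' @return A named list of [compound()] objects.
#' @export
read_compounds <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mw_g_mol", "log_kow", "pka", "ionization_class",
            "sol_water_mg_L", "sol_vehicle_mg_mL")
  if (!all(need %in% names(tab)))
    stopf("compound table must have columns: %s", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    compound(r$name, r$mw_g_mol, r$log_kow, pka = r$pka,
             ionization_class = r$ionization_class,
             sol_water_mg_L = r$sol_water_mg_L,
             sol_vehicle_mg_mL = r$sol_vehicle_mg_mL)
  })
  names(out) <- tab$name
  out
}
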