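# Packaged fixtures: the printed compound, exposure, maturation and
# SC-thickness tables, guarded by checksums, plus the synthetic ratio
# generator used in tests and demos.

FIXTURE_MD5 <- c(
  compounds = "53ba63e4265c6f89627cae1e31bf68b7",
  adult_ivpt = "1880cfe764d912cc422e7ca69aedf981",
  infant_ivpt = "2dec18dc373fbea6a61b28427e09f471",
  maturation_models = "0927c7b8f797c16dd227278557f8ac6f",
  sc_thickness_adult = "ced3fa77f29404fdeac6ae6ea526bf02",
  sc_thickness_infant_adult = "199a7e5c74203d9c43d502c831db2ed6"
)

#' Load a packaged fixture table
#'
#' Reads one of the packaged data tables, verifying its checksum first (a
#' guard against silent fixture edits).  Available fixtures:
#' `"compounds"` (physicochemical inputs), `"adult_ivpt"` (adult exposure
#' scenarios and observations), `"infant_ivpt"` (infant scenarios and
#' observations, with gestational age in weeks and postnatal age in the
#' printed unit plus a unit column), `"maturation_models"` (maturation
#' equation coefficients), `"sc_thickness_adult"` (adult SC thickness
#' measurements by anatomical site), `"sc_thickness_infant_adult"`
#' (infant vs adult SC thickness comparison means).
#'
#' @param name fixture name.
#' @return A data frame.  For `"infant_ivpt"` an extra column
#'   `postnatal_age_days` holds the canonical postnatal age in days.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(FIXTURE_MD5))
    stopf("unknown fixture '%s'; available: %s", name,
          paste(names(FIXTURE_MD5), collapse = ", "))
  path <- system.file("extdata", paste0(name, ".csv"), package = "pedperm",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(FIXTURE_MD5[[name]])))
    stopf("fixture '%s' failed its checksum (found %s)", name, sum)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (name == "infant_ivpt") {
    mult <- c(h = 1 / 24, d = 1, w = 7)[tab$postnatal_age_unit]
    if (any(is.na(mult))) stopf("unknown postnatal age unit in fixture")
    tab$postnatal_age_days <- tab$postnatal_age_value * mult
  }
  tab
}

#' Packaged compounds
#'
#' The three evaluation compounds as [compound()] objects.
#' @return Named list of compounds.
#' @export
fixture_compounds <- function() {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(load_fixture("compounds"), tmp, row.names = FALSE)
  read_compounds(tmp)
}

#' Maturation models from a coefficient table
#'
#' Materialises [maturation_model()] objects from a coefficient table with
#' columns `parameter_id, model_label, form, a, b, c, n, m, cap_age_days,
#' min_age_days` (the packaged `"maturation_models"` fixture layout).
#'
#' @param tab coefficient table; defaults to the packaged fixture.
#' @param sc_model which SC thickness model label to use (2 or 1).
#' @return Named list of maturation models keyed by parameter id.
#' @export
maturation_models_from_table <- function(tab = load_fixture("maturation_models"),
                                         sc_model = 2) {
  keep_label <- paste0("sc_model_", sc_model)
  tab <- tab[tab$parameter_id != "sc_thickness" |
               tab$model_label == keep_label, ]
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    co <- c(a = r$a, b = r$b, c = r$c, n = r$n, m = r$m)
    co <- co[!is.na(co)]
    maturation_model(r$parameter_id, r$form, co,
                     cap_age_days = if (is.na(r$cap_age_days)) Inf
                                    else r$cap_age_days,
                     min_age_days = r$min_age_days)
  })
  names(out) <- tab$parameter_id
  out[MATURATION_PARAMS]
}

#' Generate synthetic child:adult ratio data
#'
#' Emits a ratio-vs-age dataset from a maturation model plus additive
#' Gaussian noise, floored at 0.01.  Serves as a test double for
#' literature-sourced ratio scatter.
#'
#' @param model a [maturation_model()].
#' @param ages ages in days.
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param seed integer seed; fixed seed gives identical datasets.
#' @return Data frame with `parameter_id`, `age_days`, `ratio`,
#'   `source_label`.
#' @export
generate_synthetic_ratios <- function(model, ages, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  mu <- maturation_ratio(model, ages)
  r <- with_seed(seed, mu + stats::rnorm(length(ages), 0, noise_sd))
  data.frame(parameter_id = model$parameter_id, age_days = ages,
             ratio = pmax(r, 0.01), source_label = "synthetic",
             stringsAsFactors = FALSE)
}
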