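# Maturation ratio models: child:adult ratios of skin parameters as
# functions of postnatal age (days), capped at 1 beyond a cap age.

MATURATION_FORMS <- c("sigmoid", "hill", "polynomial")
MATURATION_PARAMS <- c("sc_thickness", "ed_thickness", "de_thickness",
                       "sc_hydration")

#' Construct a maturation model
#'
#' A maturation model maps postnatal age (days) to a child:adult ratio of one
#' skin parameter.  Below `cap_age_days` the functional form is evaluated;
#' at and beyond the cap the ratio is exactly 1.
#'
#' Functional forms (Age in days):
#' * `sigmoid`: `a * Age / (b + Age) + c`
#' * `hill`: `a * Age^n / (b^n + Age^n) + c`
#' * `polynomial`: `a * Age^n + b * Age^m + c`
#'
#' @param parameter_id one of `"sc_thickness"`, `"ed_thickness"`,
#'   `"de_thickness"`, `"sc_hydration"`.
#' @param form functional form, one of `"sigmoid"`, `"hill"`, `"polynomial"`.
#' @param coefficients named numeric vector using names `a`, `b`, `c`, `n`,
#'   `m` as the form requires; missing polynomial terms default to 0.
#' @param cap_age_days age at/beyond which the ratio is exactly 1, or `Inf`
#'   for forms that approach 1 asymptotically.
#' @param min_age_days evaluation floor for the age; ages below it are
#'   clamped.  Used for the SC hydration polynomial whose negative-exponent
#'   term diverges as age approaches 0 (floor 1 day).
#' @return An object of class `"maturation_model"`.
#' @export
maturation_model <- function(parameter_id, form, coefficients,
                             cap_age_days = Inf, min_age_days = 0) {
  parameter_id <- match.arg(parameter_id, MATURATION_PARAMS)
  form <- match.arg(form, MATURATION_FORMS)
  if (!all(is.finite(coefficients)))
    stopf("maturation coefficients must be finite")
  structure(list(parameter_id = parameter_id, form = form,
                 coefficients = coefficients, cap_age_days = cap_age_days,
                 min_age_days = min_age_days),
            class = "maturation_model")
}

# Evaluate a raw functional form (no cap) at ages (days).
eval_maturation_form <- function(form, coefficients, age_days) {
  cf <- function(nm, default = NA_real_) {
    if (!nm %in% names(coefficients)) return(default)
    v <- coefficients[[nm]]
    if (is.null(v) || is.na(v)) default else v
  }
  a <- cf("a"); b <- cf("b"); c <- cf("c")
  switch(form,
         sigmoid = a * age_days / (b + age_days) + c,
         hill = {
           n <- cf("n")
           a * age_days^n / (b^n + age_days^n) + c
         },
         polynomial = {
           n <- cf("n"); m <- cf("m", 0)
           a2 <- cf("a", 0); b2 <- cf("b", 0)
           t1 <- if (a2 == 0) 0 else a2 * age_days^n
           t2 <- if (b2 == 0) 0 else b2 * age_days^m
           t1 + t2 + c
         },
         stopf("unknown maturation form '%s'", form))
}

#' Evaluate a maturation ratio
#'
#' @param model a [maturation_model()].
#' @param age_days postnatal age(s) in days (>= 0).
#' @return Child:adult ratio(s); exactly 1 at and beyond the model's cap age.
#' @export
maturation_ratio <- function(model, age_days) {
  stopifnot(inherits(model, "maturation_model"))
  if (any(age_days < 0)) stopf("age_days must be non-negative")
  age <- pmax(age_days, model$min_age_days)
  r <- eval_maturation_form(model$form, model$coefficients, age)
  r[age_days >= model$cap_age_days] <- 1
  r
}

#' @export
predict.maturation_model <- function(object, age_days, ...) {
  maturation_ratio(object, age_days)
}

#' @export
print.maturation_model <- function(x, ...) {
  cat(sprintf("<maturation_model> %s: %s form, cap %s d\n", x$parameter_id,
              x$form,
              if (is.finite(x$cap_age_days))
                format(x$cap_age_days, digits = 4) else "none"))
  cat("  coefficients:",
      paste(names(x$coefficients),
            signif(x$coefficients, 4), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Default maturation models
#'
#' The packaged maturation ratio models for SC thickness, viable epidermis
#' thickness, dermis thickness, and SC hydration:
#' * SC thickness (model 2, the default): `2.662e-7 * Age^1.878 + 0.724`
#'   for Age <= 1604 d, 1 beyond.  An alternative SC model 1 (fitted on a
#'   dataset including neonatal measurements that exceed adult values) is
#'   available via `sc_model = 1`.
#' * Epidermis: Hill, `(1 - 0.634) * Age^5.363 / (18.702^5.363 + Age^5.363)
#'   + 0.634` (approaches 1 asymptotically).
#' * Dermis: sigmoid, `(1.5 - 0.407) * Age / (8974 + Age) + 0.407` for
#'   Age <= 9883 d, 1 beyond (the printed formula leaves a small deliberate
#'   jump at the cap).
#' * Hydration: `-0.344 * Age^0.245 - 17.585 * Age^(-0.0171) + 18.530` for
#'   Age <= 1182 d, 1 beyond; evaluated at max(Age, 1 day).  This ratio
#'   exceeds 1 around one month of age.
#'
#' @param sc_model which SC thickness model to use (2, the default, or 1).
#' @return Named list of [maturation_model()] objects with elements
#'   `sc_thickness`, `ed_thickness`, `de_thickness`, `sc_hydration`.
#' @export
default_maturation_models <- function(sc_model = 2) {
  sc <- if (sc_model == 2) {
    maturation_model("sc_thickness", "polynomial",
                     c(a = 2.662e-7, n = 1.878, c = 0.724),
                     cap_age_days = 1604)
  } else {
    maturation_model("sc_thickness", "polynomial",
                     c(a = 2.401e-7, n = 2.000, b = -99.43, m = 2.071e-3,
                       c = 101.4),
                     cap_age_days = 1510, min_age_days = 1)
  }
  list(
    sc_thickness = sc,
    ed_thickness = maturation_model("ed_thickness", "hill",
                                    c(a = 1 - 0.634, b = 18.702, c = 0.634,
                                      n = 5.363)),
    de_thickness = maturation_model("de_thickness", "sigmoid",
                                    c(a = 1.5 - 0.407, b = 8974, c = 0.407),
                                    cap_age_days = 9883),
    sc_hydration = maturation_model("sc_hydration", "polynomial",
                                    c(a = -0.344, n = 0.245, b = -17.585,
                                      m = -0.0171, c = 18.530),
                                    cap_age_days = 1182, min_age_days = 1)
  )
}

#' Age-dependent skin parameters
#'
#' Scales the adult reference skin parameters by the maturation ratios at a
#' given postnatal age.
#'
#' @param reference an [adult_reference()].
#' @param models named list of [maturation_model()]s covering all four
#'   parameter ids (as from [default_maturation_models()]).
#' @param age_days postnatal age in days.
#' @return An object of class `"age_parameters"`: `age_days`, `h_sc_um`,
#'   `h_ed_um`, `h_de_um`, `hydration_ratio`.
#' @export
pediatric_parameters <- function(reference, models, age_days) {
  missing <- setdiff(MATURATION_PARAMS, names(models))
  if (length(missing))
    stopf("missing maturation model(s): %s", paste(missing, collapse = ", "))
  structure(list(
    age_days = age_days,
    h_sc_um = reference$h_sc_hydrated_um *
      maturation_ratio(models$sc_thickness, age_days),
    h_ed_um = reference$h_ed_um *
      maturation_ratio(models$ed_thickness, age_days),
    h_de_um = reference$h_de_um *
      maturation_ratio(models$de_thickness, age_days),
    hydration_ratio = reference$hydration_ref *
      maturation_ratio(models$sc_hydration, age_days)
  ), class = "age_parameters")
}

ADULT_AGE_DAYS <- 30 * 365.25
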