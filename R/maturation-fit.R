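# Fitting candidate maturation forms to child:adult ratio data and
# selecting among them by leave-one-out cross-validation.

form_par_names <- function(form) {
  switch(form,
         sigmoid = c("a", "b", "c"),
         hill = c("a", "b", "c", "n"),
         polynomial = c("a", "n", "b", "m", "c"),
         stopf("unknown form '%s'", form))
}

# Random starting values from broad boxes: b (age scale) log-uniform on
# [1, 1e4] days, c in [0, 2], exponents in [0.01, 8], amplitudes a (and the
# polynomial b) uniform on [-100, 100] for the saturating forms and
# sign-symmetric log-uniform magnitude in [1e-9, 1] for power-law terms.
random_start <- function(form) {
  lunif <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  switch(form,
    sigmoid = c(a = stats::runif(1, -100, 100), b = lunif(1, 1e4),
                c = stats::runif(1, 0, 2)),
    hill = c(a = stats::runif(1, -100, 100), b = lunif(1, 1e4),
             c = stats::runif(1, 0, 2), n = stats::runif(1, 0.01, 8)),
    polynomial = c(a = sample(c(-1, 1), 1) * lunif(1e-9, 1),
                   n = stats::runif(1, 0.01, 8),
                   b = sample(c(-1, 1), 1) * lunif(1e-9, 1),
                   m = stats::runif(1, 0.01, 8),
                   c = stats::runif(1, 0, 2)))
}

validate_ratio_data <- function(data) {
  if (!all(c("age_days", "ratio") %in% names(data)))
    stopf("ratio data needs columns age_days and ratio")
  if (any(data$age_days < 0)) stopf("age_days must be non-negative")
  if (any(data$ratio <= 0)) stopf("ratios must be positive")
  data
}

#' Fit one maturation functional form
#'
#' Unweighted nonlinear least squares of a candidate maturation form to
#' child:adult ratio data on the ratio scale, with multi-start
#' Levenberg-Marquardt optimisation from broad random boxes.
#'
#' @param data data frame with columns `age_days` and `ratio` (and optionally
#'   `source_label`).
#' @param form one of `"sigmoid"`, `"hill"`, `"polynomial"`.
#' @param starts number of random starting points (default 20).
#' @param seed integer seed for the random starts.
#' @return An object of class `"maturation_fit"`: `form`, `coefficients`,
#'   `rss`, `converged`, `n`, plus the data used.
#' @export
fit_maturation <- function(data, form = c("sigmoid", "hill", "polynomial"),
                           starts = 20, seed = 1) {
  form <- match.arg(form)
  data <- validate_ratio_data(data)
  npar <- length(form_par_names(form))
  if (nrow(data) < npar + 1)
    stopf("need at least %d records to fit the %s form", npar + 1, form)

  resid_fn <- function(p) {
    r <- eval_maturation_form(form, p, data$age_days) - data$ratio
    r[!is.finite(r)] <- 1e6
    r
  }

  best <- NULL
  with_seed(seed, {
    for (s in seq_len(starts)) {
      p0 <- random_start(form)
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = p0, fn = resid_fn,
          control = minpack.lm::nls.lm.control(maxiter = 200))),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (!is.finite(rss) || any(!is.finite(unlist(fit$par)))) next
      if (is.null(best) || rss < best$rss)
        best <- list(par = unlist(fit$par), rss = rss)
    }
  })

  if (is.null(best)) {
    return(structure(list(form = form, coefficients = NULL, rss = Inf,
                          converged = FALSE, n = nrow(data), data = data,
                          starts = starts, seed = seed),
                     class = "maturation_fit"))
  }
  structure(list(form = form, coefficients = best$par, rss = best$rss,
                 converged = TRUE, n = nrow(data), data = data,
                 starts = starts, seed = seed),
            class = "maturation_fit")
}

#' @export
coef.maturation_fit <- function(object, ...) object$coefficients

#' @export
predict.maturation_fit <- function(object, age_days = NULL, ...) {
  if (!object$converged) stopf("fit did not converge")
  if (is.null(age_days)) age_days <- object$data$age_days
  eval_maturation_form(object$form, object$coefficients, age_days)
}

#' @export
residuals.maturation_fit <- function(object, ...) {
  predict(object) - object$data$ratio
}

#' @export
print.maturation_fit <- function(x, ...) {
  cat(sprintf("<maturation_fit> %s form, n = %d, RSS = %.4g%s\n", x$form,
              x$n, x$rss, if (x$converged) "" else " (NOT converged)"))
  if (x$converged)
    cat("  coefficients:",
        paste(names(x$coefficients), signif(x$coefficients, 4),
              sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.maturation_fit <- function(object, ...) {
  out <- list(form = object$form, coefficients = object$coefficients,
              rss = object$rss, n = object$n,
              sigma = sqrt(object$rss / max(object$n -
                length(object$coefficients), 1)),
              converged = object$converged)
  class(out) <- "summary.maturation_fit"
  out
}

#' @export
print.summary.maturation_fit <- function(x, ...) {
  cat(sprintf("Maturation fit (%s), n = %d\n", x$form, x$n))
  cat(sprintf("  RSS %.4g, residual sd %.4g\n", x$rss, x$sigma))
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' @export
plot.maturation_fit <- function(x, ...) {
  graphics::plot(x$data$age_days, x$data$ratio, xlab = "postnatal age (days)",
                 ylab = "child:adult ratio", log = "x", ...)
  ages <- exp(seq(log(max(min(x$data$age_days), 0.5)),
                  log(max(x$data$age_days)), length.out = 200))
  graphics::lines(ages, predict(x, ages), col = 2)
  invisible(x)
}

#' Leave-one-out cross-validation error
#'
#' For each record, fits the form on the remaining n-1 records and predicts
#' the held-out ratio; returns the mean squared prediction error over the
#' folds.  Folds whose fit fails to converge are excluded and counted.
#'
#' @inheritParams fit_maturation
#' @param starts random starts per fold.
#' @return A list: `mse`, `n_folds`, `n_failed`, per-fold squared errors.
#' @export
loocv_maturation <- function(data, form, starts = 20, seed = 1) {
  data <- validate_ratio_data(data)
  npar <- length(form_par_names(form))
  if (nrow(data) < npar + 2)
    stopf("LOOCV needs at least %d records for the %s form", npar + 2, form)
  errs <- rep(NA_real_, nrow(data))
  for (i in seq_len(nrow(data))) {
    fit <- fit_maturation(data[-i, , drop = FALSE], form, starts = starts,
                          seed = seed + i)
    if (!fit$converged) next
    errs[i] <- (predict(fit, data$age_days[i]) - data$ratio[i])^2
  }
  ok <- !is.na(errs)
  if (!any(ok)) stopf("no LOOCV fold converged for the %s form", form)
  list(mse = mean(errs[ok]), n_folds = sum(ok), n_failed = sum(!ok),
       fold_errors = errs)
}

#' Select a maturation model by LOOCV
#'
#' Fits each candidate form, scores it by leave-one-out cross-validation, and
#' returns the winner (lowest LOOCV mean squared error; ties broken by fewer
#' parameters, then by lower RSS) together with a capped
#' [maturation_model()].  The cap age is the age at which the fitted curve
#' first reaches 1, found by root solving; if the curve never reaches 1 the
#' model is uncapped.
#'
#' @inheritParams fit_maturation
#' @param forms candidate forms (at least one).
#' @param parameter_id parameter id recorded in the returned model.
#' @return A list of class `"maturation_selection"`: `fit` (the winning
#'   `maturation_fit`), `model` (the capped `maturation_model`), `loocv`
#'   (named vector of LOOCV errors), `form`.
#' @export
select_maturation_model <- function(data,
                                    forms = c("sigmoid", "hill", "polynomial"),
                                    parameter_id = "sc_thickness",
                                    starts = 20, seed = 1) {
  if (length(forms) < 1) stopf("need at least one candidate form")
  data <- validate_ratio_data(data)
  scores <- rep(Inf, length(forms)); names(scores) <- forms
  fits <- vector("list", length(forms)); names(fits) <- forms
  for (f in forms) {
    fits[[f]] <- fit_maturation(data, f, starts = starts, seed = seed)
    if (!fits[[f]]$converged) next
    scores[f] <- tryCatch(
      loocv_maturation(data, f, starts = starts, seed = seed)$mse,
      error = function(e) Inf)
  }
  if (all(!is.finite(scores))) stopf("all candidate forms failed")
  npar <- vapply(forms, function(f) length(form_par_names(f)), numeric(1))
  rss <- vapply(fits, function(f) if (f$converged) f$rss else Inf, numeric(1))
  ord <- order(scores, npar, rss)
  win <- forms[ord[1]]
  fit <- fits[[win]]
  cap <- find_cap_age(fit)
  model <- maturation_model(parameter_id, win, fit$coefficients,
                            cap_age_days = cap)
  structure(list(fit = fit, model = model, loocv = scores, form = win),
            class = "maturation_selection")
}

# First age (days) at which the fitted curve reaches 1, or Inf.
find_cap_age <- function(fit, max_age = 30 * 365.25) {
  f <- function(a) predict(fit, a) - 1
  ages <- exp(seq(log(1e-3), log(max_age), length.out = 400))
  v <- f(ages)
  idx <- which(v >= 0)
  if (!length(idx)) return(Inf)
  i <- idx[1]
  if (i == 1) return(ages[1])
  stats::uniroot(f, c(ages[i - 1], ages[i]), tol = 1e-6)$root
}

#' @export
print.maturation_selection <- function(x, ...) {
  cat("<maturation_selection>\n  LOOCV MSE:",
      paste(names(x$loocv), signif(x$loocv, 4), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  selected: %s (cap %s d)\n", x$form,
              if (is.finite(x$model$cap_age_days))
                format(x$model$cap_age_days, digits = 4) else "none"))
  invisible(x)
}
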