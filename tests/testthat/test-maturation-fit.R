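# Nonlinear fitting of maturation forms and LOOCV model selection.

test_that("noiseless model-generated data is recovered exactly", {
  ages <- exp(seq(log(1), log(2000), length.out = 30))

  sig <- maturation_model("de_thickness", "sigmoid",
                          c(a = 1.093, b = 8974, c = 0.407))
  d <- generate_synthetic_ratios(sig, ages, noise_sd = 0, seed = 1)
  f <- fit_maturation(d, "sigmoid", starts = 20, seed = 3)
  expect_true(f$converged)
  expect_lt(f$rss, 1e-10)
  expect_equal(coef(f)[c("a", "b", "c")],
               c(a = 1.093, b = 8974, c = 0.407), tolerance = 0.01)

  hill <- default_maturation_models()$ed_thickness
  dh <- generate_synthetic_ratios(hill, ages, noise_sd = 0, seed = 1)
  fh <- fit_maturation(dh, "hill", starts = 20, seed = 3)
  expect_lt(fh$rss, 1e-8)
  expect_equal(unname(coef(fh)["n"]), 5.363, tolerance = 0.01)
})

test_that("flat data yields a flat fitted curve", {
  ages <- seq(1, 1000, length.out = 20)
  d <- data.frame(age_days = ages, ratio = rep(1, 20))
  f <- fit_maturation(d, "sigmoid", starts = 20, seed = 2)
  expect_true(all(abs(predict(f, c(2, 50, 800)) - 1) < 1e-4))
})

test_that("fitting is invariant to record order and dataset duplication", {
  hill <- default_maturation_models()$ed_thickness
  ages <- seq(2, 80, length.out = 40)
  d <- generate_synthetic_ratios(hill, ages, noise_sd = 0.05, seed = 6)
  f1 <- fit_maturation(d, "hill", starts = 20, seed = 3)
  f2 <- fit_maturation(d[rev(seq_len(nrow(d))), ], "hill", starts = 20,
                       seed = 3)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
  f3 <- fit_maturation(rbind(d, d), "hill", starts = 20, seed = 3)
  expect_equal(coef(f1), coef(f3), tolerance = 1e-3)
})

test_that("Hill parameter recovery from noisy data is unbiased within 15%", {
  # parameter-recovery simulation at the epidermis curve: sigma = 0.05,
  # 40 ages spanning the maturation transition, 20 replicate datasets;
  # the median recovered (b, c, n) must land within 15% of truth
  hill <- default_maturation_models()$ed_thickness
  truth <- c(b = 18.702, c = 0.634, n = 5.363)
  ages <- seq(2, 80, length.out = 40)
  cc <- t(vapply(1:20, function(s) {
    d <- generate_synthetic_ratios(hill, ages, noise_sd = 0.05, seed = s)
    coef(fit_maturation(d, "hill", starts = 30, seed = 3))[names(truth)]
  }, truth))
  med <- apply(cc, 2, stats::median)
  expect_true(all(abs(med - truth) / truth < 0.15))
})

test_that("LOOCV behaves on clean data and enforces its preconditions", {
  hill <- default_maturation_models()$ed_thickness
  ages <- exp(seq(log(1), log(1000), length.out = 15))
  d0 <- generate_synthetic_ratios(hill, ages, noise_sd = 0, seed = 1)
  cv <- loocv_maturation(d0, "hill", starts = 10, seed = 2)
  expect_lt(cv$mse, 1e-6)
  expect_equal(cv$n_folds + cv$n_failed, 15)

  # n = parameter count + 1 is too small
  expect_error(loocv_maturation(d0[1:5, ], "hill", starts = 5, seed = 1),
               "at least")
})

test_that("LOOCV error approaches the noise variance at large n", {
  hill <- default_maturation_models()$ed_thickness
  ages <- seq(1, 2000, length.out = 200)
  d <- generate_synthetic_ratios(hill, ages, noise_sd = 0.05, seed = 8)
  cv <- loocv_maturation(d, "hill", starts = 6, seed = 2)
  expect_equal(cv$mse, 0.05^2, tolerance = 0.25)
})

test_that("select_maturation_model picks the generating form and caps it", {
  hill <- default_maturation_models()$ed_thickness
  ages <- exp(seq(log(1), log(1000), length.out = 15))
  d <- generate_synthetic_ratios(hill, ages, noise_sd = 0.02, seed = 5)
  sel <- select_maturation_model(d, c("sigmoid", "hill"), starts = 10,
                                 seed = 2)
  expect_equal(sel$form, "hill")
  expect_s3_class(sel$model, "maturation_model")

  # single candidate: returned as-is
  sel1 <- select_maturation_model(d, "hill", starts = 10, seed = 2)
  expect_equal(sel1$form, "hill")

  # packaged SC model 2 coefficients: the curve crosses 1 near the printed
  # cap age (~1604 days to 3 significant figures)
  scfit <- structure(list(form = "polynomial",
                          coefficients = c(a = 2.662e-7, n = 1.878,
                                           c = 0.724),
                          converged = TRUE),
                     class = "maturation_fit")
  cap <- pedperm:::find_cap_age(scfit)
  expect_equal(signif(cap, 3), 1600)
  expect_lt(abs(cap - 1604) / 1604, 0.02)
})
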