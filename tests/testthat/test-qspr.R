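# QSPR closures: nominal correlations, ionization, layer coefficients.

test_that("nominal QSPR correlations evaluate and stay affine", {
  # frozen values from direct evaluation of the printed correlations
  expect_equal(log10_ktrans_nominal(0), -0.570)
  expect_equal(log10_ktrans_nominal(232.2), -5.732975, tolerance = 1e-5)
  expect_equal(log10_ktrans_nominal(467.6), -7.089848, tolerance = 1e-5)
  expect_equal(log10_pc_pro_w_nominal(0), log10(5.4))
  expect_equal(log10_pc_pro_w_nominal(1.47), 1.129294, tolerance = 1e-5)
  expect_equal(log10_pc_pro_w_nominal(4), 1.812394, tolerance = 1e-5)
  expect_equal(log10_k_lip_w_nominal(0), log10(0.43))
  expect_equal(log10_k_lip_w_nominal(1.5), 0.848469, tolerance = 1e-5)
  expect_equal(log10_k_lip_w_nominal(4), 2.873468, tolerance = 1e-5)

  # slopes recovered by finite differencing at two points
  slope <- function(f, x1, x2) (f(x2) - f(x1)) / (x2 - x1)
  expect_equal(slope(log10_pc_pro_w_nominal, -1, 3), 0.27)
  expect_equal(slope(log10_k_lip_w_nominal, 0.5, 2.5), 0.81)
  # ktrans is affine in MW^(1/3)
  expect_equal(slope(function(z) log10_ktrans_nominal(z^3), 2, 6), -0.840)

  expect_error(log10_ktrans_nominal(-1), "non-negative")
})

test_that("fraction_nonionized follows Henderson-Hasselbalch", {
  expect_equal(fraction_nonionized(7.3, 7.3, "acidic"), 0.5)
  expect_equal(fraction_nonionized(4, 7.3, "acidic"), 0.99950, tolerance = 1e-4)
  expect_equal(fraction_nonionized(4, 8.65, "basic"), 2.2387e-5,
               tolerance = 1e-4)
  expect_equal(fraction_nonionized(NA, 8, "basic"), 1)
  expect_equal(fraction_nonionized(3, 9, "neutral"), 1)

  # bounded in [0, 1] and acid/base symmetric under pH - pKa reflection
  for (dph in seq(-6, 6, by = 0.75)) {
    fa <- fraction_nonionized(7 + dph, 7, "acidic")
    fb <- fraction_nonionized(7 - dph, 7, "basic")
    expect_gte(fa, 0); expect_lte(fa, 1)
    expect_equal(fa, fb)
  }
})

test_that("qspr_set enforces the printed uncertainty ranges", {
  cmp <- compound("x", 232.2, 1.47, pka = 7.3, ionization_class = "acidic",
                  sol_water_mg_L = 1110)
  nom <- qspr_bounds(cmp)
  expect_equal(nom$upper - nom$nominal,
               c(log10_ktrans = 1.26, log10_pc_pro_w = 0.32,
                 log10_k_lip_w = 0.434))
  # inside the box: accepted
  q <- qspr_set(cmp, log10_ktrans = nom$nominal[[1]] + 1.2,
                provenance = "fitted")
  expect_s3_class(q, "qspr_set")
  # outside: rejected
  expect_error(qspr_set(cmp, log10_ktrans = nom$nominal[[1]] + 1.3,
                        provenance = "fitted"), "uncertainty ranges")
})

test_that("layer_coefficients matches the hand-computed SC closure", {
  cfg <- model_config()
  ref <- adult_reference()
  cmp <- compound("phenobarbital", 232.2, 1.47, pka = 7.3,
                  ionization_class = "acidic", sol_water_mg_L = 1110)
  q <- qspr_set(cmp)
  phys <- pediatric_parameters(ref, default_maturation_models(),
                               ADULT_AGE_DAYS_T)
  co <- layer_coefficients(cmp, q, phys, cfg, ref, vehicle_ph = NA)

  # spreadsheet evaluation of the weighted phase sum (f_ni = 1, hydration 1)
  k_expected <- 0.60 * 1 + 0.325 * 10^(0.27 * 1.47 + log10(5.4)) +
    0.075 * 10^(0.81 * 1.47 + log10(0.43))
  expect_equal(co$k_sc_w, k_expected, tolerance = 1e-6)

  # D_sc is linear in ktrans (10x ktrans -> 10x d_sc)
  q10 <- qspr_set(cmp, log10_ktrans = log10_ktrans_nominal(232.2) + 1,
                  provenance = "fitted")
  co10 <- layer_coefficients(cmp, q10, phys, cfg, ref, vehicle_ph = NA)
  expect_equal(co10$d_sc / co$d_sc, 10, tolerance = 1e-9)

  # pure-water SC: k_sc_w = 1
  cfg_w <- model_config(phi_w = 1, phi_pro = 1e-12, phi_lip = 1e-12)
  co_w <- layer_coefficients(cmp, q, phys, cfg_w, ref, vehicle_ph = NA)
  expect_equal(co_w$k_sc_w, 1, tolerance = 1e-6)

  # monotone non-decreasing in each uncertain parameter
  for (p in c("log10_ktrans", "log10_k_lip_w", "log10_pc_pro_w")) {
    args <- list(cmp); args[[p]] <- qspr_bounds(cmp)$nominal[[p]] + 0.3
    args$provenance <- "fitted"
    qq <- do.call(qspr_set, args)
    cc <- layer_coefficients(cmp, qq, phys, cfg, ref, vehicle_ph = NA)
    if (p == "log10_ktrans") expect_gt(cc$d_sc, co$d_sc)
    if (p == "log10_k_lip_w") expect_gt(cc$k_sc_w, co$k_sc_w)
    if (p == "log10_pc_pro_w") expect_gt(cc$k_sc_w, co$k_sc_w)
  }

  # all outputs positive and finite
  expect_true(all(unlist(unclass(co)) > 0))
})
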