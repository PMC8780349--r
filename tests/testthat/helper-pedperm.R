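# Shared test helpers: small model builders and an independent spectral
# reference solution for the linear multilayer diffusion problem.

test_compounds <- function() fixture_compounds()

# A toy three-layer configuration with comparable layer diffusivities
# (non-stiff), used for oracle comparisons.
toy_coeffs <- function(d = c(2e-4, 1e-3, 1e-3), k = c(3, 0.8, 0.8)) {
  structure(list(d_sc = d[1], d_ed = d[2], d_de = d[3],
                 k_sc_w = k[1], k_ed_w = k[2], k_de_w = k[3]),
            class = "layer_coefficients")
}

toy_params <- function(h_sc = 30, h_ed = 50, h_de = 100) {
  structure(list(age_days = ADULT_AGE_DAYS_T, h_sc_um = h_sc, h_ed_um = h_ed,
                 h_de_um = h_de, hydration_ratio = 1),
            class = "age_parameters")
}

ADULT_AGE_DAYS_T <- 30 * 365.25

# Independent reference for the saturated-donor multilayer problem, solved
# by eigendecomposition of the semi-discrete linear system (spectral
# solution, no time stepping).  Returns receptor accumulation Q(T) and
# terminal flux J(T) on a fine grid.
spectral_reference <- function(h_um, D, K, donor_activity, T_h,
                               cells_per_layer = 60) {
  h <- h_um / 1e4
  n <- rep(cells_per_layer, 3)
  dx <- rep(h / n, times = n)
  Dv <- rep(D, times = n)
  Kv <- rep(K, times = n)
  N <- length(dx)
  # resistance of each half-cell in activity variables
  r <- (dx / 2) / (Dv * Kv)
  g <- c(1 / r[1],                       # donor interface (well-mixed donor)
         1 / (r[-N] + r[-1]),            # internal interfaces
         1 / r[N])                       # sink interface
  wk <- dx * Kv                          # converts cell amount to activity
  # d u_i/dt = g_i (a_{i-1} - a_i) - g_{i+1} (a_i - a_{i+1}), a_0 = donor
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    A[i, i] <- -(g[i] + g[i + 1]) / wk[i]
    if (i > 1) A[i, i - 1] <- g[i] / wk[i - 1]
    if (i < N) A[i, i + 1] <- g[i + 1] / wk[i + 1]
  }
  b <- c(g[1] * donor_activity, rep(0, N - 1))
  eg <- eigen(A)
  V <- eg$vectors; lam <- eg$values
  Vinvb <- solve(V, b)
  u_ss <- -V %*% (Vinvb / lam)                 # steady state
  z0 <- solve(V, -u_ss)                        # u(0) = 0
  u_T <- Re(V %*% (z0 * exp(lam * T_h))) + Re(u_ss)
  J_T <- g[N + 1] * u_T[N] / wk[N]
  # Q(T) = g_bot/wk_N * int_0^T u_N dt, integrated mode-wise
  int_u <- Re(V %*% (z0 * (exp(lam * T_h) - 1) / lam)) + Re(u_ss) * T_h
  Q_T <- g[N + 1] * int_u[N] / wk[N]
  list(J = as.numeric(J_T), Q = as.numeric(Q_T))
}

# Convenience: scenario + fit for one packaged compound row.
fit_packaged_compound <- function(name, starts = 10, seed = 42, ...) {
  atab <- load_fixture("adult_ivpt")
  row <- atab[atab$compound == name, ]
  cmp <- test_compounds()[[name]]
  cfg <- model_config()
  scen <- pedperm_scenario(cmp, row, cfg)
  fit_adult(cmp, scen, row$observed_flux_ug_cm2_h, row$observed_Q_ug_cm2,
            config = cfg, starts = starts, seed = seed, ...)
}

pedperm_scenario <- function(cmp, row, cfg) {
  sol <- if (!is.na(cmp$sol_vehicle_mg_mL) && !grepl("buffer", row$solvent))
    cmp$sol_vehicle_mg_mL * 1000 else cmp$sol_water_mg_L
  exposure_scenario(row$dose_ug_cm2, row$duration_h,
                    vehicle_ph = row$vehicle_ph,
                    solubility_vehicle_ug_cm3 = sol,
                    vehicle_thickness_um = cfg$vehicle_thickness_um)
}
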