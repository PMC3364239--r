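test_that("uncorrelated Poisson streams give G consistent with zero", {
  set.seed(50)
  s <- poisson_stream(15000, 15000, 4)
  curve <- multitau_correlate(s, base_lag_s = 1e-5)
  expect_true(all(abs(curve$G) < 4 * curve$G_se + 1e-12))
})

test_that("a single photon pair produces a delta correlation at its lag", {
  ins <- quiet_instrument()
  dt_pair <- 6e-3   # sits on the level-0 lag grid
  s <- make_stream(c(0.1, 0.1 + dt_pair), c(0L, 1L), 1, instrument = ins)
  grid <- multitau_lag_grid(1, base_lag_s = 1e-3, points_per_octave = 4)
  curve <- direct_correlate(s, "parallel", "perpendicular", grid,
                            base_lag_s = 1e-3)
  peak <- which.max(curve$G)
  expect_equal(curve$lags_s[peak], 6e-3, tolerance = 1e-9)
})

test_that("multi-tau equals the brute-force direct correlator bit-for-bit", {
  set.seed(51)
  for (i in 1:6) {
    dur <- runif(1, 0.5, 2)
    s <- poisson_stream(runif(1, 500, 4000), runif(1, 500, 4000), dur)
    mt <- multitau_correlate(s, base_lag_s = 1e-3, points_per_octave = 4,
                             n_segments = 1)
    dc <- direct_correlate(s, "parallel", "perpendicular", mt)
    expect_equal(length(mt$G), length(dc$G))
    expect_lt(max(abs(mt$G - dc$G)), 1e-10)
  }
})

test_that("cross-correlation is symmetric in channel order", {
  sim <- diffusing_sim(seed = 52, mean_N = 2, per_fluor = 3e4, D = 30,
                       duration_s = 0.9)
  ab <- multitau_correlate(sim$stream, "parallel", "perpendicular")
  ba <- multitau_correlate(sim$stream, "perpendicular", "parallel")
  fa <- fit_diffusion_model(ab, 0.35, 0.15)
  fb <- fit_diffusion_model(ba, 0.35, 0.15)
  pooled <- sqrt(fa$se["tau_D_s"]^2 + fb$se["tau_D_s"]^2)
  expect_lt(abs(fa$tau_D_s - fb$tau_D_s), 4 * pooled)
  expect_equal(fa$N_mean, fb$N_mean, tolerance = 0.1)
})

test_that("diffusion fit recovers exact model parameters to 6 figures", {
  curve <- model_curve(N = 65, tau_D_s = 345e-6, ratio = 0.15)
  fit <- fit_diffusion_model(curve, 0.35, 0.15)
  expect_equal(fit$N_mean, 65, tolerance = 1e-6)
  expect_equal(fit$tau_D_s, 345e-6, tolerance = 1e-6)
  expect_equal(fit$baseline, 0, tolerance = 1e-8)
  # freeing the ratio still recovers it
  fit2 <- fit_diffusion_model(curve, 0.35, omega_z_ratio = NULL)
  expect_equal(fit2$omega_z_ratio, 0.15, tolerance = 1e-4)
  expect_equal(fit2$tau_D_s, 345e-6, tolerance = 1e-5)
  # scaling property: doubling N halves the amplitude at unchanged tau_D
  fit3 <- fit_diffusion_model(model_curve(130, 345e-6, 0.15), 0.35, 0.15)
  expect_equal(fit3$G0_model / fit$G0_model, 0.5, tolerance = 1e-6)
  expect_equal(fit3$tau_D_s, fit$tau_D_s, tolerance = 1e-6)
})

test_that("fixing vs freeing the waist ratio leaves tau_D indistinguishable", {
  set.seed(53)
  curve <- model_curve(10, 3e-4, 0.15, noise_sd = 2e-5, se = 2e-5)
  f_fix <- fit_diffusion_model(curve, 0.35, 0.15)
  f_free <- fit_diffusion_model(curve, 0.35, NULL)
  pooled <- sqrt(f_fix$se["tau_D_s"]^2 + f_free$se["tau_D_s"]^2)
  expect_lt(abs(f_fix$tau_D_s - f_free$tau_D_s), 3 * pooled + 1e-9)
})

test_that("global dilution fit shares the ratio and scales N per curve", {
  curves <- lapply(c(65, 130, 260, 520), function(N)
    model_curve(N, 74.8e-6, 0.15))
  fit <- global_fit_dilution_series(curves)
  expect_equal(fit$omega_z_ratio, 0.15, tolerance = 1e-5)
  expect_equal(fit$tau_D_s, 74.8e-6, tolerance = 1e-6)
  expect_equal(fit$N_mean, c(65, 130, 260, 520), tolerance = 1e-5)
  # live-cell-power variant with a different true ratio
  fit2 <- global_fit_dilution_series(lapply(c(20, 60, 200), function(N)
    model_curve(N, 299e-6, 0.10)))
  expect_equal(fit2$omega_z_ratio, 0.10, tolerance = 1e-4)
  expect_error(global_fit_dilution_series(curves[1:2]), "3")
})

test_that("correlator input validation", {
  s <- make_stream(c(0.1, 0.2), c(0L, 0L), 1)
  expect_error(multitau_correlate(s), "empty channel")
  expect_error(multitau_correlate(poisson_stream(100, 100, 0.05),
                                  base_lag_s = 1e-3),
               "duration too short")
  big <- poisson_stream(6e4, 6e4, 1)
  expect_error(direct_correlate(big, lag_grid = multitau_lag_grid(1, 1e-3),
                                base_lag_s = 1e-3), "brute-force")
})

test_that("correlation amplitude law: fitted N tracks the true occupancy", {
  # gamma / G(0) recovers <N> across a grid of occupancies
  for (cfg in list(list(N = 1, b = 5e4, seed = 55),
                   list(N = 5, b = 1.6e4, seed = 56),
                   list(N = 20, b = 4e3, seed = 57))) {
    sim <- diffusing_sim(seed = cfg$seed, mean_N = cfg$N, per_fluor = cfg$b,
                         D = 30, duration_s = 1.2)
    fit <- fit_diffusion_model(multitau_correlate(sim$stream), 0.35, 0.15)
    tr <- sim$truth$species[[1]]
    expect_lt(abs(fit$N_mean - tr$realized_N),
              max(3 * fit$se["N_mean"], 0.12 * tr$realized_N))
  }
})

test_that("simulated dilution series recovers the dilution scaling", {
  # fast-dye conditions: the axial knee (~44 tau_D) must sit well inside the
  # usable lag range or omega/z carries no information at all. Even then the
  # ratio stays weakly identified at desk-scale photon budgets (a gentle
  # square-root factor competing with tau_D and the baseline), so it is
  # checked for statistical consistency and order of magnitude; the
  # estimator's correctness given informative data is pinned by the
  # exact-model tests above.
  sims <- lapply(seq_along(c(0.25, 0.5, 1)), function(i)
    diffusing_sim(seed = 210 + i, mean_N = c(0.25, 0.5, 1)[i],
                  per_fluor = 7e4, D = 300, duration_s = 0.8,
                  theta_rot_ns = 0.15, lifetime_ns = 4))
  curves <- lapply(sims, function(s) multitau_correlate(s$stream))
  fit <- global_fit_dilution_series(curves)
  expect_gt(fit$omega_z_ratio, 0.04)
  expect_lt(fit$omega_z_ratio, 0.5)
  expect_lt(abs(fit$omega_z_ratio - 0.15),
            max(3 * fit$se[["omega_z_ratio"]], 0.5 * 0.15))
  truth_N <- vapply(sims, function(s) s$truth$species[[1]]$realized_N, 1.0)
  # recovered N proportional to the nominal dilution
  ratios <- fit$N_mean / truth_N
  expect_lt(max(abs(ratios / mean(ratios) - 1)), 0.10)
  expect_lt(abs(mean(ratios) - 1), 0.10)
})
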