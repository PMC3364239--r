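test_that("anisotropy decay model has the right structure and limits", {
  mono <- species_spec(1, n_fluor = 1, theta_rot_ns = 15.3)
  r <- anisotropy_decay_model(mono)
  t <- seq(0, 12, 0.1)
  expect_equal(r(t), 0.4 * exp(-t / 15.3))

  # dimer with full transfer depolarization: plateau at r0/2 before rotation
  dim_fast <- species_spec(1, n_fluor = 2, phi_fret_ns = 0.05)
  rd <- anisotropy_decay_model(dim_fast)
  # at t where FRET has equilibrated but rotation has barely begun
  expect_equal(rd(0.5) / (0.4 * exp(-0.5 / 16.4)), 0.5, tolerance = 1e-4)

  # phi -> Inf reduces to the monomer curve for any n
  hex_slow <- species_spec(1, n_fluor = 6, phi_fret_ns = 1e12,
                           theta_rot_ns = 15.3)
  expect_equal(anisotropy_decay_model(hex_slow)(t), r(t), tolerance = 1e-9)

  # r_et_ratio raises the plateau: L = (1 + (n-1) c)/n
  tri <- species_spec(1, n_fluor = 3, r_et_ratio = 0.25)
  expect_equal(attr(anisotropy_decay_model(tri), "plateau"), 1.5 / 3)
})

test_that("sample_micro_time matches the folded-exponential law", {
  set.seed(20)
  x <- sample_micro_time(2e5, 3.1, 12.5)
  expect_true(all(x >= 0 & x < 12.5))
  # oracle: closed-form folded mean (tau - (tau+T) q)/(1 - q), q = exp(-T/tau)
  q <- exp(-12.5 / 3.1)
  folded_mean <- (3.1 - (3.1 + 12.5) * q) / (1 - q)
  expect_equal(folded_mean, 2.87432, tolerance = 1e-5)
  expect_lt(abs(mean(x) - folded_mean), 3 * sd(x) / sqrt(length(x)))
  # KS against the folded-exponential CDF
  cdf <- function(v) (1 - exp(-v / 3.1)) / (1 - q)
  ks <- suppressWarnings(ks.test(x, cdf))
  expect_gt(ks$p.value, 0.01)
  # degenerate limit
  expect_lt(max(sample_micro_time(100, 1e-9, 12.5)), 1e-6)
})

test_that("polarization assignment reproduces the stated odds", {
  expect_equal(polarization_prob(0, 1), 0.5)
  expect_equal(polarization_prob(0.4, 1), 1.8 / 2.4)
  expect_equal(polarization_prob(0.4, 2), 1.8 / (1.8 + 0.3))
  expect_error(polarization_prob(1.2, 1), "outside")
  set.seed(21)
  ch <- assign_polarization(rep(0, 2e4), function(t) rep(0.4, length(t)), 1)
  expect_lt(abs(mean(ch == 0) - 0.75), 3 * sqrt(0.75 * 0.25 / 2e4))
})

test_that("simulation is deterministic and validates its configuration", {
  a <- pinned_sim(seed = 5, brightness_total = 2e4, duration_s = 0.5)
  b <- pinned_sim(seed = 5, brightness_total = 2e4, duration_s = 0.5)
  expect_identical(a$stream$records, b$stream$records)

  sp <- species_spec(1, D_um2_s = 300)
  expect_error(
    simulation_config(sp, omega_nm = 424, duration_s = 1, dt_s = 1e-5),
    "too coarse")
  expect_warning(
    simulate_stream(simulation_config(
      species_spec(2, peak_brightness_per_fluor = 9e4, D_um2_s = 0),
      duration_s = 0.01, seed = 1)),
    "100,000 cps")
})

test_that("pinned complex photon count obeys the Poisson mean", {
  sim <- pinned_sim(seed = 9, brightness_total = 1e4, duration_s = 10)
  lambda <- sim$truth$species[[1]]$brightness_cpsm * 10
  expect_lt(abs(nrow(sim$stream$records) - lambda), 3 * sqrt(lambda))
})

test_that("ground truth records the Eq.-7-consistent correlation time", {
  sp <- species_spec(1, D_um2_s = 85)
  cfg <- simulation_config(sp, omega_nm = 424, duration_s = 0.02, seed = 2)
  sim <- simulate_stream(cfg)
  tr <- sim$truth$species[[1]]
  expect_equal(tr$tau_D_s, (0.424)^2 / (8 * 85), tolerance = 1e-12)
  expect_equal(diffusion_coefficient(tr$tau_D_s, 424), 85, tolerance = 1e-9)
})

test_that("lifetime decay is invariant under homo-FRET (n-mer vs monomer)", {
  mono <- pinned_sim(seed = 31, n_fluor = 1, brightness_total = 3e5,
                     duration_s = 1.5)
  pent <- pinned_sim(seed = 32, n_fluor = 5, brightness_total = 3e5,
                     duration_s = 1.5, phi_fret_ns = 0.7)
  f1 <- fit_exponential_decay(
    total_intensity_decay(micro_time_histogram(mono$stream, 0.1), 1), 1)
  f5 <- fit_exponential_decay(
    total_intensity_decay(micro_time_histogram(pent$stream, 0.1), 1), 1)
  expect_equal(f1$time_constants_ns, 3.1, tolerance = 0.03)
  expect_equal(f5$time_constants_ns, 3.1, tolerance = 0.03)
  expect_equal(f5$time_constants_ns / f1$time_constants_ns, 1, tolerance = 0.03)
})

test_that("dark-only simulation shows no cross-correlation", {
  ins <- instrument_config(dark_rate_par_cps = 2000, dark_rate_perp_cps = 2000)
  sim <- simulate_stream(simulation_config(list(), duration_s = 20,
                                           instrument = ins, seed = 13))
  curve <- multitau_correlate(sim$stream, base_lag_s = 1e-4)
  expect_true(all(abs(curve$G) < 4 * curve$G_se + 1e-12))
})

test_that("YAML round trip of a simulation configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "omega_nm: 424", "z0_nm: 2827", "duration_s: 0.5", "seed: 4",
    "instrument:", "  g_factor: 1.1", "  dark_rate_par_cps: 400",
    "species:",
    "- mean_N: 1.5", "  n_fluor: 3", "  peak_brightness_per_fluor: 5000",
    "  D_um2_s: 30"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$instrument$g_factor, 1.1)
  expect_equal(cfg$species[[1]]$n_fluor, 3L)
  expect_equal(cfg$dt_s, (0.424)^2 / (8 * 30) / 50)
})

test_that("fitted correlation times obey tau_D = omega^2/(8 D) across a grid", {
  grid <- list(list(D = 15, omega = 350), list(D = 40, omega = 350),
               list(D = 25, omega = 500))
  for (g in grid) {
    tds <- sapply(1:4, function(seed) {
      sim <- diffusing_sim(seed = 90 + seed * 7 + g$D, mean_N = 1.5,
                           per_fluor = 3e4, D = g$D, duration_s = 1.0,
                           omega_nm = g$omega)
      fit_diffusion_model(multitau_correlate(sim$stream), 0.35, 0.15)$tau_D_s
    })
    truth <- (g$omega / 1000)^2 / (8 * g$D)
    expect_lt(abs(mean(tds) - truth),
              max(3 * sd(tds) / sqrt(length(tds)), 0.1 * truth))
  }
})
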