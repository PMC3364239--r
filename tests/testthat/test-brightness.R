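test_that("brightness and normalized brightness arithmetic", {
  expect_equal(molecular_brightness(65000, 65), 1000)
  expect_equal(molecular_brightness(0, 10), 0)
  expect_error(molecular_brightness(100, 0), "positive")
  expect_equal(normalized_brightness(5000, 5000), 1)
  expect_error(normalized_brightness(5000, 500, power_complex_mw = 10.2,
                                     power_reference_mw = 6),
               "different powers")
  expect_warning(
    rho <- normalized_brightness(5000, 500, power_complex_mw = 10.2,
                                 power_reference_mw = 6, override = TRUE),
    "different powers")
  expect_equal(rho, 10)
})

test_that("beam geometry relations reproduce their closed forms and round trip", {
  # two-photon relation: tau_D = omega^2 / (8 D)
  expect_equal(beam_waist(300, 74.8e-6), 423.7, tolerance = 1e-3)
  expect_equal(diffusion_coefficient(345e-6, 424), 65.1, tolerance = 1e-3)
  # scaling: doubling tau_D halves D
  expect_equal(diffusion_coefficient(2 * 345e-6, 424),
               diffusion_coefficient(345e-6, 424) / 2)
  # round trips to machine precision
  for (om in c(300, 424, 500)) for (td in c(5e-5, 3.45e-4)) {
    expect_equal(beam_waist(diffusion_coefficient(td, om), td), om,
                 tolerance = 1e-12)
  }
  expect_equal(axial_from_ratio(424, 0.15), 424 / 0.15)
  g <- beam_geometry(424, omega_z_ratio = 0.15)
  expect_equal(g$z0_nm / 1000, 2.8, tolerance = 0.01)
  expect_equal(g$volume_fl, pi^1.5 * 0.424^2 * 2.8267 / 8, tolerance = 1e-4)
  expect_equal(observation_volume(367, 3700), 0.347, tolerance = 1e-2)
})

test_that("concentration and molecule count invert exactly", {
  expect_equal(molecules(0, 0.35), 0)
  for (c0 in c(1e-9, 5.7e-7, 1e-6, 1e-3)) {
    expect_equal(concentration(molecules(c0, 0.35), 0.35), c0,
                 tolerance = 1e-12)
  }
})

test_that("brightness calibration line fits, bands, exclusion", {
  # perfect line through the origin
  line <- fit_brightness_line(1:6, 1200 * (1:6))
  expect_equal(line$slope, 1200, tolerance = 1e-9)
  expect_equal(line$intercept, 0, tolerance = 1e-6)
  # perfect affine line on a subset
  line2 <- fit_brightness_line(2:6, 900 * (2:6) + 350)
  expect_equal(line2$slope, 900, tolerance = 1e-9)
  expect_equal(line2$intercept, 350, tolerance = 1e-6)
  # excluding an autofluorescence-elevated monomer point
  eta <- c(1000 * 1 + 400, 1000 * (2:6))    # V1 elevated
  line3 <- fit_brightness_line(1:6, eta, exclude = 1, by_n = TRUE)
  expect_equal(line3$slope, 1000, tolerance = 1e-9)
  resid_v1 <- eta[1] - (line3$intercept + line3$slope * 1)
  expect_gt(resid_v1, 0)
  expect_error(fit_brightness_line(1:2, c(1, 2), exclude = 1), "fewer than 2")

  # reading rho off the line (in-cell route)
  nb <- normalized_brightness_from_line(1000 * 12, line3)
  expect_equal(nb$rho, 12, tolerance = 1e-9)
  expect_equal(normalized_brightness_from_line(line3$slope + line3$intercept,
                                               line3)$rho, 1, tolerance = 1e-9)
  expect_equal(normalized_brightness_from_line(line3$intercept, line3)$rho, 0,
               tolerance = 1e-9)
  expect_warning(normalized_brightness_from_line(line3$intercept - 50, line3),
                 "negative rho")
})

test_that("count-rate background correction dilutes brightness linearly", {
  expect_equal(apparent_brightness_count_background(1000, 5e4, 0), 1000)
  expect_equal(apparent_brightness_count_background(1000, 5e4, 2.5e4), 500)
  expect_error(apparent_brightness_count_background(1000, 5e4, 5e4), "k_B")
  # inverse undoes the correction
  expect_equal(correct_brightness_count_background(
    apparent_brightness_count_background(1234, 8e4, 1.7e4), 8e4, 1.7e4), 1234)
  # monotone decreasing in k_B
  kb <- seq(0, 4e4, 1e4)
  expect_true(all(diff(apparent_brightness_count_background(1000, 5e4, kb)) < 0))
})

test_that("species background correction is a brightness-weighted mean", {
  bg0 <- background_model()
  expect_equal(apparent_brightness_species(1000, 3, bg0), 1000)
  bg <- background_model(species = data.frame(eta_b = 1, N_b = 10))
  expect_equal(apparent_brightness_species(10, 1, bg), 110 / 20)  # = 5.5
  # always between the dimmest and brightest species present
  set.seed(60)
  for (i in 1:30) {
    k <- sample(1:4, 1)
    bgi <- background_model(species = data.frame(eta_b = runif(k, 1, 5000),
                                                 N_b = runif(k, 0.1, 50)))
    eta <- runif(1, 1, 5000); N <- runif(1, 0.1, 50)
    app <- apparent_brightness_species(eta, N, bgi)
    expect_gte(app, min(c(eta, bgi$species$eta_b)) - 1e-9)
    expect_lte(app, max(c(eta, bgi$species$eta_b)) + 1e-9)
  }
  # the dim-background contribution becomes negligible as tag copies grow:
  # apparent/true brightness rises monotonically toward 1
  bg_dim <- background_model(species = data.frame(eta_b = 50, N_b = 100))
  ratio_n <- sapply(c(1, 2, 6, 12, 48), function(n)
    apparent_brightness_species(n * 1000, 2, bg_dim) / (n * 1000))
  expect_true(all(diff(ratio_n) > 0))
  expect_lt(abs(ratio_n[5] - 1), 0.06)
})

test_that("in-cell concatemer series with autofluorescence matches the line route", {
  # apparent brightness of V1..V6 under a fluctuating dim background, then a
  # line fit on V2-V6 reads a 12-mer back correctly
  bg <- background_model(species = data.frame(eta_b = 60, N_b = 40))
  eta_true <- 800 * (1:6)
  eta_app <- sapply(eta_true, apparent_brightness_species, N_mean = 2,
                    background = bg)
  line <- fit_brightness_line(1:6, eta_app, exclude = 1, by_n = TRUE)
  # the monomer sits visibly above the line fitted to the 2..6-mers
  resid_v1 <- eta_app[1] - (line$intercept + line$slope * 1)
  expect_gt(resid_v1, 100)
  eta12 <- apparent_brightness_species(800 * 12, 2, bg)
  rho <- normalized_brightness_from_line(eta12, line)$rho
  expect_equal(rho, 12, tolerance = 0.05)
})
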