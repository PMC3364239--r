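test_that("photon file round trip is bit-exact, order preserved, empty ok", {
  set.seed(1)
  ins <- instrument_config(g_factor = 1.17, dark_rate_par_cps = 431,
                           dark_rate_perp_cps = 612)
  s <- make_stream(sort(runif(500, 0, 3)), sample(0:1, 500, TRUE), 3,
                   instrument = ins)
  path <- withr::local_tempfile(fileext = ".pstr")
  write_photon_stream(s, path)
  s2 <- read_photon_stream(path)
  expect_identical(s2$records$channel, s$records$channel)
  expect_identical(s2$records$macro_ticks, s$records$macro_ticks)
  expect_identical(s2$records$micro_ns, s$records$micro_ns)
  expect_identical(unclass(s2$instrument), unclass(s$instrument))
  expect_identical(s2$duration_s, s$duration_s)
  expect_true(!is.unsorted(s2$records$macro_ticks))

  # empty stream: valid file, zero rows
  e <- photon_stream(data.frame(channel = integer(), macro_ticks = numeric(),
                                micro_ns = numeric()), ins, 1)
  write_photon_stream(e, path)
  e2 <- read_photon_stream(path)
  expect_equal(nrow(e2$records), 0)
  expect_equal(e2$instrument$g_factor, 1.17)
})

test_that("format and invariant violations are rejected with useful errors", {
  ins <- instrument_config()
  expect_error(photon_stream(data.frame(channel = 0L, macro_ticks = 1.5,
                                        micro_ns = 1), ins, 1),
               "integer-valued")
  expect_error(photon_stream(data.frame(channel = 0L, macro_ticks = 1,
                                        micro_ns = 13), ins, 1),
               "micro_time")
  expect_error(photon_stream(data.frame(channel = c(0L, 0L),
                                        macro_ticks = c(5, 1),
                                        micro_ns = c(1, 1)), ins, 1),
               "non-decreasing")

  path <- withr::local_tempfile(fileext = ".pstr")
  writeLines(c("# pulse_period_ns = 12.5", "channel\tmacro\tmicro",
               "0\t1\t1.0"), path)
  expect_error(read_photon_stream(path), "missing field")
  writeLines(c("# pulse_period_ns = twelve", "# micro_resolution_ns = 0.01",
               "# macro_clock_s = 1e-8", "# g_factor = 1",
               "# dark_rate_par_cps = 0", "# dark_rate_perp_cps = 0",
               "# duration_s = 1", "channel\tmacro\tmicro"), path)
  expect_error(read_photon_stream(path), "pulse_period_ns")
  # data row violating the micro-time bound names the record
  writeLines(c("# pulse_period_ns = 12.5", "# micro_resolution_ns = 0.01",
               "# macro_clock_s = 1e-8", "# g_factor = 1",
               "# dark_rate_par_cps = 0", "# dark_rate_perp_cps = 0",
               "# duration_s = 1", "channel\tmacro\tmicro",
               "0\t1\t1.0", "1\t2\t14.0"), path)
  expect_error(read_photon_stream(path), "record 2")
})

test_that("micro-time histogram conserves counts for any bin width", {
  set.seed(2)
  ins <- quiet_instrument()
  s <- make_stream(sort(runif(4000, 0, 1)), sample(0:1, 4000, TRUE), 1,
                   instrument = ins,
                   micro_ns = sample_micro_time(4000, 3.1, 12.5))
  for (bw in c(0.05, 0.1, 0.3, 1.7, 12.5)) {
    h <- micro_time_histogram(s, bw)
    expect_equal(sum(h$counts_par), sum(s$records$channel == 0))
    expect_equal(sum(h$counts_perp), sum(s$records$channel == 1))
  }
  # delta input lands in a single bin
  d <- make_stream(sort(runif(50, 0, 1)), rep(0L, 50), 1, instrument = ins,
                   micro_ns = rep(2.0, 50))
  h <- suppressWarnings(micro_time_histogram(d, 0.5))
  expect_equal(sum(h$counts_par > 0), 1)
  expect_equal(max(h$counts_par), 50)
  # empty channel warns, does not error
  expect_warning(micro_time_histogram(d, 0.5), "perpendicular")
})

test_that("dark-count-only streams give flat micro-time histograms", {
  # simulator with no species: dark counts only
  ins <- instrument_config(dark_rate_par_cps = 500, dark_rate_perp_cps = 500)
  cfg <- simulation_config(list(), duration_s = 20, instrument = ins, seed = 3)
  sim <- simulate_stream(cfg)
  h <- micro_time_histogram(sim$stream, 12.5 / 32)  # divides the ADC grid evenly
  for (counts in list(h$counts_par, h$counts_perp)) {
    gof <- suppressWarnings(chisq.test(counts))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("intensity trace conserves photons and estimates the rate", {
  set.seed(4)
  s <- poisson_stream(12000, 8000, 1)
  tr <- intensity_trace(s, 0.1)
  expect_equal(sum(tr$counts), nrow(s$records))
  rate <- mean(tr$counts) / attr(tr, "bin_width_s")
  expect_lt(abs(rate - 20000), 3 * sqrt(20000 / 1))
  # bleaching-like linear decay in rate is detected by a negative slope
  set.seed(5)
  t_bleach <- NULL
  for (i in 1:20) {   # thinned inhomogeneous Poisson, rate halves over run
    tt <- runif(3000, 0, 1)
    t_bleach <- c(t_bleach, tt[runif(3000) < 1 - 0.5 * tt])
  }
  sb <- make_stream(sort(t_bleach), rep(0L, length(t_bleach)), 1)
  trb <- intensity_trace(sb, 0.05)
  fit <- lm(counts ~ time_s, data = trb)
  expect_lt(summary(fit)$coefficients["time_s", "t value"], -5)
  expect_error(intensity_trace(sb, 2), "bin_width_s")
})

test_that("simulator count rate matches the ground-truth manifest", {
  sim <- pinned_sim(seed = 11, brightness_total = 5e4, duration_s = 2)
  expected <- sim$truth$species[[1]]$brightness_cpsm * 2
  observed <- count_rate(sim$stream) * 2   # photons over 2 s
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})
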