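# Shared fixtures: all test data is built in code.

# instrument without dark counts, for tests where darks only add noise
quiet_instrument <- function(g = 1) {
  instrument_config(g_factor = g, dark_rate_par_cps = 0, dark_rate_perp_cps = 0)
}

# photon_stream from raw arrival times (s) and channels; micro-times uniform
# unless supplied
make_stream <- function(t_s, channel, duration_s,
                        instrument = quiet_instrument(),
                        micro_ns = NULL) {
  ord <- order(t_s)
  n <- length(t_s)
  if (is.null(micro_ns))
    micro_ns <- runif(n, 0, instrument$pulse_period_ns * 0.999)
  photon_stream(
    data.frame(channel = as.integer(channel[ord]),
               macro_ticks = floor(t_s[ord] / instrument$macro_clock_s),
               micro_ns = micro_ns[ord]),
    instrument, duration_s, provenance = "test fixture"
  )
}

# two independent homogeneous Poisson channels
poisson_stream <- function(rate_par, rate_perp, duration_s,
                           instrument = quiet_instrument()) {
  n1 <- rpois(1, rate_par * duration_s)
  n2 <- rpois(1, rate_perp * duration_s)
  make_stream(c(runif(n1, 0, duration_s), runif(n2, 0, duration_s)),
              c(rep(0L, n1), rep(1L, n2)), duration_s, instrument)
}

# decay_histogram built directly from counts (for arithmetic tests)
make_hist <- function(counts_par, counts_perp, bin_width_ns = 0.1,
                      dark_par = 0, dark_perp = 0) {
  structure(
    list(bin_centers_ns = (seq_along(counts_par) - 0.5) * bin_width_ns,
         counts_par = as.numeric(counts_par),
         counts_perp = as.numeric(counts_perp),
         dark_level_par = dark_par, dark_level_perp = dark_perp,
         bin_width_ns = bin_width_ns, duration_s = 1),
    class = "decay_histogram"
  )
}

# correlation_curve built from the diffusion model (for exact-fit tests)
model_curve <- function(N, tau_D_s, ratio, gamma = 0.35,
                        lags_s = exp(seq(log(1e-6), log(1e-2), length.out = 60)),
                        se = 1e-4, noise_sd = 0, duration_s = 10) {
  G <- (gamma / N) / ((1 + lags_s / tau_D_s) *
                        sqrt(1 + ratio^2 * lags_s / tau_D_s))
  if (noise_sd > 0) G <- G + rnorm(length(G), 0, noise_sd)
  structure(
    list(lags_s = lags_s, G = G, G_se = rep(se, length(lags_s)),
         kind = "cross", mean_rates = c(parallel = NA, perpendicular = NA),
         duration_s = duration_s, base_lag_s = min(lags_s),
         points_per_octave = NA_integer_, n_segments = 1L,
         grid = NULL),
    class = "correlation_curve"
  )
}

# anisotropy_decay from a clean model curve (for exact-fit tests)
model_anisotropy <- function(t_ns, r, se = 1e-4) {
  structure(
    list(bin_centers_ns = t_ns, r = r, r_se = rep(se, length(t_ns)),
         empty = rep(FALSE, length(t_ns)), g_used = 1, n_clamped = 0,
         bin_width_ns = diff(t_ns[1:2])),
    class = "anisotropy_decay"
  )
}

# pinned-at-focus simulation: cheap source of large micro-time photon counts
pinned_sim <- function(seed, n_fluor = 1, brightness_total = 5e5,
                       duration_s = 2, g = 1, theta_rot_ns = 16.4,
                       phi_fret_ns = 1, lifetime_ns = 3.1, r0 = 0.4,
                       dark = 0, r_et_ratio = 0) {
  sp <- species_spec(mean_N = 1, n_fluor = n_fluor,
                     peak_brightness_per_fluor = brightness_total / n_fluor,
                     D_um2_s = 0, lifetime_ns = lifetime_ns, r0 = r0,
                     theta_rot_ns = theta_rot_ns, phi_fret_ns = phi_fret_ns,
                     r_et_ratio = r_et_ratio)
  ins <- instrument_config(g_factor = g, dark_rate_par_cps = dark,
                           dark_rate_perp_cps = dark)
  cfg <- simulation_config(sp, duration_s = duration_s, instrument = ins,
                           seed = seed)
  suppressWarnings(simulate_stream(cfg))
}

# diffusing single-species simulation with the study-condition geometry
diffusing_sim <- function(seed, mean_N = 2, n_fluor = 1, per_fluor = 7000,
                          D = 30, duration_s = 1.8, omega_nm = 424,
                          ratio = 0.15, dark = 0, theta_rot_ns = 16.4,
                          lifetime_ns = 3.1) {
  sp <- species_spec(mean_N = mean_N, n_fluor = n_fluor,
                     peak_brightness_per_fluor = per_fluor, D_um2_s = D,
                     lifetime_ns = lifetime_ns, theta_rot_ns = theta_rot_ns)
  ins <- instrument_config(dark_rate_par_cps = dark, dark_rate_perp_cps = dark)
  cfg <- simulation_config(sp, omega_nm = omega_nm, z0_nm = omega_nm / ratio,
                           duration_s = duration_s, instrument = ins,
                           seed = seed)
  suppressWarnings(simulate_stream(cfg))
}

# brute-force enumeration of the random-pairing expectation:
# E[total transferred] / E[number of donors] over all label outcomes
enumerate_pairing <- function(n_pairs, p, E) {
  tot_fret <- 0; tot_don <- 0
  for (mask in 0:(2^(2 * n_pairs) - 1)) {
    lab <- as.integer(intToBits(mask))[1:(2 * n_pairs)]
    pr <- prod(ifelse(lab == 1, p, 1 - p))
    d1 <- lab[seq(1, 2 * n_pairs, 2)] == 1
    d2 <- lab[seq(2, 2 * n_pairs, 2)] == 1
    tot_fret <- tot_fret + pr * E * (sum(d1 & !d2) + sum(!d1 & d2))
    tot_don <- tot_don + pr * sum(lab)
  }
  tot_fret / tot_don
}
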