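#' Fluorophore complex (species) specification for the simulator
#'
#' Describes one diffusing species of n-mer fluorophore complexes: how many
#' fluorophores each complex carries, their per-fluorophore peak brightness at
#' the beam centre, the diffusion coefficient, the excited-state lifetime, and
#' the depolarization model (fundamental anisotropy, rotational correlation
#' time, and for n >= 2 the homo-FRET energy-exchange time).
#'
#' Defaults describe a Venus-like fluorescent protein: 3.1 ns lifetime,
#' 16.4 ns rotational correlation time, homo-FRET depolarization within the
#' first ~2 ns for oligomers.
#'
#' @param mean_N Mean number of complexes in the observation volume.
#' @param n_fluor Fluorophores per complex (integer >= 1).
#' @param peak_brightness_per_fluor Counts/s detected from one fluorophore at
#'   the beam centre.
#' @param D_um2_s Diffusion coefficient in um^2/s; `0` pins the complexes at
#'   the beam centre (useful for micro-time-only studies where diffusion
#'   statistics are irrelevant).
#' @param lifetime_ns Excited-state decay constant tau (ns).
#' @param r0 Fundamental anisotropy (0..1).
#' @param theta_rot_ns Rotational correlation time (ns).
#' @param phi_fret_ns Homo-FRET depolarization time (ns); ignored for
#'   monomers.
#' @param r_et_ratio Ratio of the energy-transfer anisotropy to r0 (0..1);
#'   0 means emission after transfer is fully depolarized.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(mean_N, n_fluor = 1L,
                         peak_brightness_per_fluor = 10000,
                         D_um2_s = 65, lifetime_ns = 3.1,
                         r0 = 0.4, theta_rot_ns = 16.4,
                         phi_fret_ns = 1.0, r_et_ratio = 0) {
  stopifnot(mean_N > 0, n_fluor >= 1, n_fluor == floor(n_fluor),
            peak_brightness_per_fluor > 0, D_um2_s >= 0,
            lifetime_ns > 0, r0 >= 0, r0 <= 1, theta_rot_ns > 0,
            phi_fret_ns > 0, r_et_ratio >= 0, r_et_ratio <= 1)
  structure(
    list(mean_N = mean_N, n_fluor = as.integer(n_fluor),
         peak_brightness_per_fluor = peak_brightness_per_fluor,
         D_um2_s = D_um2_s, lifetime_ns = lifetime_ns, r0 = r0,
         theta_rot_ns = theta_rot_ns, phi_fret_ns = phi_fret_ns,
         r_et_ratio = r_et_ratio),
    class = "species_spec"
  )
}

#' Simulation configuration
#'
#' Full generative parameter set for a Brownian-dynamics photon-stream
#' simulation: the species present, the two-photon beam geometry, the
#' instrument, the acquisition duration, the propagation step, the periodic
#' box size and the RNG seed.
#'
#' @param species A `species_spec` or list of them.
#' @param omega_nm Radial beam waist (1/e^2 of the squared-Gaussian detection
#'   weight) in nm.
#' @param z0_nm Axial beam waist in nm.
#' @param instrument An [instrument_config()].
#' @param duration_s Acquisition duration in seconds.
#' @param dt_s Propagation step in seconds; must satisfy dt <= tau_D/50 for
#'   the fastest diffusing species. Default: tau_D/50 of the fastest species.
#' @param box_multiplier Box half-width in units of (omega, omega, z0);
#'   must be >= 4 so the periodic images do not distort the correlation.
#' @param irf_sigma_ns Optional Gaussian detector/IRF timing jitter SD (ns)
#'   added to each photon's micro-time (0 = ideal delta response). All decay
#'   analysis here is tail fitting, so a realistic sub-100 ps jitter does not
#'   bias the fits.
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(species, omega_nm = 424, z0_nm = omega_nm / 0.15,
                              instrument = instrument_config(),
                              duration_s = 1, dt_s = NULL,
                              box_multiplier = 4, irf_sigma_ns = 0,
                              seed = 1L) {
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(length(species) >= 0,
            all(vapply(species, inherits, TRUE, "species_spec")),
            omega_nm > 0, z0_nm > 0, inherits(instrument, "instrument_config"),
            duration_s > 0, box_multiplier >= 4, irf_sigma_ns >= 0)
  omega_um <- omega_nm / 1000
  tau_D <- vapply(species, function(s)
    if (s$D_um2_s > 0) omega_um^2 / (8 * s$D_um2_s) else Inf, 1.0)
  if (is.null(dt_s)) {
    dt_s <- if (all(!is.finite(tau_D))) duration_s / 1000 else min(tau_D) / 50
  }
  if (any(is.finite(tau_D)) && dt_s > min(tau_D) / 50 * (1 + 1e-9)) {
    stop(sprintf(
      "dt_s = %.3g s too coarse: fastest species has tau_D = %.3g s, need dt <= %.3g s",
      dt_s, min(tau_D), min(tau_D) / 50))
  }
  structure(
    list(species = species, omega_nm = omega_nm, z0_nm = z0_nm,
         instrument = instrument, duration_s = duration_s, dt_s = dt_s,
         box_multiplier = box_multiplier, irf_sigma_ns = irf_sigma_ns,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Parametric anisotropy decay model of a species
#'
#' Builds the time-resolved anisotropy r(t) implied by a species'
#' depolarization parameters:
#' \deqn{r(t) = r_0 e^{-t/\theta} [ (1 - L) e^{-t/\phi} + L ],\quad
#'       L = (1 + (n - 1)\, c) / n}
#' where theta is the rotational correlation time, phi the homo-FRET
#' energy-exchange time, n the number of fluorophores per complex and c the
#' ratio of energy-transfer anisotropy to r0. For a monomer (or phi -> Inf)
#' this reduces exactly to r(t) = r0 exp(-t/theta). The plateau L is the
#' steady-state fraction of emission still carrying the excitation
#' polarization once excitation has equilibrated over the n fluorophores.
#'
#' @param species A [species_spec()].
#' @return A function `r(t_ns)` of class `anisotropy_model`; the parameters
#'   are attached as attributes (`r0`, `theta_rot_ns`, `phi_fret_ns`,
#'   `plateau`).
#' @export
anisotropy_decay_model <- function(species) {
  stopifnot(inherits(species, "species_spec"))
  r0 <- species$r0; theta <- species$theta_rot_ns
  n <- species$n_fluor; phi <- species$phi_fret_ns
  L <- if (n == 1L) 1 else (1 + (n - 1) * species$r_et_ratio) / n
  f <- if (n == 1L) {
    function(t_ns) r0 * exp(-t_ns / theta)
  } else {
    function(t_ns) r0 * exp(-t_ns / theta) * ((1 - L) * exp(-t_ns / phi) + L)
  }
  structure(f, class = c("anisotropy_model", "function"),
            r0 = r0, theta_rot_ns = theta,
            phi_fret_ns = if (n == 1L) Inf else phi, plateau = L)
}

#' Sample photon micro-times from a folded exponential decay
#'
#' Draws excited-state decay times from Exponential(lifetime) and folds them
#' modulo the pulse period, reproducing what a TCSPC digitizer records when
#' the decay outlasts a laser period.
#'
#' @param n Number of samples.
#' @param lifetime_ns Decay constant tau in ns (> 0).
#' @param pulse_period_ns Pulse period in ns.
#' @return Numeric vector of micro-times in `[0, pulse_period_ns)`.
#' @export
sample_micro_time <- function(n, lifetime_ns, pulse_period_ns = 12.5) {
  stopifnot(lifetime_ns > 0, pulse_period_ns > 0)
  stats::rexp(n, rate = 1 / lifetime_ns) %% pulse_period_ns
}

#' Probability that a photon is detected in the parallel channel
#'
#' For emission with anisotropy r, the parallel and perpendicular intensities
#' are proportional to (1 + 2r) and (1 - r); a detector with g-factor g
#' registers perpendicular photons with relative efficiency 1/g. The detection
#' odds are therefore (1 + 2r) : (1 - r)/g.
#'
#' @param r Anisotropy value(s) in `[-0.5, 1]`.
#' @param g Instrument g-factor.
#' @return P(parallel), same length as `r`.
#' @export
polarization_prob <- function(r, g = 1) {
  if (any(r < -0.5 - 1e-12 | r > 1 + 1e-12))
    stop("anisotropy outside [-0.5, 1]")
  par <- 1 + 2 * r
  perp <- (1 - r) / g
  par / (par + perp)
}

#' Assign a polarization channel to photons
#'
#' Draws the detection channel for each photon from the Bernoulli law implied
#' by the anisotropy at its (unfolded) emission delay. With g = 1 the standard
#' anisotropy estimator applied to the resulting histograms converges to
#' r(t).
#'
#' @param micro_time_ns Emission delays in ns (unfolded, i.e. the actual time
#'   since excitation).
#' @param r_model An `anisotropy_model` function (or any function of t in ns
#'   returning r).
#' @param g Instrument g-factor.
#' @return Integer channel codes (0 = parallel, 1 = perpendicular).
#' @export
assign_polarization <- function(micro_time_ns, r_model, g = 1) {
  p_par <- polarization_prob(r_model(micro_time_ns), g)
  ifelse(stats::runif(length(micro_time_ns)) < p_par, .CH_PAR, .CH_PERP)
}

# molecules in the periodic box per molecule in the observation volume:
# V_box = 8 b^3 omega^2 z0, V_obs = pi^{3/2} omega^2 z0 / 8
.box_to_obs_ratio <- function(box_multiplier) {
  64 * box_multiplier^3 / pi^1.5
}

#' Simulate a polarization-resolved photon stream
#'
#' Brownian-dynamics generator: molecules are initialized uniformly in a
#' periodic box around the two-photon observation volume, propagated with
#' per-axis Gaussian steps of SD sqrt(2 D dt), and emit photons as an
#' inhomogeneous Poisson process with rate
#' `n_fluor * peak_brightness_per_fluor * W(x, y, z)` where
#' `W = exp(-4 (x^2 + y^2)/omega^2) exp(-4 z^2/z0^2)` is the squared-Gaussian
#' two-photon detection weight. With this convention the fitted correlation
#' time obeys tau_D = omega^2 / (8 D) exactly. Each photon receives a
#' micro-time drawn from Exponential(lifetime) folded modulo the pulse period
#' and a polarization channel drawn from the species' anisotropy decay model
#' evaluated at the unfolded delay. Because the two detectors see the
#' parallel and perpendicular projections, the probability that an emitted
#' photon is detected at all depends on its instantaneous anisotropy
#' (proportional to `(1 + 2r) + (1 - r)/g`); emitted photons are thinned
#' accordingly, which makes the total-intensity decay `I_par + 2 g I_perp`
#' exactly mono-exponential and the histogram anisotropy estimator exactly
#' r(t). The emission rate is scaled by the inverse mean detection efficiency
#' so that `peak_brightness_per_fluor` is the *detected* brightness per
#' fluorophore at the beam centre: detected concatemer brightness is then
#' proportional to the fluorophore count, the convention under which
#' normalized brightness reads out stoichiometry. The detected brightness per
#' complex (`n_fluor * peak_brightness_per_fluor`) is recorded in the ground
#' truth as `brightness_cpsm`. Independent Poisson dark counts with uniform
#' micro- and macro-times are added per channel at the configured dark
#' rates.
#'
#' Species with `D_um2_s = 0` are pinned at the beam centre (`W = 1`), with
#' exactly `round(mean_N)` copies; this mode exists for micro-time studies
#' where the diffusion statistics would only add cost.
#'
#' A warning is issued when the configured mean count rate exceeds
#' 100,000 cps, the operating limit above which real TCSPC hardware shows
#' pile-up (which this simulator does not model).
#'
#' @param config A [simulation_config()].
#' @return A list with elements `stream` (a [photon_stream()]) and `truth`
#'   (a `ground_truth` list: per-species realized mean N, tau_D, D,
#'   brightness per complex, lifetime and depolarization parameters, plus
#'   realized photon counts per channel, beam geometry and seed).
#' @export
simulate_stream <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ins <- config$instrument
  omega_um <- config$omega_nm / 1000
  z0_um <- config$z0_nm / 1000
  dur <- config$duration_s
  ratio_box <- .box_to_obs_ratio(config$box_multiplier)

  expected_rate <- sum(vapply(config$species, function(s)
    s$mean_N * s$n_fluor * s$peak_brightness_per_fluor, 1.0)) +
    ins$dark_rate_par_cps + ins$dark_rate_perp_cps
  if (expected_rate > 1e5)
    warning(sprintf(paste0(
      "configured mean count rate %.0f cps exceeds the 100,000 cps pile-up ",
      "guideline for real TCSPC acquisition"), expected_rate))

  all_ch <- integer(0); all_t <- numeric(0); all_micro <- numeric(0)
  truth_species <- list()

  for (si in seq_along(config$species)) {
    s <- config$species[[si]]
    rate_complex <- s$n_fluor * s$peak_brightness_per_fluor
    model <- anisotropy_decay_model(s)
    g <- ins$g_factor
    # mean polarization-dependent detection efficiency: E[w]/w_max with
    # w(r) = (1 + 2r) + (1 - r)/g and E[r] over the exponential delay in
    # closed form; emission is scaled by 1/det_eff so that the configured
    # peak_brightness_per_fluor is the *detected* brightness at beam centre
    # (the convention in which concatemer brightness is proportional to n)
    w_max <- max(1 + 1 / g, (1 + 2 * s$r0) + (1 - s$r0) / g)
    L <- attr(model, "plateau"); phi <- attr(model, "phi_fret_ns")
    tau_l <- s$lifetime_ns
    Er <- s$r0 * ((1 - L) / (1 + tau_l / s$theta_rot_ns + tau_l / phi) +
                    L / (1 + tau_l / s$theta_rot_ns))
    det_eff <- ((1 + 2 * Er) + (1 - Er) / g) / w_max
    rate_emit <- rate_complex / det_eff
    if (s$D_um2_s == 0) {
      n_mol <- max(1L, as.integer(round(s$mean_N)))
      n_ph <- stats::rpois(1, n_mol * rate_emit * dur)
      t_s <- sort(stats::runif(n_ph, 0, dur))
      realized_N <- n_mol
      tau_D <- Inf
    } else {
      n_mol <- max(1L, as.integer(round(s$mean_N * ratio_box)))
      n_steps <- floor(dur / config$dt_s)
      t_s <- .bd_photon_times(
        n_mol, n_steps, config$dt_s,
        sqrt(2 * s$D_um2_s * config$dt_s),
        config$box_multiplier * omega_um, config$box_multiplier * omega_um,
        config$box_multiplier * z0_um,
        omega_um, z0_um, rate_emit
      )
      realized_N <- n_mol / ratio_box
      tau_D <- omega_um^2 / (8 * s$D_um2_s)
    }
    delay <- stats::rexp(length(t_s), rate = 1 / s$lifetime_ns)
    # polarization-dependent detection: emitted photons reach the detector
    # pair with probability proportional to (1 + 2r) + (1 - r)/g
    w <- (1 + 2 * model(delay)) + (1 - model(delay)) / g
    keep <- stats::runif(length(t_s)) * w_max < w
    t_s <- t_s[keep]; delay <- delay[keep]
    n_ph <- length(t_s)
    ch <- assign_polarization(delay, model, g)
    detected <- delay
    if (config$irf_sigma_ns > 0)
      detected <- detected + stats::rnorm(n_ph, 0, config$irf_sigma_ns)
    micro <- .quantize_micro(detected %% ins$pulse_period_ns, ins)
    all_ch <- c(all_ch, ch); all_t <- c(all_t, t_s); all_micro <- c(all_micro, micro)
    truth_species[[si]] <- list(
      n_fluor = s$n_fluor, mean_N = s$mean_N, realized_N = realized_N,
      n_molecules = n_mol, D_um2_s = s$D_um2_s, tau_D_s = tau_D,
      emission_rate_cpsm = rate_emit,
      detection_efficiency = det_eff,
      brightness_cpsm = rate_complex, lifetime_ns = s$lifetime_ns,
      r0 = s$r0, theta_rot_ns = s$theta_rot_ns,
      phi_fret_ns = attr(model, "phi_fret_ns"),
      plateau = attr(model, "plateau"),
      photons = n_ph
    )
  }

  for (code in c(.CH_PAR, .CH_PERP)) {
    rate <- if (code == .CH_PAR) ins$dark_rate_par_cps else ins$dark_rate_perp_cps
    if (rate > 0) {
      n_d <- stats::rpois(1, rate * dur)
      all_ch <- c(all_ch, rep(code, n_d))
      all_t <- c(all_t, stats::runif(n_d, 0, dur))
      all_micro <- c(all_micro, .quantize_micro(
        stats::runif(n_d, 0, ins$pulse_period_ns), ins))
    }
  }

  ord <- order(all_t)
  records <- data.frame(
    channel = all_ch[ord],
    macro_ticks = floor(all_t[ord] / ins$macro_clock_s),
    micro_ns = all_micro[ord]
  )
  stream <- photon_stream(records, ins, dur,
                          provenance = sprintf("fpfa simulation seed=%d", config$seed))
  truth <- structure(
    list(species = truth_species,
         omega_nm = config$omega_nm, z0_nm = config$z0_nm,
         volume_fl = observation_volume(config$omega_nm, config$z0_nm),
         duration_s = dur, dt_s = config$dt_s,
         box_multiplier = config$box_multiplier, seed = config$seed,
         counts_par = sum(records$channel == .CH_PAR),
         counts_perp = sum(records$channel == .CH_PERP)),
    class = "ground_truth"
  )
  list(stream = stream, truth = truth)
}

# snap a micro-time to the centre of its digitizer bin, keeping it < period
.quantize_micro <- function(micro_ns, ins) {
  res <- ins$micro_resolution_ns
  n_bins <- max(1, floor(ins$pulse_period_ns / res))
  q <- (pmin(floor(micro_ns / res), n_bins - 1) + 0.5) * res
  pmin(q, ins$pulse_period_ns * (1 - 1e-12))
}

#' Read a simulation configuration from a YAML file
#'
#' The file mirrors [simulation_config()]: top-level keys `omega_nm`, `z0_nm`,
#' `duration_s`, `dt_s` (optional), `box_multiplier`, `seed`, an optional
#' `instrument` mapping with [instrument_config()] fields, and a `species`
#' list whose entries hold [species_spec()] fields.
#'
#' @param path Path to the YAML config.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  ins <- do.call(instrument_config, y$instrument %||% list())
  sp <- lapply(y$species, function(s) do.call(species_spec, s))
  args <- y[setdiff(names(y), c("instrument", "species"))]
  do.call(simulation_config, c(list(species = sp, instrument = ins), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
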