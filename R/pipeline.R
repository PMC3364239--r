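# End-to-end FPFA orchestration: simulate / analyze / calibrate / fret.
# These are the functions the command-line wrapper (inst/cli/fpfa) calls.

#' Simulate a photon stream to disk
#'
#' Runs [simulate_stream()] and writes the photon file plus a ground-truth
#' manifest (`<out>.truth.json`) next to it.
#'
#' @param config A [simulation_config()] or a path to a YAML config file.
#' @param out Output photon file path.
#' @param seed Optional seed overriding the config's.
#' @return Invisibly, the `ground_truth`.
#' @export
fpfa_simulate <- function(config, out, seed = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- simulate_stream(config)
  write_photon_stream(sim$stream, out)
  jsonlite::write_json(unclass(sim$truth), paste0(out, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim$truth)
}

#' Full FPFA analysis of a photon stream
#'
#' Runs the joint micro-time and macro-time analysis that defines FPFA:
#' micro-time histograms of both polarization channels; time-resolved
#' anisotropy with exponential model selection (a fast component on top of
#' rotational decay is the homo-FRET signature); the total-intensity lifetime
#' decay with a mono-exponential tail fit; the parallel x perpendicular
#' cross-correlation with the two-photon 3-D Gaussian diffusion fit giving
#' `<N>` and `tau_D`; molecular brightness with the constant-background
#' (dark-rate) correction; and, when calibration information is available,
#' normalized brightness, diffusion coefficient, observation volume and
#' concentration.
#'
#' A warning is issued when the count rate is outside the [20,000, 100,000]
#' cps envelope within which TCSPC anisotropy and fluctuation measurements
#' are reliable (signal-to-dark at the bottom, pile-up at the top). When the
#' signal does not rise above the recorded dark rates the report flags
#' insufficient signal instead of fitting.
#'
#' @param stream A [photon_stream()] or path to a photon file.
#' @param g g-factor; default from the stream header.
#' @param gamma PSF shape constant for the diffusion fit.
#' @param omega_z_ratio Waist ratio for the diffusion fit (fixed), or `NULL`
#'   to fit it; superseded by `calibration`.
#' @param calibration Optional calibration list (as produced by
#'   [fpfa_calibrate()] or read from its JSON): fields `g`, `omega_nm`,
#'   `omega_z_ratio`, `z0_nm`, `volume_fl`.
#' @param eta_reference Optional monomer brightness (cpsm) for normalized
#'   brightness.
#' @param brightness_line Optional `calibration_line` for the in-cell
#'   normalized brightness.
#' @param micro_bin_ns Micro-time histogram bin width (ns).
#' @param base_lag_s,points_per_octave,n_segments Correlator settings.
#' @param anis_window_ns,lifetime_window_ns Optional fit windows.
#' @param max_anis_components Largest anisotropy model tried (model selection
#'   prefers fewer components unless reduced chi-square improves > 20%).
#' @return An object of class `fpfa_report` (a nested list; see
#'   [write_fpfa_report()]).
#' @export
fpfa_analyze <- function(stream, g = NULL, gamma = 0.35, omega_z_ratio = 0.15,
                         calibration = NULL, eta_reference = NULL,
                         brightness_line = NULL,
                         micro_bin_ns = 0.1, base_lag_s = 1e-6,
                         points_per_octave = 8L, n_segments = 10L,
                         anis_window_ns = NULL, lifetime_window_ns = NULL,
                         max_anis_components = 2L) {
  src <- NULL
  if (is.character(stream)) {
    src <- stream
    stream <- read_photon_stream(stream)
  }
  stopifnot(inherits(stream, "photon_stream"))
  ins <- stream$instrument
  if (!is.null(calibration)) {
    if (!is.null(calibration$g)) g <- calibration$g
    if (!is.null(calibration$omega_z_ratio)) omega_z_ratio <- calibration$omega_z_ratio
  }
  if (is.null(g)) g <- ins$g_factor

  rate_total <- count_rate(stream)
  dark_total <- ins$dark_rate_par_cps + ins$dark_rate_perp_cps
  if (rate_total < 2e4 || rate_total > 1e5)
    warning(sprintf(
      "count rate %.0f cps outside the [20,000, 100,000] cps operating envelope",
      rate_total))
  insufficient <- rate_total <= dark_total * 1.5

  report <- list(
    provenance = list(
      source = src %||% "in-memory stream",
      md5 = if (!is.null(src)) unname(tools::md5sum(src)) else NA_character_,
      n_photons = nrow(stream$records),
      duration_s = stream$duration_s,
      count_rate_cps = rate_total,
      g_used = g, gamma = gamma,
      stream_provenance = stream$provenance),
    insufficient_signal = insufficient
  )
  if (insufficient) {
    warning("signal not above dark level; skipping fits")
    return(structure(report, class = "fpfa_report"))
  }

  hist <- micro_time_histogram(stream, micro_bin_ns)
  tra <- time_resolved_anisotropy(hist, g)
  life <- total_intensity_decay(hist, g)
  anis_fit <- select_exponential_model(tra, max_anis_components, anis_window_ns)
  life_fit <- fit_exponential_decay(life, 1, lifetime_window_ns)

  curve <- multitau_correlate(stream, "parallel", "perpendicular",
                              base_lag_s, points_per_octave, n_segments)
  diff_fit <- fit_diffusion_model(curve, gamma, omega_z_ratio)

  eta_app <- molecular_brightness(rate_total, diff_fit$N_mean)
  eta <- if (dark_total > 0 && dark_total < rate_total)
    correct_brightness_count_background(eta_app, rate_total, dark_total)
  else eta_app

  brightness <- list(k_mean_cps = rate_total, k_dark_cps = dark_total,
                     N_mean = diff_fit$N_mean,
                     eta_app_cpsm = eta_app, eta_cpsm = eta)
  if (!is.null(eta_reference))
    brightness$rho <- normalized_brightness(eta, eta_reference)
  if (!is.null(brightness_line)) {
    nb <- normalized_brightness_from_line(eta, brightness_line)
    brightness$rho_from_line <- nb$rho
    brightness$rho_from_line_se <- nb$rho_se
  }

  geometry <- NULL
  if (!is.null(calibration) && !is.null(calibration$omega_nm)) {
    geom <- beam_geometry(calibration$omega_nm,
                          omega_z_ratio = calibration$omega_z_ratio %||%
                            omega_z_ratio)
    geometry <- list(omega_nm = geom$omega_nm, z0_nm = geom$z0_nm,
                     omega_z_ratio = geom$omega_z_ratio,
                     volume_fl = geom$volume_fl,
                     D_um2_s = diffusion_coefficient(diff_fit$tau_D_s,
                                                     geom$omega_nm),
                     concentration_molar = concentration(diff_fit$N_mean,
                                                         geom$volume_fl))
  }

  report$anisotropy <- list(
    n_components = anis_fit$n_components,
    amplitudes = anis_fit$amplitudes,
    time_constants_ns = anis_fit$time_constants_ns,
    offset = anis_fit$offset,
    reduced_chi2 = anis_fit$reduced_chi2,
    fit_window_ns = anis_fit$fit_window_ns)
  report$lifetime <- list(
    tau_ns = life_fit$time_constants_ns,
    amplitude = life_fit$amplitudes,
    reduced_chi2 = life_fit$reduced_chi2,
    fit_window_ns = life_fit$fit_window_ns)
  report$diffusion <- list(
    N_mean = diff_fit$N_mean, tau_D_s = diff_fit$tau_D_s,
    omega_z_ratio = diff_fit$omega_z_ratio, gamma = gamma,
    reduced_chi2 = diff_fit$reduced_chi2)
  report$brightness <- brightness
  report$geometry <- geometry
  report$curves <- list(histogram = hist, anisotropy = tra, lifetime = life,
                        correlation = curve)
  report$fits <- list(anisotropy = anis_fit, lifetime = life_fit,
                      diffusion = diff_fit)
  structure(report, class = "fpfa_report")
}

#' @export
print.fpfa_report <- function(x, ...) {
  cat("<fpfa_report>\n")
  p <- x$provenance
  cat(sprintf("  %s: %d photons, %.3g s, %.0f cps\n", p$source, p$n_photons,
              p$duration_s, p$count_rate_cps))
  if (isTRUE(x$insufficient_signal)) {
    cat("  ** insufficient signal above dark level; no fits **\n")
    return(invisible(x))
  }
  a <- x$anisotropy
  cat(sprintf("  anisotropy: %d component(s), tau = %s ns, offset %.3g\n",
              a$n_components,
              paste(signif(a$time_constants_ns, 3), collapse = ", "), a$offset))
  cat(sprintf("  lifetime: tau = %.3g ns\n", x$lifetime$tau_ns))
  d <- x$diffusion
  cat(sprintf("  diffusion: <N> = %.3g, tau_D = %.3g s\n", d$N_mean, d$tau_D_s))
  b <- x$brightness
  cat(sprintf("  brightness: eta = %.4g cpsm%s\n", b$eta_cpsm,
              if (!is.null(b$rho)) sprintf(", rho = %.3g", b$rho) else ""))
  if (!is.null(x$geometry))
    cat(sprintf("  geometry: V = %.3g fl, D = %.3g um2/s, conc = %.3g M\n",
                x$geometry$volume_fl, x$geometry$D_um2_s,
                x$geometry$concentration_molar))
  invisible(x)
}

#' Write an FPFA report as JSON (plus optional TSV curves)
#'
#' @param report An `fpfa_report`.
#' @param path Output JSON path.
#' @param curves Also export the intermediate curves as TSV files next to the
#'   JSON (`<path>.anisotropy.tsv`, `.lifetime.tsv`, `.correlation.tsv`,
#'   `.histogram.tsv`).
#' @return Invisibly, `path`.
#' @export
write_fpfa_report <- function(report, path, curves = TRUE) {
  stopifnot(inherits(report, "fpfa_report"))
  out <- report[setdiff(names(report), c("curves", "fits"))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  if (curves && !is.null(report$curves)) {
    write_anisotropy_decay(report$curves$anisotropy, paste0(path, ".anisotropy.tsv"))
    utils::write.table(
      data.frame(bin_center_ns = report$curves$lifetime$bin_centers_ns,
                 F = report$curves$lifetime$total_intensity),
      paste0(path, ".lifetime.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_correlation_curve(report$curves$correlation, paste0(path, ".correlation.tsv"))
    write_decay_histogram(report$curves$histogram, paste0(path, ".histogram.tsv"))
  }
  invisible(path)
}

#' Instrument and beam calibration workflows
#'
#' Three calibration modes, mirroring standard FPFA practice:
#' \describe{
#'   \item{`g_factor`}{Tail fit of a fast-rotating dye (fluorescein): g makes
#'     the tail-window anisotropy vanish.}
#'   \item{`beam_waist`}{Correlation time of a standard of known diffusion
#'     coefficient (fluorescein, `D_standard = 300` um^2/s) gives
#'     `omega = sqrt(8 D tau_D)`.}
#'   \item{`dilution_series`}{Global diffusion fit over curves from known
#'     dilutions: shared omega/z and tau_D, per-curve `<N>`.}
#' }
#'
#' @param mode `"g_factor"`, `"beam_waist"` or `"dilution_series"`.
#' @param streams A [photon_stream()] or list of them (photon file paths are
#'   accepted); for `dilution_series`, pre-computed `correlation_curve`s are
#'   also accepted.
#' @param D_standard_um2_s Diffusion coefficient of the standard (um^2/s);
#'   required in `beam_waist` mode (fluorescein: 300 um^2/s at room
#'   temperature).
#' @param tail_window_ns Tail window for `g_factor` mode.
#' @param micro_bin_ns Histogram bin width for `g_factor` mode.
#' @param gamma,base_lag_s,points_per_octave,n_segments Correlator/fit
#'   settings.
#' @param excitation_power_mw Annotation stored in the calibration.
#' @param calibration Existing calibration list to update (fields are merged).
#' @return A calibration list with the fields filled in by the chosen mode
#'   (`g`; `omega_nm`, `tau_D_standard_s`; `omega_z_ratio`, `z0_nm`,
#'   `volume_fl`, `N_mean_series`).
#' @export
fpfa_calibrate <- function(mode = c("g_factor", "beam_waist", "dilution_series"),
                           streams, D_standard_um2_s = NULL,
                           tail_window_ns = NULL, micro_bin_ns = 0.1,
                           gamma = 0.35, base_lag_s = 1e-6,
                           points_per_octave = 8L, n_segments = 10L,
                           excitation_power_mw = NA_real_,
                           calibration = list()) {
  mode <- match.arg(mode)
  as_stream <- function(x) if (is.character(x)) read_photon_stream(x) else x
  if (inherits(streams, c("photon_stream", "correlation_curve")) ||
      is.character(streams) && length(streams) == 1)
    streams <- list(streams)
  streams <- lapply(streams, as_stream)
  cal <- calibration
  cal$excitation_power_mw <- excitation_power_mw

  if (mode == "g_factor") {
    s <- streams[[1]]
    hist <- micro_time_histogram(s, micro_bin_ns)
    if (is.null(tail_window_ns)) {
      period <- s$instrument$pulse_period_ns
      tail_window_ns <- c(period * 0.4, period)
    }
    cal$g <- calibrate_g_factor(hist, tail_window_ns)
  } else if (mode == "beam_waist") {
    if (is.null(D_standard_um2_s))
      stop("beam_waist mode needs D_standard_um2_s (fluorescein: 300 um^2/s)")
    curves <- lapply(streams, function(s) {
      if (inherits(s, "correlation_curve")) s
      else multitau_correlate(s, "parallel", "perpendicular", base_lag_s,
                              points_per_octave, n_segments)
    })
    avg <- average_correlation_curves(curves)
    fit <- fit_diffusion_model(avg, gamma,
                               cal$omega_z_ratio %||% 0.15)
    cal$tau_D_standard_s <- fit$tau_D_s
    cal$omega_nm <- beam_waist(D_standard_um2_s, fit$tau_D_s)
    cal$D_standard_um2_s <- D_standard_um2_s
  } else {
    curves <- lapply(streams, function(s) {
      if (inherits(s, "correlation_curve")) s
      else multitau_correlate(s, "parallel", "perpendicular", base_lag_s,
                              points_per_octave, n_segments)
    })
    fit <- global_fit_dilution_series(curves, gamma)
    cal$omega_z_ratio <- fit$omega_z_ratio
    cal$tau_D_series_s <- fit$tau_D_s
    cal$N_mean_series <- fit$N_mean
  }
  if (!is.null(cal$omega_nm) && !is.null(cal$omega_z_ratio)) {
    cal$z0_nm <- axial_from_ratio(cal$omega_nm, cal$omega_z_ratio)
    cal$volume_fl <- observation_volume(cal$omega_nm, cal$z0_nm)
  }
  cal
}

#' Write / read a calibration file
#' @param calibration Calibration list from [fpfa_calibrate()].
#' @param path JSON path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   the calibration list.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(calibration, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Fit the hetero-FRET pairing model from a points table
#'
#' @param points Data frame with columns `p`, `E_obs` and optional `weight`,
#'   or the path to such a TSV ([read_fret_points()]).
#' @param bootstrap Number of bootstrap resamples for a CI on E (0 = none).
#' @return A `pairing_fit`; with bootstrapping, attributes `E_ci` (2.5/97.5
#'   percentiles) and `bootstrap` are attached.
#' @export
fpfa_fret <- function(points, bootstrap = 0) {
  if (is.character(points)) points <- read_fret_points(points)
  w <- if ("weight" %in% names(points)) points$weight else NULL
  fit <- fit_pairing_model(points$p, points$E_obs, w)
  if (bootstrap > 0) {
    n <- nrow(points)
    Es <- replicate(bootstrap, {
      i <- sample.int(n, n, replace = TRUE)
      tryCatch(suppressWarnings(
        fit_pairing_model(points$p[i], points$E_obs[i],
                          if (!is.null(w)) w[i])$E),
        error = function(e) NA_real_)
    })
    attr(fit, "E_ci") <- stats::quantile(Es, c(0.025, 0.975), na.rm = TRUE)
    attr(fit, "bootstrap") <- bootstrap
  }
  fit
}
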