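# Stoichiometry and calibration arithmetic: molecular and normalized
# brightness, the correlation-time/diffusion relation, two-photon observation
# volume, concentrations, and background-brightness corrections.

.AVOGADRO <- 6.02214076e23

#' Molecular brightness
#'
#' The average number of detected photons per second per fluctuating molecule
#' (cpsm): `eta = <k> / <N>`, where `<k>` is the average count rate and `<N>`
#' the fitted mean number of molecules in the observation volume.
#'
#' @param k_mean_cps Average count rate, both channels summed (counts/s).
#' @param N_mean Mean number of molecules (> 0).
#' @return Brightness eta in cpsm.
#' @export
molecular_brightness <- function(k_mean_cps, N_mean) {
  if (any(N_mean <= 0)) stop("N_mean must be positive")
  k_mean_cps / N_mean
}

#' Normalized brightness against a monomer reference
#'
#' `rho = eta_complex / eta_reference`: the average number of fluorophores per
#' complex, read against the brightness of a single fluorophore measured
#' under the same conditions. Both brightnesses must come from the same
#' excitation power; if power annotations are supplied and disagree the
#' function refuses unless `override = TRUE`.
#'
#' @param eta_complex Brightness of the complex (cpsm).
#' @param eta_reference Brightness of the monomeric fluorophore (cpsm, > 0).
#' @param power_complex_mw,power_reference_mw Optional excitation power
#'   annotations (mW) used to enforce matched conditions.
#' @param override Allow mismatched powers (with a warning).
#' @return Normalized brightness rho.
#' @export
normalized_brightness <- function(eta_complex, eta_reference,
                                  power_complex_mw = NULL,
                                  power_reference_mw = NULL,
                                  override = FALSE) {
  if (any(eta_reference <= 0)) stop("eta_reference must be positive")
  if (!is.null(power_complex_mw) && !is.null(power_reference_mw) &&
      !isTRUE(all.equal(power_complex_mw, power_reference_mw))) {
    msg <- sprintf(
      "brightnesses measured at different powers (%.3g vs %.3g mW); rho is only meaningful under matched conditions",
      power_complex_mw, power_reference_mw)
    if (!override) stop(msg) else warning(msg)
  }
  eta_complex / eta_reference
}

#' Fit the concatemer brightness calibration line
#'
#' Ordinary least squares of brightness on the number of fluorophores per
#' concatemer, with 95% confidence and prediction bands. Points can be
#' excluded (e.g. a monomer inflated by cellular autofluorescence) before
#' fitting.
#'
#' @param n_fluor Number of fluorophores per construct.
#' @param eta Measured brightness (cpsm), same length.
#' @param exclude Optional indices or `n_fluor` values (if `by_n = TRUE`) to
#'   drop.
#' @param by_n Interpret `exclude` as `n_fluor` values rather than indices.
#' @param conf_level Confidence level for the bands.
#' @param band_at Grid of n values at which bands are evaluated.
#' @return An object of class `calibration_line`: `slope` (m), `intercept`
#'   (b), `se` (named), `included` data frame, `bands` data frame with
#'   confidence and prediction intervals, `conf_level`, the underlying `lm`
#'   fit.
#' @export
fit_brightness_line <- function(n_fluor, eta, exclude = NULL, by_n = FALSE,
                                conf_level = 0.95,
                                band_at = seq(min(n_fluor), max(n_fluor),
                                              length.out = 50)) {
  stopifnot(length(n_fluor) == length(eta))
  keep <- rep(TRUE, length(n_fluor))
  if (!is.null(exclude)) {
    if (by_n) keep[n_fluor %in% exclude] <- FALSE else keep[exclude] <- FALSE
  }
  if (sum(keep) < 2) stop("fewer than 2 points after exclusion")
  d <- data.frame(n = n_fluor[keep], eta = eta[keep])
  fit <- stats::lm(eta ~ n, data = d)
  nd <- data.frame(n = band_at)
  cb <- stats::predict(fit, nd, interval = "confidence", level = conf_level)
  pb <- stats::predict(fit, nd, interval = "prediction", level = conf_level)
  co <- stats::coef(fit)
  if (co["n"] <= 0) warning("calibration slope is not positive; check inputs")
  structure(
    list(slope = unname(co["n"]), intercept = unname(co["(Intercept)"]),
         se = c(slope = sqrt(stats::vcov(fit)["n", "n"]),
                intercept = sqrt(stats::vcov(fit)["(Intercept)", "(Intercept)"])),
         vcov = stats::vcov(fit),
         included = d,
         bands = data.frame(n = band_at, fit = cb[, "fit"],
                            conf_lo = cb[, "lwr"], conf_hi = cb[, "upr"],
                            pred_lo = pb[, "lwr"], pred_hi = pb[, "upr"]),
         conf_level = conf_level, lm = fit),
    class = "calibration_line"
  )
}

#' Normalized brightness from a calibration line
#'
#' In cells, where autofluorescence offsets the brightness scale, the
#' normalized brightness is read off the concatemer calibration line:
#' `rho = (eta - b) / m` with slope m and intercept b. Uncertainty is
#' propagated to first order from the line's parameter covariance and the
#' sample's brightness SE.
#'
#' @param eta Measured brightness (cpsm).
#' @param line A `calibration_line`.
#' @param eta_se Optional SE of `eta`.
#' @return List with `rho` and `rho_se`. A sample dimmer than the intercept
#'   yields a negative rho with a warning.
#' @export
normalized_brightness_from_line <- function(eta, line, eta_se = 0) {
  stopifnot(inherits(line, "calibration_line"))
  m <- line$slope; b <- line$intercept
  rho <- (eta - b) / m
  if (any(rho < 0))
    warning("brightness below the calibration intercept: negative rho (sub-background sample)")
  # delta method: d rho/d eta = 1/m, d rho/d b = -1/m, d rho/d m = -rho/m
  grad_b <- -1 / m
  grad_m <- -rho / m
  V <- line$vcov  # order: (Intercept), n
  var_line <- grad_b^2 * V[1, 1] + grad_m^2 * V[2, 2] +
    2 * grad_b * grad_m * V[1, 2]
  list(rho = rho, rho_se = sqrt(var_line + (eta_se / m)^2))
}

#' Diffusion coefficient from a correlation time (two-photon)
#'
#' For two-photon excitation the diffusion correlation time and coefficient
#' are related by `tau_D = omega^2 / (8 D)`.
#'
#' @param tau_D_s Correlation time in seconds.
#' @param omega_nm Radial beam waist in nm.
#' @return Diffusion coefficient in um^2/s.
#' @export
diffusion_coefficient <- function(tau_D_s, omega_nm) {
  stopifnot(all(tau_D_s > 0), all(omega_nm > 0))
  (omega_nm / 1000)^2 / (8 * tau_D_s)
}

#' Radial beam waist from a diffusion standard
#'
#' Inverse of [diffusion_coefficient()]: `omega = sqrt(8 D tau_D)`. Measuring
#' the correlation time of a standard of known D (fluorescein,
#' D = 300 um^2/s at room temperature) calibrates the beam waist.
#'
#' @param D_um2_s Diffusion coefficient in um^2/s.
#' @param tau_D_s Correlation time in seconds.
#' @return Radial waist omega in nm.
#' @export
beam_waist <- function(D_um2_s, tau_D_s) {
  stopifnot(all(D_um2_s > 0), all(tau_D_s > 0))
  1000 * sqrt(8 * D_um2_s * tau_D_s)
}

#' Two-photon observation volume
#'
#' Effective two-photon 3-D Gaussian volume
#' `V = pi^{3/2} omega^2 z / 8`, in femtoliters.
#'
#' @param omega_nm Radial waist in nm.
#' @param z0_nm Axial waist in nm.
#' @return Volume in fl.
#' @export
observation_volume <- function(omega_nm, z0_nm) {
  stopifnot(all(omega_nm > 0), all(z0_nm > 0))
  pi^1.5 * (omega_nm / 1000)^2 * (z0_nm / 1000) / 8
}

#' Axial waist from the radial waist and the waist ratio
#' @param omega_nm Radial waist in nm.
#' @param omega_z_ratio Ratio omega/z in (0, 1).
#' @return Axial waist z in nm.
#' @export
axial_from_ratio <- function(omega_nm, omega_z_ratio) {
  stopifnot(all(omega_nm > 0), all(omega_z_ratio > 0), all(omega_z_ratio < 1))
  omega_nm / omega_z_ratio
}

#' Concentration from a molecule count
#' @param N_mean Mean number of molecules in the volume.
#' @param volume_fl Observation volume in fl.
#' @return Concentration in mol/L.
#' @export
concentration <- function(N_mean, volume_fl) {
  stopifnot(all(volume_fl > 0), all(N_mean >= 0))
  N_mean / (.AVOGADRO * volume_fl * 1e-15)
}

#' Molecule count from a concentration
#' @param conc_molar Concentration in mol/L.
#' @param volume_fl Observation volume in fl.
#' @return Mean number of molecules in the volume.
#' @export
molecules <- function(conc_molar, volume_fl) {
  stopifnot(all(volume_fl > 0), all(conc_molar >= 0))
  conc_molar * .AVOGADRO * volume_fl * 1e-15
}

#' Apparent brightness under a constant background count rate
#'
#' A background that only adds counts (dark counts, stray light) does not
#' fluctuate with the molecules, so it dilutes the correlation amplitude and
#' the apparent brightness becomes
#' `eta_app = eta (k - k_B) / k`. The function is monotone decreasing in
#' `k_B`; inverting it recovers the background-free brightness from a
#' measured apparent one.
#'
#' @param eta True (background-free) brightness in cpsm.
#' @param k_mean_cps Total measured count rate (sample + background).
#' @param k_B_cps Background count rate, `0 <= k_B < k_mean`.
#' @return Apparent brightness eta_app.
#' @export
apparent_brightness_count_background <- function(eta, k_mean_cps, k_B_cps) {
  if (any(k_B_cps < 0) || any(k_B_cps >= k_mean_cps))
    stop("need 0 <= k_B < k_mean (no signal left otherwise)")
  eta * (k_mean_cps - k_B_cps) / k_mean_cps
}

#' Invert the count-rate background correction
#' @inheritParams apparent_brightness_count_background
#' @param eta_app Measured apparent brightness.
#' @return Background-free brightness eta.
#' @export
correct_brightness_count_background <- function(eta_app, k_mean_cps, k_B_cps) {
  if (any(k_B_cps < 0) || any(k_B_cps >= k_mean_cps))
    stop("need 0 <= k_B < k_mean (no signal left otherwise)")
  eta_app * k_mean_cps / (k_mean_cps - k_B_cps)
}

#' Background model: fluctuating background species
#'
#' @param k_B_cps Constant background count rate (counts/s).
#' @param species Data frame with columns `eta_b` (cpsm) and `N_b` (mean
#'   molecules) for each fluctuating background species; may be empty.
#' @return An object of class `background_model`.
#' @export
background_model <- function(k_B_cps = 0, species = data.frame(eta_b = numeric(),
                                                               N_b = numeric())) {
  stopifnot(k_B_cps >= 0, is.data.frame(species),
            all(c("eta_b", "N_b") %in% names(species)),
            all(species$eta_b >= 0), all(species$N_b >= 0))
  structure(list(k_B_cps = k_B_cps, species = species),
            class = "background_model")
}

#' Apparent brightness with fluctuating background species
#'
#' With several fluctuating fluorescent species the apparent brightness is
#' the brightness-squared-weighted mean
#' \deqn{\eta_{app} = \frac{\eta^2 \langle N\rangle + \sum_b \eta_b^2 \langle N_b\rangle}
#'                        {\eta \langle N\rangle + \sum_b \eta_b \langle N_b\rangle}}
#' It reduces to eta with no background and always lies between the dimmest
#' and brightest species present.
#'
#' @param eta Brightness of the species of interest (cpsm).
#' @param N_mean Its mean molecule number.
#' @param background A [background_model()] (only its `species` table is
#'   used).
#' @return Apparent brightness eta_app.
#' @export
apparent_brightness_species <- function(eta, N_mean, background) {
  stopifnot(inherits(background, "background_model"))
  eb <- background$species$eta_b; nb <- background$species$N_b
  num <- eta^2 * N_mean + sum(eb^2 * nb)
  den <- eta * N_mean + sum(eb * nb)
  if (den <= 0) stop("no species with a positive count rate")
  num / den
}

#' Beam geometry record
#'
#' @param omega_nm Radial waist (nm).
#' @param z0_nm Axial waist (nm); default from `omega_z_ratio`.
#' @param omega_z_ratio Waist ratio; default `omega_nm / z0_nm`.
#' @param excitation_power_mw Annotation only.
#' @return An object of class `beam_geometry` with `omega_nm`, `z0_nm`,
#'   `omega_z_ratio`, `volume_fl`, `excitation_power_mw`.
#' @export
beam_geometry <- function(omega_nm, z0_nm = NULL, omega_z_ratio = NULL,
                          excitation_power_mw = NA_real_) {
  if (is.null(z0_nm) && is.null(omega_z_ratio))
    stop("supply z0_nm or omega_z_ratio")
  if (is.null(z0_nm)) z0_nm <- axial_from_ratio(omega_nm, omega_z_ratio)
  if (is.null(omega_z_ratio)) omega_z_ratio <- omega_nm / z0_nm
  structure(
    list(omega_nm = omega_nm, z0_nm = z0_nm, omega_z_ratio = omega_z_ratio,
         volume_fl = observation_volume(omega_nm, z0_nm),
         excitation_power_mw = excitation_power_mw),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> omega = %.4g nm, z = %.4g nm (ratio %.3g), V = %.3g fl\n",
              x$omega_nm, x$z0_nm, x$omega_z_ratio, x$volume_fl))
  if (is.finite(x$excitation_power_mw))
    cat(sprintf("  excitation power %.3g mW\n", x$excitation_power_mw))
  invisible(x)
}
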