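#' Time-resolved anisotropy from a polarized decay histogram
#'
#' Computes the per-bin anisotropy
#' \deqn{r(t) = \frac{I_{\parallel}(t) - g I_{\perp}(t)}
#'                   {I_{\parallel}(t) + 2 g I_{\perp}(t)}}
#' on dark-subtracted counts, where g corrects the relative detection
#' efficiency of the perpendicular channel. Dark levels come from the
#' histogram (instrument dark rate scaled to a per-bin expectation); negative
#' dark-subtracted counts are clamped to zero and the clamp count reported.
#' Per-bin standard errors are propagated from Poisson counting statistics by
#' the delta method. Bins with zero total intensity yield `NA` and are
#' flagged, never division faults.
#'
#' @param hist A `decay_histogram` from [micro_time_histogram()].
#' @param g Instrument g-factor (> 0).
#' @return An object of class `anisotropy_decay` with `bin_centers_ns`, `r`,
#'   `r_se`, `empty` (logical flag per bin), `g_used`, `n_clamped`.
#' @export
time_resolved_anisotropy <- function(hist, g = 1) {
  stopifnot(inherits(hist, "decay_histogram"), g > 0)
  ds <- .dark_subtract(hist)
  Ipar <- ds$par; Iperp <- ds$perp
  denom <- Ipar + 2 * g * Iperp
  empty <- denom <= 0
  r <- ifelse(empty, NA_real_, (Ipar - g * Iperp) / denom)
  # delta method on raw Poisson counts (variance = raw counts)
  var_par <- hist$counts_par
  var_perp <- hist$counts_perp
  se <- ifelse(empty, NA_real_,
               sqrt((3 * g * Iperp)^2 * var_par + (3 * g * Ipar)^2 * var_perp) /
                 denom^2)
  structure(
    list(bin_centers_ns = hist$bin_centers_ns, r = r, r_se = se,
         empty = empty, g_used = g, n_clamped = ds$n_clamped,
         bin_width_ns = hist$bin_width_ns),
    class = "anisotropy_decay"
  )
}

#' Total fluorescence intensity decay (lifetime decay)
#'
#' Reconstructs the rotation-free total intensity decay
#' \deqn{F(t) = I_{\parallel}(t) + 2 g I_{\perp}(t)}
#' from dark-subtracted polarized counts. F(t) follows the excited-state
#' population decay regardless of depolarization, which is why homo-FRET
#' leaves it unchanged.
#'
#' @inheritParams time_resolved_anisotropy
#' @return An object of class `lifetime_decay` with `bin_centers_ns`,
#'   `total_intensity`, `se`, `n_clamped`.
#' @export
total_intensity_decay <- function(hist, g = 1) {
  stopifnot(inherits(hist, "decay_histogram"), g > 0)
  ds <- .dark_subtract(hist)
  f <- ds$par + 2 * g * ds$perp
  se <- sqrt(hist$counts_par + (2 * g)^2 * hist$counts_perp)
  structure(
    list(bin_centers_ns = hist$bin_centers_ns, total_intensity = f,
         se = se, g_used = g, n_clamped = ds$n_clamped,
         bin_width_ns = hist$bin_width_ns),
    class = "lifetime_decay"
  )
}

.dark_subtract <- function(hist) {
  par <- hist$counts_par - hist$dark_level_par
  perp <- hist$counts_perp - hist$dark_level_perp
  n_clamped <- sum(par < 0) + sum(perp < 0)
  list(par = pmax(par, 0), perp = pmax(perp, 0), n_clamped = n_clamped)
}

#' Fit a sum of exponentials to a decay
#'
#' Weighted least-squares fit of
#' \deqn{y(t) = \sum_{i=1}^{k} a_i e^{-t/\tau_i} (+\; c)}
#' to an anisotropy or lifetime decay; weights are 1/SE^2. Anisotropy fits
#' include the constant offset c (residual/limiting anisotropy); lifetime
#' fits do not. Pure tail fitting: the default window starts 0.5 ns after the
#' intensity peak so no instrument-response deconvolution is needed.
#'
#' Starting values use log-spaced time constants across the window with
#' amplitudes from a weighted linear solve (the model is linear in amplitudes
#' given the time constants), refined with the Levenberg-Marquardt algorithm.
#'
#' @param decay An `anisotropy_decay` or `lifetime_decay`.
#' @param n_components Number of exponential components (1..3).
#' @param fit_window Numeric `c(t_start, t_end)` in ns; default starts 0.5 ns
#'   after the data peak and ends at the last bin.
#' @param offset Include a constant offset; defaults to `TRUE` for anisotropy
#'   decays and `FALSE` for lifetime decays.
#' @return An object of class `exp_fit`: `amplitudes`, `time_constants_ns`
#'   (sorted ascending, amplitudes reordered to match), `offset`,
#'   `fit_window_ns`, `reduced_chi2`, `n_components`, `n_points`,
#'   `at_bounds` flag.
#' @export
fit_exponential_decay <- function(decay, n_components = 1, fit_window = NULL,
                                  offset = inherits(decay, "anisotropy_decay")) {
  stopifnot(n_components %in% 1:3)
  if (inherits(decay, "anisotropy_decay")) {
    t <- decay$bin_centers_ns; y <- decay$r; se <- decay$r_se
  } else if (inherits(decay, "lifetime_decay")) {
    t <- decay$bin_centers_ns; y <- decay$total_intensity
    se <- pmax(decay$se, 1)   # Poisson floor so empty bins don't blow up
  } else stop("decay must be an anisotropy_decay or lifetime_decay")

  ok <- is.finite(y) & is.finite(se) & se > 0
  if (is.null(fit_window)) {
    peak_t <- t[which.max(if (inherits(decay, "anisotropy_decay"))
      ifelse(ok, y, -Inf) else ifelse(ok, y, -Inf))]
    fit_window <- c(peak_t + 0.5, max(t))
  }
  sel <- ok & t >= fit_window[1] & t <= fit_window[2]
  if (sum(sel) < 10) stop("fewer than 10 usable bins in the fit window")
  t <- t[sel]; y <- y[sel]; w <- 1 / se[sel]^2

  k <- n_components
  amp_solve <- function(log_tau) {
    X <- vapply(exp(log_tau), function(tau) exp(-t / tau), numeric(length(t)))
    if (offset) X <- cbind(X, 1)
    fit <- stats::lm.wfit(X, y, w)
    fit$coefficients
  }
  resid_fun <- function(par) {
    log_tau <- par[seq_len(k)]
    a <- par[k + seq_len(k + offset)]
    X <- vapply(exp(log_tau), function(tau) exp(-t / tau), numeric(length(t)))
    if (offset) X <- cbind(X, 1)
    sqrt(w) * (y - drop(X %*% a))
  }
  span <- fit_window[2] - fit_window[1]
  log_tau0 <- log(exp(seq(log(max(span / 50, 0.2)), log(span * 1.5),
                          length.out = max(k, 2))[seq_len(k)]))
  a0 <- amp_solve(log_tau0)
  a0[is.na(a0)] <- 0
  res <- minpack.lm::nls.lm(
    par = c(log_tau0, a0), fn = resid_fun,
    lower = c(rep(log(1e-3), k), rep(-Inf, k + offset)),
    upper = c(rep(log(1e5), k), rep(Inf, k + offset)),
    control = minpack.lm::nls.lm.control(maxiter = 400)
  )
  if (res$info == 0 || !all(is.finite(res$par)))
    stop(sprintf("exponential fit did not converge (start taus: %s ns)",
                 paste(signif(exp(log_tau0), 3), collapse = ", ")))
  taus <- exp(res$par[seq_len(k)])
  amps <- res$par[k + seq_len(k)]
  off <- if (offset) res$par[2 * k + 1] else 0
  at_bounds <- any(taus <= 1.001e-3 | taus >= 0.999e5)
  if (at_bounds) warning("a fitted time constant hit its bound; fit is suspect")
  o <- order(taus)
  dof <- length(t) - length(res$par)
  structure(
    list(amplitudes = unname(amps[o]), time_constants_ns = unname(taus[o]),
         offset = unname(off),
         fit_window_ns = fit_window,
         reduced_chi2 = sum(res$fvec^2) / max(dof, 1),
         n_components = k, n_points = length(t), at_bounds = at_bounds,
         has_offset = offset),
    class = "exp_fit"
  )
}

#' Evaluate an exponential-fit model
#' @param fit An `exp_fit`.
#' @param t_ns Times in ns.
#' @return Model values.
#' @export
predict_exp_fit <- function(fit, t_ns) {
  stopifnot(inherits(fit, "exp_fit"))
  drop(vapply(fit$time_constants_ns, function(tau) exp(-t_ns / tau),
              numeric(length(t_ns))) %*% fit$amplitudes) + fit$offset
}

#' Choose the number of exponential components
#'
#' Fits 1..`max_components` exponentials and prefers the smaller model unless
#' the reduced chi-square improves by more than 20% *and* the smaller model
#' actually misfits (reduced chi-square > 1.2) - otherwise exact or
#' well-fitted data would be "improved" by meaningless extra components.
#' This mirrors the common practice of accepting a second (fast homo-FRET)
#' component only when it is clearly demanded by the residuals.
#'
#' @inheritParams fit_exponential_decay
#' @param max_components Largest model to consider (2 or 3).
#' @return The selected `exp_fit`, with attribute `candidates` holding all
#'   fitted models.
#' @export
select_exponential_model <- function(decay, max_components = 2,
                                     fit_window = NULL,
                                     offset = inherits(decay, "anisotropy_decay")) {
  fits <- lapply(seq_len(max_components), function(k)
    tryCatch(fit_exponential_decay(decay, k, fit_window, offset),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no exponential model converged")
  best <- fits[[1]]
  for (f in fits[-1]) {
    if (best$reduced_chi2 > 1.2 && f$reduced_chi2 < 0.8 * best$reduced_chi2)
      best <- f
  }
  attr(best, "candidates") <- fits
  best
}

#' Calibrate the g-factor from a fast-rotating dye
#'
#' For a dye whose anisotropy has fully decayed within the tail window (e.g.
#' fluorescein), the true anisotropy there is zero, so g is the ratio of mean
#' parallel to mean perpendicular dark-subtracted counts over the window:
#' the value that makes the tail-window anisotropy vanish.
#'
#' @param hist A `decay_histogram`.
#' @param tail_window_ns `c(t_start, t_end)` in ns over which the anisotropy
#'   is assumed fully decayed.
#' @return The scalar g-factor.
#' @export
calibrate_g_factor <- function(hist, tail_window_ns) {
  stopifnot(inherits(hist, "decay_histogram"), length(tail_window_ns) == 2)
  sel <- hist$bin_centers_ns >= tail_window_ns[1] &
    hist$bin_centers_ns <= tail_window_ns[2]
  if (!any(sel)) stop("tail window contains no bins")
  total <- sum(hist$counts_par[sel]) + sum(hist$counts_perp[sel])
  if (total < 100)
    stop(sprintf("insufficient data: %d counts in tail window (need >= 100)", total))
  ds <- .dark_subtract(hist)
  mp <- mean(ds$par[sel]); mq <- mean(ds$perp[sel])
  if (mq <= 0) stop("no perpendicular signal in tail window")
  mp / mq
}

#' Export an anisotropy decay as TSV
#' @param decay An `anisotropy_decay`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_anisotropy_decay <- function(decay, path) {
  stopifnot(inherits(decay, "anisotropy_decay"))
  utils::write.table(
    data.frame(bin_center_ns = decay$bin_centers_ns, r = decay$r,
               r_se = decay$r_se),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %d component(s), window [%.3g, %.3g] ns\n",
              x$n_components, x$fit_window_ns[1], x$fit_window_ns[2]))
  for (i in seq_len(x$n_components))
    cat(sprintf("  a%d = %.4g, tau%d = %.4g ns\n", i, x$amplitudes[i], i,
                x$time_constants_ns[i]))
  if (x$has_offset) cat(sprintf("  offset = %.4g\n", x$offset))
  cat(sprintf("  reduced chi2 = %.4g on %d points\n", x$reduced_chi2, x$n_points))
  invisible(x)
}
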