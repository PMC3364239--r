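# Shared bin-grid convention for both correlators
# ------------------------------------------------
# The acquisition (or one segment of it) is divided into base bins of width
# `base_lag` seconds; a photon at time t (relative to the segment start) has
# base index floor(t / base_lag). Level l uses bins of width base_lag * 2^l,
# and a photon's level-l index is its base index integer-divided by 2^l, so
# every implementation agrees bit-exactly about which bin a photon occupies.
# Level 0 carries lags 1..2m (m = points_per_octave), every deeper level lags
# m+1..2m at doubled width; levels are added while at least 4m bins remain.
#
# The normalized estimator at level width w, integer count arrays a, b of
# length n and integer lag k is
#   G = num * M / (Sa * Sb) - 1,   M = n - k,
#   num = sum_{i=1}^{M} a_i b_{i+k},  Sa = sum_{i=1}^{M} a_i,
#   Sb = sum_{i=k+1}^{n} b_i
# (symmetric normalization: each series is averaged over the window it
# actually contributes to).

.mt_levels <- function(n0, points_per_octave) {
  m <- points_per_octave
  levels <- list(list(level = 0L, k = 1:(2L * m)))
  l <- 1L
  while (floor(n0 / 2^l) >= 4L * m) {
    levels[[l + 1L]] <- list(level = l, k = (m + 1L):(2L * m))
    l <- l + 1L
  }
  levels
}

#' Multi-tau lag grid
#'
#' The quasi-logarithmic lag grid used by [multitau_correlate()]: level 0
#' holds lags `1..2m` at the base width, each subsequent level lags `m+1..2m`
#' at twice the previous width, for as long as at least `4m` bins of the
#' segment remain.
#'
#' @param segment_s Segment duration in seconds.
#' @param base_lag_s Base bin width / smallest lag (s).
#' @param points_per_octave Lags per octave m.
#' @return Data frame with columns `level`, `k`, `width_s`, `lag_s`.
#' @export
multitau_lag_grid <- function(segment_s, base_lag_s = 1e-6,
                              points_per_octave = 8L) {
  n0 <- floor(segment_s / base_lag_s)
  lv <- .mt_levels(n0, points_per_octave)
  do.call(rbind, lapply(lv, function(x)
    data.frame(level = x$level, k = x$k, width_s = base_lag_s * 2^x$level,
               lag_s = x$k * base_lag_s * 2^x$level)))
}

.mt_estimate <- function(a, b, k) {
  n <- length(a)
  M <- n - k
  if (M < 1) return(NA_real_)
  Sa <- sum(a[1:M])
  Sb <- sum(b[(k + 1):n])
  if (Sa == 0 || Sb == 0) return(NA_real_)
  num <- sum(a[1:M] * b[(k + 1):n])
  num * M / (Sa * Sb) - 1
}

# multi-tau correlation of one segment: progressive pairwise rebinning
.mt_segment <- function(idx0_a, idx0_b, n0, points_per_octave) {
  a <- as.numeric(tabulate(idx0_a + 1L, nbins = n0))
  b <- as.numeric(tabulate(idx0_b + 1L, nbins = n0))
  lv <- .mt_levels(n0, points_per_octave)
  out <- numeric(0)
  for (x in lv) {
    if (x$level > 0L) {
      n <- 2L * (length(a) %/% 2L)
      a <- a[seq(1L, n, by = 2L)] + a[seq(2L, n, by = 2L)]
      b <- b[seq(1L, n, by = 2L)] + b[seq(2L, n, by = 2L)]
    }
    out <- c(out, vapply(x$k, function(k) .mt_estimate(a, b, k), 1.0))
  }
  out
}

#' Multi-tau correlation of photon arrival streams
#'
#' Computes the normalized auto- or cross-correlation
#' \deqn{G(\tau) = \langle \delta F_A(t)\, \delta F_B(t+\tau)\rangle /
#'       (\langle F_A\rangle \langle F_B\rangle)}
#' of the macro-time photon streams of two channels on a quasi-logarithmic
#' multi-tau grid: arrival times are binned at the base lag and the count
#' series is rebinned (bin width doubling every `points_per_octave` lags) as
#' the lag grows. Cross-correlating the parallel and perpendicular detectors
#' (`chA != chB`) is free of detector artifacts such as afterpulsing.
#'
#' The acquisition is split into `n_segments` equal segments; the reported
#' curve is the mean of the per-segment curves and `G_se` the standard error
#' of that mean.
#'
#' @param stream A [photon_stream()].
#' @param chA,chB Channel of the first/second series (`"parallel"`,
#'   `"perpendicular"`).
#' @param base_lag_s Base bin width / smallest lag (s).
#' @param points_per_octave Lags per octave.
#' @param n_segments Number of segments for error estimation (>= 1).
#' @return An object of class `correlation_curve`: `lags_s`, `G`, `G_se`,
#'   `kind` (`"auto_par"`, `"auto_perp"` or `"cross"`), `mean_rates` (cps per
#'   channel), `duration_s`, `grid` (the lag-grid data frame), plus the
#'   parameters used. Lags whose estimate is undefined in any segment (empty
#'   rebinned window) are dropped.
#' @export
multitau_correlate <- function(stream, chA = "parallel", chB = "perpendicular",
                               base_lag_s = 1e-6, points_per_octave = 8L,
                               n_segments = 10L) {
  stopifnot(inherits(stream, "photon_stream"), base_lag_s > 0,
            points_per_octave >= 2, n_segments >= 1)
  ta <- arrival_times(stream, chA)
  tb <- if (identical(chA, chB)) ta else arrival_times(stream, chB)
  if (length(ta) == 0 || length(tb) == 0)
    stop("empty channel: cannot correlate")
  seg_dur <- stream$duration_s / n_segments
  n0 <- floor(seg_dur / base_lag_s)
  m <- as.integer(points_per_octave)
  if (n0 < 4L * m)
    stop(sprintf(
      "duration too short: need >= %.3g s (%d segments of %d base bins)",
      4 * m * base_lag_s * n_segments, n_segments, 4L * m))
  grid <- multitau_lag_grid(seg_dur, base_lag_s, m)
  per_seg <- matrix(NA_real_, n_segments, nrow(grid))
  for (s in seq_len(n_segments)) {
    t0 <- (s - 1) * seg_dur
    in_a <- ta >= t0 & ta < t0 + seg_dur
    in_b <- tb >= t0 & tb < t0 + seg_dur
    ia <- floor((ta[in_a] - t0) / base_lag_s)
    ib <- floor((tb[in_b] - t0) / base_lag_s)
    ia <- ia[ia < n0]; ib <- ib[ib < n0]
    per_seg[s, ] <- .mt_segment(ia, ib, n0, m)
  }
  ok <- colSums(is.na(per_seg)) == 0L
  G <- colMeans(per_seg)[ok]
  G_se <- if (n_segments > 1)
    apply(per_seg[, ok, drop = FALSE], 2, stats::sd) / sqrt(n_segments)
  else rep(NA_real_, sum(ok))
  kind <- if (identical(chA, chB)) {
    if (channel_code(chA) == .CH_PAR) "auto_par" else "auto_perp"
  } else "cross"
  structure(
    list(lags_s = grid$lag_s[ok], G = G, G_se = G_se, kind = kind,
         mean_rates = c(parallel = count_rate(stream, "parallel"),
                        perpendicular = count_rate(stream, "perpendicular")),
         duration_s = stream$duration_s, base_lag_s = base_lag_s,
         points_per_octave = m, n_segments = as.integer(n_segments),
         grid = grid[ok, , drop = FALSE]),
    class = "correlation_curve"
  )
}

#' Brute-force direct correlator (testing oracle)
#'
#' Computes the same normalized correlation estimator as
#' [multitau_correlate()] by explicit per-lag time binning: for every lag the
#' photon times are binned from scratch at that lag's bin width and the lag
#' products are accumulated in a plain loop. No progressive rebinning, no
#' shared state between lags. It is deliberately slow and refuses large
#' streams; its purpose is to cross-validate the multi-tau bookkeeping
#' bit-for-bit.
#'
#' @param stream A [photon_stream()].
#' @param chA,chB Channels as in [multitau_correlate()].
#' @param lag_grid Data frame with columns `level`, `k`, `width_s`, `lag_s`
#'   (see [multitau_lag_grid()]); also accepts a `correlation_curve`, whose
#'   grid and base lag are then reused.
#' @param base_lag_s Base bin width; taken from `lag_grid` if it is a curve.
#' @return A `correlation_curve` (single segment, no SE).
#' @export
direct_correlate <- function(stream, chA = "parallel", chB = "perpendicular",
                             lag_grid, base_lag_s = NULL) {
  stopifnot(inherits(stream, "photon_stream"))
  if (inherits(lag_grid, "correlation_curve")) {
    base_lag_s <- lag_grid$base_lag_s
    lag_grid <- lag_grid$grid
  }
  if (is.null(base_lag_s)) stop("base_lag_s is required with a raw lag grid")
  if (nrow(stream$records) > 1e5)
    stop("direct_correlate is a brute-force oracle: refuse streams > 1e5 photons")
  ta <- arrival_times(stream, chA)
  tb <- if (identical(chA, chB)) ta else arrival_times(stream, chB)
  if (length(ta) == 0 || length(tb) == 0) stop("empty channel: cannot correlate")
  n0 <- floor(stream$duration_s / base_lag_s)
  ia0 <- floor(ta / base_lag_s); ia0 <- ia0[ia0 < n0]
  ib0 <- floor(tb / base_lag_s); ib0 <- ib0[ib0 < n0]
  G <- numeric(nrow(lag_grid))
  for (j in seq_len(nrow(lag_grid))) {
    l <- lag_grid$level[j]; k <- lag_grid$k[j]
    n <- n0 %/% 2^l
    ia <- ia0 %/% 2^l; ib <- ib0 %/% 2^l
    a <- numeric(n); b <- numeric(n)
    for (i in seq_along(ia)) if (ia[i] < n) a[ia[i] + 1] <- a[ia[i] + 1] + 1
    for (i in seq_along(ib)) if (ib[i] < n) b[ib[i] + 1] <- b[ib[i] + 1] + 1
    M <- n - k
    if (M < 1) { G[j] <- NA_real_; next }
    num <- 0; Sa <- 0; Sb <- 0
    for (i in seq_len(M)) {
      num <- num + a[i] * b[i + k]
      Sa <- Sa + a[i]
      Sb <- Sb + b[i + k]
    }
    G[j] <- if (Sa == 0 || Sb == 0) NA_real_ else num * M / (Sa * Sb) - 1
  }
  ok <- is.finite(G)
  structure(
    list(lags_s = lag_grid$lag_s[ok], G = G[ok], G_se = rep(NA_real_, sum(ok)),
         kind = if (identical(chA, chB)) {
           if (channel_code(chA) == .CH_PAR) "auto_par" else "auto_perp"
         } else "cross",
         mean_rates = c(parallel = count_rate(stream, "parallel"),
                        perpendicular = count_rate(stream, "perpendicular")),
         duration_s = stream$duration_s, base_lag_s = base_lag_s,
         points_per_octave = NA_integer_, n_segments = 1L,
         grid = lag_grid[ok, , drop = FALSE]),
    class = "correlation_curve"
  )
}

.diffusion_G <- function(tau, N, tau_D, ratio, gamma) {
  (gamma / N) / ((1 + tau / tau_D) * sqrt(1 + ratio^2 * tau / tau_D))
}

#' Fit the single-component two-photon 3-D Gaussian diffusion model
#'
#' Weighted least-squares fit of
#' \deqn{G(\tau) = \frac{\gamma}{\langle N\rangle}
#'   \left(1 + \frac{\tau}{\tau_D}\right)^{-1}
#'   \left(1 + \left(\frac{\omega}{z}\right)^2 \frac{\tau}{\tau_D}\right)^{-1/2}}
#' to a correlation curve, yielding the mean number of molecules in the
#' observation volume `<N>` and the diffusion correlation time `tau_D`.
#' `gamma` is the PSF shape constant, 0.35 for a two-photon 3-D Gaussian, and
#' is never fitted. The beam-waist ratio omega/z can be held fixed (the
#' calibrated value) or fitted.
#'
#' @param curve A `correlation_curve`.
#' @param gamma PSF shape constant (fixed).
#' @param omega_z_ratio Either a fixed numeric ratio in (0, 1) or `NULL` to
#'   fit it.
#' @param lag_window `c(min, max)` lag in seconds; default
#'   `[base_lag, duration/100]`.
#' @param baseline `"free"` (default) fits an additive constant alongside the
#'   model; `"zero"` pins it. Finite-acquisition estimators carry a small
#'   lag-independent negative offset (the measured mean used for
#'   normalization is itself correlated with the fluctuations), and a free
#'   baseline absorbs it; with noiseless model data it converges to zero, so
#'   exact recovery is unaffected.
#' @return An object of class `diffusion_fit`: `N_mean`, `tau_D_s`,
#'   `omega_z_ratio`, `ratio_fitted`, `gamma`, `baseline`, `reduced_chi2`,
#'   `se` (named vector), `G0_model` = gamma/N, `G0_curve` (mean of the three
#'   smallest-lag points), `n_lags`.
#' @export
fit_diffusion_model <- function(curve, gamma = 0.35, omega_z_ratio = 0.15,
                                lag_window = NULL,
                                baseline = c("free", "zero")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(curve, "correlation_curve"), gamma > 0)
  if (is.null(lag_window))
    lag_window <- c(min(curve$lags_s), curve$duration_s / 100)
  sel <- curve$lags_s >= lag_window[1] & curve$lags_s <= lag_window[2] &
    is.finite(curve$G)
  if (sum(sel) < 20)
    stop(sprintf("only %d lags in fit window; need >= 20", sum(sel)))
  tau <- curve$lags_s[sel]; G <- curve$G[sel]; se <- curve$G_se[sel]
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, length(G))
  ratio_free <- is.null(omega_z_ratio) || is.na(omega_z_ratio)

  G1 <- mean(G[seq_len(min(3, length(G)))])
  if (!is.finite(G1) || G1 <= 0) G1 <- max(G[G > 0], na.rm = TRUE)
  N0 <- max(gamma / G1, 1e-3)
  tauD0 <- tau[which.min(abs(G - G1 / 2))]
  if (!is.finite(tauD0) || tauD0 <= 0) tauD0 <- stats::median(tau)

  base_free <- baseline == "free"
  resid_fun <- function(par) {
    N <- exp(par[1]); tD <- exp(par[2])
    ratio <- if (ratio_free) stats::plogis(par[3]) else omega_z_ratio
    b <- if (base_free) par[2 + ratio_free + 1] else 0
    sqrt(w) * (G - .diffusion_G(tau, N, tD, ratio, gamma) - b)
  }
  par0 <- c(log(N0), log(tauD0), if (ratio_free) stats::qlogis(0.2),
            if (base_free) 0)
  res <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  if (res$info == 0 || !all(is.finite(res$par)))
    stop(sprintf("diffusion fit did not converge (starts: N = %.3g, tau_D = %.3g s)",
                 N0, tauD0))
  N <- exp(res$par[1]); tau_D <- exp(res$par[2])
  ratio <- if (ratio_free) stats::plogis(res$par[3]) else omega_z_ratio
  base <- if (base_free) res$par[2 + ratio_free + 1] else 0
  dof <- max(length(G) - length(res$par), 1)
  s2 <- sum(res$fvec^2) / dof
  cv <- tryCatch(solve(res$hessian) * s2, error = function(e) NULL)
  se_out <- c(N_mean = NA_real_, tau_D_s = NA_real_)
  if (!is.null(cv)) {
    # delta method back from log scale
    se_out["N_mean"] <- sqrt(abs(cv[1, 1])) * N
    se_out["tau_D_s"] <- sqrt(abs(cv[2, 2])) * tau_D
  }
  structure(
    list(N_mean = N, tau_D_s = tau_D, omega_z_ratio = ratio,
         ratio_fitted = ratio_free, gamma = gamma, baseline = base,
         reduced_chi2 = s2, se = se_out,
         G0_model = gamma / N, G0_curve = G1,
         n_lags = length(G), lag_window_s = lag_window),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> <N> = %.4g, tau_D = %.4g s, omega/z = %.3g%s\n",
              x$N_mean, x$tau_D_s, x$omega_z_ratio,
              if (x$ratio_fitted) " (fitted)" else " (fixed)"))
  cat(sprintf("  gamma = %.3g (fixed), reduced chi2 = %.3g on %d lags\n",
              x$gamma, x$reduced_chi2, x$n_lags))
  cat(sprintf("  G(0) model %.4g vs curve %.4g\n", x$G0_model, x$G0_curve))
  invisible(x)
}

#' Average replicate correlation curves
#'
#' Replicate measurements of the same sample are commonly averaged before
#' fitting. Curves must share a lag grid; otherwise they are resampled onto
#' the first curve's grid by interpolation in log-lag, with a warning.
#'
#' @param curves List of `correlation_curve` objects.
#' @return A `correlation_curve` whose `G` is the mean and `G_se` the standard
#'   error over replicates.
#' @export
average_correlation_curves <- function(curves) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "correlation_curve")))
  ref <- curves[[1]]
  Gs <- vapply(curves, function(cv) {
    if (length(cv$lags_s) == length(ref$lags_s) &&
        all(cv$lags_s == ref$lags_s)) return(cv$G)
    warning("inconsistent lag grids: resampling onto the first curve's grid")
    stats::approx(log(cv$lags_s), cv$G, xout = log(ref$lags_s), rule = 2)$y
  }, numeric(length(ref$lags_s)))
  Gs <- matrix(Gs, nrow = length(ref$lags_s))
  out <- ref
  out$G <- rowMeans(Gs)
  out$G_se <- if (length(curves) > 1)
    apply(Gs, 1, stats::sd) / sqrt(length(curves)) else ref$G_se
  out
}

#' Global fit of a dilution series
#'
#' Fits the two-photon 3-D Gaussian diffusion model jointly to correlation
#' curves from a dilution series of one species: the beam-waist ratio omega/z
#' and the correlation time tau_D are shared across curves (constant power,
#' constant geometry, same molecule), while `<N>` is free per curve. This is
#' the standard way to calibrate omega/z from known dilutions.
#'
#' @param curves List of >= 3 `correlation_curve` objects.
#' @param gamma PSF shape constant (fixed).
#' @param lag_window Optional shared lag window (s).
#' @return An object of class `dilution_fit`: `omega_z_ratio`, `tau_D_s`,
#'   `N_mean` (one per curve), `reduced_chi2`, `se` for the shared
#'   parameters.
#' @export
global_fit_dilution_series <- function(curves, gamma = 0.35, lag_window = NULL,
                                       baseline = c("free", "zero")) {
  baseline <- match.arg(baseline)
  stopifnot(length(curves) >= 3,
            all(vapply(curves, inherits, TRUE, "correlation_curve")))
  ref <- curves[[1]]
  same_grid <- all(vapply(curves, function(cv)
    length(cv$lags_s) == length(ref$lags_s) && all(cv$lags_s == ref$lags_s), TRUE))
  if (!same_grid) {
    warning("inconsistent lag grids: resampling onto the first curve's grid")
    curves <- lapply(curves, function(cv) {
      if (identical(cv$lags_s, ref$lags_s)) return(cv)
      cv$G <- stats::approx(log(cv$lags_s), cv$G, xout = log(ref$lags_s), rule = 2)$y
      cv$G_se <- rep(NA_real_, length(ref$lags_s))
      cv$lags_s <- ref$lags_s
      cv
    })
  }
  if (is.null(lag_window))
    lag_window <- c(min(ref$lags_s), ref$duration_s / 100)
  sel <- ref$lags_s >= lag_window[1] & ref$lags_s <= lag_window[2]
  tau <- ref$lags_s[sel]
  nc <- length(curves)
  Gm <- vapply(curves, function(cv) cv$G[sel], numeric(sum(sel)))
  Wm <- vapply(curves, function(cv) {
    se <- cv$G_se[sel]
    if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, sum(sel))
  }, numeric(sum(sel)))

  N0 <- pmax(gamma / pmax(Gm[1, ], 1e-12), 1e-3)
  tauD0 <- tau[which.min(abs(Gm[, 1] - Gm[1, 1] / 2))]
  base_free <- baseline == "free"
  resid_fun <- function(par) {
    ratio <- stats::plogis(par[1]); tD <- exp(par[2])
    Ns <- exp(par[2 + seq_len(nc)])
    bs <- if (base_free) par[2 + nc + seq_len(nc)] else rep(0, nc)
    unlist(lapply(seq_len(nc), function(j)
      sqrt(Wm[, j]) * (Gm[, j] - .diffusion_G(tau, Ns[j], tD, ratio, gamma) -
                         bs[j])))
  }
  res <- minpack.lm::nls.lm(par = c(stats::qlogis(0.2), log(tauD0), log(N0),
                                    if (base_free) rep(0, nc)),
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 600))
  if (res$info == 0 || !all(is.finite(res$par)))
    stop("global dilution fit did not converge")
  ratio <- stats::plogis(res$par[1]); tau_D <- exp(res$par[2])
  Ns <- exp(res$par[2 + seq_len(nc)])
  dof <- max(length(res$fvec) - length(res$par), 1)
  s2 <- sum(res$fvec^2) / dof
  cv <- tryCatch(solve(res$hessian) * s2, error = function(e) NULL)
  se_shared <- c(omega_z_ratio = NA_real_, tau_D_s = NA_real_)
  if (!is.null(cv)) {
    se_shared["omega_z_ratio"] <- sqrt(abs(cv[1, 1])) * ratio * (1 - ratio)
    se_shared["tau_D_s"] <- sqrt(abs(cv[2, 2])) * tau_D
  }
  structure(
    list(omega_z_ratio = ratio, tau_D_s = tau_D, N_mean = Ns,
         gamma = gamma, reduced_chi2 = s2, se = se_shared,
         n_curves = nc, lag_window_s = lag_window),
    class = "dilution_fit"
  )
}

#' Export a correlation curve as TSV
#' @param curve A `correlation_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_correlation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  utils::write.table(
    data.frame(lag_s = curve$lags_s, G = curve$G, G_se = curve$G_se),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.correlation_curve <- function(x, ..., fit = NULL) {
  graphics::plot(x$lags_s, x$G, log = "x", xlab = "lag (s)",
                 ylab = "G(tau)", pch = 16, cex = 0.6, ...)
  if (!is.null(x$G_se) && any(is.finite(x$G_se)))
    graphics::segments(x$lags_s, x$G - x$G_se, x$lags_s, x$G + x$G_se,
                       col = "grey60")
  if (inherits(fit, "diffusion_fit"))
    graphics::lines(x$lags_s, .diffusion_G(x$lags_s, fit$N_mean, fit$tau_D_s,
                                           fit$omega_z_ratio, fit$gamma),
                    col = "red")
  invisible(x)
}

#' @export
plot.anisotropy_decay <- function(x, ...) {
  graphics::plot(x$bin_centers_ns, x$r, xlab = "time (ns)", ylab = "r(t)",
                 pch = 16, cex = 0.5, ...)
  invisible(x)
}
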