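# Binomial donor-fraction pairing model for hetero-FRET.
#
# If subunits carrying a donor (fraction p) or an acceptor (fraction 1 - p)
# pair at random, donor-donor pairs occur at p^2, acceptor-acceptor at
# (1 - p)^2 and mixed pairs at 2 p (1 - p). Only donors report FRET: a donor
# in a mixed pair transfers with pairwise efficiency E, a donor paired with
# another donor transfers nothing. Averaging over donors gives the observed
# ensemble efficiency E_obs = E (1 - p) - linear in p, with slope -E and
# intercept E. That signature (intercept = -slope) is the test for exclusive
# 1 donor : 1 acceptor pairing.

#' Expected ensemble FRET efficiency under random pairing
#'
#' @param p Fraction donor in `[0, 1]`.
#' @param E Pairwise FRET efficiency in `[0, 1]`.
#' @return Expected observed efficiency `E (1 - p)`.
#' @export
expected_fret <- function(p, E) {
  stopifnot(all(p >= 0 & p <= 1), all(E >= 0 & E <= 1))
  E * (1 - p)
}

#' Fit the pairing model to per-cell (fraction donor, E_obs) points
#'
#' Linear regression of the observed FRET efficiency on the donor fraction.
#' Under exclusive 1:1 pairing the intercept (E_obs at p = 0) and the negated
#' slope both estimate the pairwise efficiency E; the fit reports both and a
#' consistency statistic `(intercept + slope) / SE`, warning when it exceeds
#' 3 (model violation, e.g. unpaired subunits giving a flat E_obs).
#'
#' @param p Fraction donor per cell.
#' @param E_obs Observed ensemble FRET efficiency per cell (slightly negative
#'   values from measurement noise are allowed and flagged).
#' @param weights Optional regression weights (default unweighted).
#' @return An object of class `pairing_fit`: `E` (from the intercept),
#'   `E_se`, `slope`, `slope_se`, `intercept`, `consistency_z`,
#'   `model_violation`, `n`, the `lm` fit.
#' @export
fit_pairing_model <- function(p, E_obs, weights = NULL) {
  stopifnot(length(p) == length(E_obs))
  if (length(p) < 3) stop("need >= 3 points")
  if (diff(range(p)) < 0.2)
    stop(sprintf("degenerate donor-fraction range (%.3g); need a span >= 0.2",
                 diff(range(p))))
  if (any(p < 0 | p > 1)) stop("fraction donor must lie in [0, 1]")
  n_neg <- sum(E_obs < 0)
  if (n_neg) warning(n_neg, " point(s) with negative E_obs (measurement noise)")
  d <- data.frame(p = p, E_obs = E_obs)
  fit <- if (is.null(weights)) stats::lm(E_obs ~ p, data = d)
         else stats::lm(E_obs ~ p, data = d, weights = weights)
  co <- stats::coef(fit); V <- stats::vcov(fit)
  intercept <- unname(co[1]); slope <- unname(co[2])
  # intercept + slope should be 0 under the pairing model
  se_sum <- sqrt(max(V[1, 1] + V[2, 2] + 2 * V[1, 2], 0))
  z <- (intercept + slope) / se_sum
  # the absolute floor keeps an exact fit (0/epsilon) from tripping the check
  violation <- is.finite(z) && abs(z) > 3 && abs(intercept + slope) > 1e-8
  if (violation)
    warning(sprintf(
      "pairing-model violation: intercept (%.3g) and -slope (%.3g) disagree by %.1f sigma",
      intercept, -slope, abs(z)))
  structure(
    list(E = intercept, E_se = sqrt(V[1, 1]),
         slope = slope, slope_se = sqrt(V[2, 2]),
         intercept = intercept, consistency_z = z,
         model_violation = violation, n = length(p), lm = fit),
    class = "pairing_fit"
  )
}

#' @export
print.pairing_fit <- function(x, ...) {
  cat(sprintf("<pairing_fit> E = %.4g +- %.2g (intercept), slope = %.4g +- %.2g, n = %d\n",
              x$E, x$E_se, x$slope, x$slope_se, x$n))
  cat(sprintf("  intercept vs -slope consistency: %.2f sigma%s\n",
              abs(x$consistency_z),
              if (x$model_violation) "  ** model violation **" else ""))
  invisible(x)
}

#' Monte-Carlo ensemble of randomly paired donors/acceptors
#'
#' Simulates one measurement (one cell): `2 n_pairs` subunits are labelled
#' donor independently with probability `p`, paired off at random, and the
#' observed efficiency is the pooled per-donor mean: donors in mixed pairs
#' contribute E, donors paired with donors contribute 0. Realizations with
#' zero donors are redrawn (and `p = 0` is rejected, since the ensemble is
#' then undefined - use [expected_fret()] for the limit).
#'
#' @param n_pairs Number of subunit pairs (>= 1).
#' @param p Donor labelling probability in (0, 1].
#' @param E Pairwise FRET efficiency.
#' @return Scalar observed ensemble efficiency for the realization.
#' @export
simulate_random_pairing <- function(n_pairs, p, E) {
  stopifnot(n_pairs >= 1, p >= 0, p <= 1, E >= 0, E <= 1)
  if (p == 0)
    stop("p = 0 gives no donors; the limiting value is expected_fret(0, E) = E")
  for (attempt in 1:1000) {
    lab <- stats::runif(2 * n_pairs) < p       # iid labels == random pairing
    d1 <- lab[seq(1, 2 * n_pairs, by = 2)]
    d2 <- lab[seq(2, 2 * n_pairs, by = 2)]
    n_donors <- sum(d1) + sum(d2)
    if (n_donors == 0) next
    # donors in mixed pairs transfer E; donor-donor pairs transfer 0
    mixed_donors <- sum(d1 & !d2) + sum(!d1 & d2)
    return(E * mixed_donors / n_donors)
  }
  stop("failed to draw a realization with at least one donor")
}

#' Read a (fraction donor, E_obs) points table
#' @param path TSV with columns `p`, `E_obs` and optional `weight`.
#' @return Data frame.
#' @export
read_fret_points <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("p", "E_obs") %in% names(d)))
    stop("points table must have columns 'p' and 'E_obs'")
  d
}
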