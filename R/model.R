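#' czdown: critical slowing down biomarkers and seizure forecasting
#'
#' The package models seizure onset as a saddle-node (fold) transition of a
#' driven bistable system, extracts the classical early-warning signatures of
#' an approaching fold -- growing autocorrelation width and variance -- from
#' periodic short iEEG snapshots, and converts the circadian/multidien
#' modulation of those biomarkers into a three-state seizure-risk forecast.
#'
#' Time conventions used throughout: the slow dynamics run in hours (one model
#' time-unit = 1 h), record-level timestamps are hours from record start, and
#' within-segment sampling is in seconds at `segment_rate_hz`.
#'
#' @useDynLib czdown, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

# Cubic state model: dz/dt = -z^3 + 1e-3*r*z + 1e-3*k.
# All closed forms below follow from that right-hand side.

#' Saddle-node folds of the bistable state model
#'
#' The model `dz/dt = -z^3 + 1e-3 r z + 1e-3 k` has two folds where a stable
#' and the unstable equilibrium coalesce: `z* = +/- sqrt(1e-3 r / 3)` and
#' `k* = 1e3 z*^3 - r z*`. At each fold both the vector field and its
#' derivative with respect to `z` vanish.
#'
#' @param r Dimensionless bifurcation-shape parameter, `r > 0`.
#' @return A data.frame with one row per fold and columns `z_star`, `k_star`.
#' @examples
#' critical_point(500)
#' @export
critical_point <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("invalid parameter: r must be a single positive number (no fold exists for r <= 0)")
  z <- sqrt(1e-3 * r / 3)
  k <- 1e3 * z^3 - r * z
  data.frame(z_star = c(z, -z), k_star = c(k, -k))
}

#' Linearized relaxation time constant at an equilibrium
#'
#' Linearizing the cubic model about an equilibrium `z_eq` gives
#' `d(delta z)/dt = (-3 z_eq^2 + 1e-3 r) * delta z`; for a stable equilibrium
#' the bracket is negative and the relaxation time constant is its reciprocal
#' magnitude. The time constant diverges as `z_eq` approaches a fold --
#' the defining signature of critical slowing down.
#'
#' @param z_eq Equilibrium state value (must lie on a stable branch).
#' @param r Bifurcation-shape parameter.
#' @return Time constant in model time-units (hours).
#' @export
linearized_time_constant <- function(z_eq, r) {
  d <- -3 * z_eq^2 + 1e-3 * r
  if (any(d >= 0))
    stop("non-finite time constant: equilibrium is unstable or critical (derivative >= 0)")
  1 / abs(d)
}

# Real equilibria of z^3 - p z - q = 0 with p = 1e-3*r, q = 1e-3*k,
# solved per element by the trigonometric/hyperbolic method. Returns a list
# of vectors: lower/upper stable branches and the unstable middle branch
# (NA where the branch does not exist for that k).
equilibrium_branches <- function(k, r) {
  p <- 1e-3 * r
  q <- 1e-3 * k
  n <- length(q)
  lower <- upper <- mid <- rep(NA_real_, n)
  # three real roots iff 4 p^3 > 27 q^2 (p > 0 here)
  disc <- 4 * p^3 - 27 * q^2
  m <- 2 * sqrt(p / 3)
  tri <- disc > 0
  if (any(tri)) {
    arg <- pmin(1, pmax(-1, (3 * q[tri] / (2 * p)) * sqrt(3 / p)))
    phi <- acos(arg)
    r0 <- m * cos(phi / 3)              # largest root
    r1 <- m * cos(phi / 3 - 2 * pi / 3) # smallest
    r2 <- m * cos(phi / 3 - 4 * pi / 3) # middle
    upper[tri] <- r0
    lo <- pmin(r1, r2)
    md <- pmax(r1, r2)
    lower[tri] <- lo
    mid[tri]   <- md
  }
  if (any(!tri)) {
    # single real root (hyperbolic form)
    qq <- q[!tri]
    t0 <- 3 * abs(qq) / (2 * p) * sqrt(3 / p)
    root <- sign(qq) * m * cosh(acosh(t0) / 3)
    up <- qq > 0
    upper[!tri][up]  <- root[up]
    lower[!tri][!up] <- root[!up]
  }
  list(lower = lower, upper = upper, unstable = mid)
}

# Drive k(t): baseline + circadian and multidien sinusoids, or a linear ramp
# when config$k_ramp = c(from, to) is set (used for fold-approach sweeps).
drive_trace <- function(times_h, config) {
  if (!is.null(config$k_ramp)) {
    span <- max(times_h) - min(times_h)
    if (span <= 0) span <- 1
    return(config$k_ramp[1] +
             (config$k_ramp[2] - config$k_ramp[1]) * (times_h - min(times_h)) / span)
  }
  config$k_baseline +
    config$k_circadian_amp * cos(2 * pi * times_h / config$circadian_period_h +
                                   config$circadian_phase0) +
    config$k_multidien_amp * cos(2 * pi * times_h / (24 * config$multidien_period_d) +
                                   config$multidien_phase0)
}

#' Integrate the driven bistable state equation
#'
#' Euler--Maruyama integration of
#' `dz = (-z^3 + 1e-3 r z + 1e-3 k(t)) dt + noise_sd dW`
#' with `k(t)` the configured circadian + multidien drive (or ramp). When the
#' state crosses the unstable branch upward a seizure starts: the trajectory
#' is held for a drawn ictal duration, then reset to the lower stable branch,
#' and crossing detection is suppressed for the refractory period.
#'
#' @param config A [sim_config()] list.
#' @return A list of class `state_trajectory` with `times_h`, `z`, `k`,
#'   `onsets_h`, `durations_s` and the fold locations.
#' @export
simulate_state <- function(config) {
  validate_sim_config(config)
  dt <- config$dt
  n <- floor(config$duration_days * 24 / dt) + 1L
  times <- (seq_len(n) - 1) * dt
  k <- drive_trace(times, config)
  br <- equilibrium_branches(k, config$r)
  zf <- sqrt(1e-3 * config$r / 3) # fold state value
  # crossing threshold: unstable branch where it exists, else the fold value
  zth <- ifelse(is.na(br$unstable), zf, br$unstable)

  z <- numeric(n)
  # start interictal: lower stable branch, or just below the vanished fold
  z[1] <- if (is.null(config$z0)) {
    if (is.na(br$lower[1])) -zf else br$lower[1]
  } else config$z0

  rng <- local_rng(config$seed, "state")
  noise <- if (config$noise_sd > 0)
    rng$rnorm(n) * config$noise_sd * sqrt(dt) else numeric(n)
  # pre-drawn pool of ictal durations (consumed in crossing order)
  dur_pool_s <- config$seizure_duration_s *
    exp(rng$rnorm(2048) * config$seizure_duration_sdlog)
  dur_pool_steps <- pmax(1L, as.integer(ceiling((dur_pool_s / 3600) / dt)))

  refr_steps <- as.integer(ceiling(config$refractory_min / 60 / dt))
  zlo <- ifelse(is.na(br$lower), -zf, br$lower)
  em <- .em_integrate(z[1], dt, config$r, k, noise, zth, zlo,
                      dur_pool_steps, refr_steps, 10)
  z <- em$z
  onsets <- times[em$onset_idx]
  durations <- dur_pool_s[seq_along(em$onset_idx)]
  structure(list(times_h = times, z = z, k = k,
                 onsets_h = onsets, durations_s = durations,
                 z_fold = zf, z_threshold = zth, branches = br,
                 config = config),
            class = "state_trajectory")
}

#' Extract the seizure catalog from a state trajectory
#'
#' Detects upward crossings of the unstable branch in the integrated
#' trajectory, merges re-detections within the refractory period, and
#' measures each event's duration as the time spent above the branch.
#'
#' @param trajectory A `state_trajectory` from [simulate_state()].
#' @param config The simulator configuration (refractory period).
#' @return A data.frame `seizure_catalog` with `onset_h` (strictly
#'   increasing) and `duration_s`.
#' @export
label_seizures <- function(trajectory, config = trajectory$config) {
  z <- trajectory$z
  zth <- trajectory$z_threshold
  above <- z > zth
  n <- length(z)
  ups <- which(!above[-n] & above[-1]) + 1L
  dt <- trajectory$times_h[2] - trajectory$times_h[1]
  refr_h <- config$refractory_min / 60
  onsets <- numeric(0); durations <- numeric(0)
  last_end <- -Inf
  for (i in ups) {
    t0 <- trajectory$times_h[i]
    if (t0 < last_end + refr_h) next
    j <- i
    while (j < n && above[j + 1L]) j <- j + 1L
    dur_h <- (j - i + 1L) * dt
    onsets <- c(onsets, t0)
    durations <- c(durations, dur_h * 3600)
    last_end <- t0 + dur_h
  }
  structure(data.frame(onset_h = onsets, duration_s = durations),
            class = c("seizure_catalog", "data.frame"))
}
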