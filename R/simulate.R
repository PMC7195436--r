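#' Simulator configuration
#'
#' Bundles every parameter of the synthetic-recording generator. The slow
#' dynamics use 1 model time-unit = 1 hour, so the circadian drive spans 24
#' units. Defaults place the system on the lower (interictal) branch of the
#' cubic with `r = 500`, whose folds sit at `k ~ +/-136`; the combined
#' circadian + multidien modulation sweeps the drive toward (but not past)
#' the upper fold, so transitions are noise-triggered preferentially near
#' drive peaks -- the regime in which the phase-locked biomarker rhythms the
#' forecaster relies on actually exist.
#'
#' @param r Dimensionless bifurcation-shape parameter (> 0).
#' @param k_baseline Drive offset.
#' @param k_circadian_amp,k_multidien_amp Drive modulation amplitudes.
#' @param circadian_period_h Circadian period in hours.
#' @param multidien_period_d Multidien period in days.
#' @param circadian_phase0,multidien_phase0 Drive phase offsets (radians).
#' @param k_ramp Optional `c(from, to)`: replace the sinusoidal drive by a
#'   linear ramp over the record (fold-approach sweeps).
#' @param noise_sd State-noise SD per sqrt(hour).
#' @param dt Integrator step in hours.
#' @param n_channels Number of recording channels.
#' @param segment_rate_hz Within-segment sampling rate.
#' @param segment_length_s Segment duration after trimming.
#' @param cadence_min Spacing between successive segments.
#' @param duration_days Total simulated span.
#' @param seizure_duration_s Median ictal duration; `seizure_duration_sdlog`
#'   is its lognormal spread.
#' @param seizure_duration_sdlog Lognormal sdlog of ictal durations.
#' @param refractory_min Post-ictal refractory period (minutes).
#' @param tau_samples_per_unit Within-segment correlation time, in samples,
#'   per unit of the linearized time constant (maps slow-model tau to the
#'   AR(1) snippet generator).
#' @param tau_max Cap on the rendered time constant near the fold.
#' @param innovation_sd AR(1) innovation SD (fixed, so stationary variance
#'   grows with tau).
#' @param measurement_noise_sd Channel-independent white measurement noise.
#' @param seizure_freq_hz,seizure_amp_factor Ictal rendering: oscillation
#'   frequency and amplitude as a multiple of baseline SD.
#' @param spike_template Waveform added at spike times (default: 0.2 s
#'   biphasic sharp wave, unit peak).
#' @param spike_rate_base Mean spike rate, events/hour.
#' @param spike_rate_mod Modulation depth of the spike rate by the drive
#'   (0 = constant rate, 1 = full modulation).
#' @param spike_rate_channel_sdlog Lognormal spread of per-channel rate
#'   factors (spatial heterogeneity of spiking).
#' @param spike_snr Spike amplitude: template RMS as a multiple of the
#'   segment background SD.
#' @param dropout_spec `NULL` (no gaps), a data.frame with `start_h` and
#'   `length_h`, or `list(target_fraction =, gap_meanlog_h =, gap_sdlog =)`
#'   for the random-gap model.
#' @param z0 Initial state (default: lower stable equilibrium).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(r = 500,
                       k_baseline = 40,
                       k_circadian_amp = 65,
                       k_multidien_amp = 55,
                       circadian_period_h = 24,
                       multidien_period_d = 10.5,
                       circadian_phase0 = 0,
                       multidien_phase0 = 0,
                       k_ramp = NULL,
                       noise_sd = 0.1,
                       dt = 0.01,
                       n_channels = 16,
                       segment_rate_hz = 400,
                       segment_length_s = 1,
                       cadence_min = 2,
                       duration_days = 30,
                       seizure_duration_s = 60,
                       seizure_duration_sdlog = 0.3,
                       refractory_min = 10,
                       tau_samples_per_unit = 3,
                       tau_max = 50,
                       innovation_sd = 1,
                       measurement_noise_sd = 0.3,
                       seizure_freq_hz = 6,
                       seizure_amp_factor = 10,
                       spike_template = default_spike_template(segment_rate_hz),
                       spike_rate_base = 20,
                       spike_rate_mod = 0.8,
                       spike_rate_channel_sdlog = 0.5,
                       spike_snr = 5,
                       dropout_spec = NULL,
                       z0 = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(config) {
  stopifnot(config$r > 0, config$noise_sd >= 0, config$dt > 0,
            config$cadence_min * 60 > config$segment_length_s,
            config$duration_days > 0, config$n_channels >= 1,
            config$segment_rate_hz > 0)
  if (length(config$spike_template) >=
      config$segment_length_s * config$segment_rate_hz)
    stop("config error: spike template longer than segment")
  invisible(config)
}

#' Default epileptiform spike template
#'
#' A 0.2 s biphasic sharp-wave (fast negative deflection followed by a slow
#' wave), unit peak amplitude -- a stand-in for the patient-specific averaged
#' template a clinical workflow would supply.
#'
#' @param rate_hz Sampling rate.
#' @param duration_s Template length in seconds.
#' @return Numeric waveform.
#' @export
default_spike_template <- function(rate_hz = 400, duration_s = 0.2) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  sharp <- -exp(-((t - 0.04)^2) / (2 * 0.008^2))
  slow <- 0.45 * exp(-((t - 0.10)^2) / (2 * 0.03^2))
  w <- sharp + slow
  w / max(abs(w))
}

# tau trace on the segment grid: linearized time constant of the stable
# equilibrium nearest the trajectory state, capped at tau_max.
segment_tau <- function(trajectory, seg_times_h, config) {
  idx <- pmin(length(trajectory$times_h),
              pmax(1L, round(seg_times_h / trajectory$config$dt) + 1L))
  k <- trajectory$k[idx]
  z <- trajectory$z[idx]
  br <- equilibrium_branches(k, config$r)
  lo <- br$lower; up <- br$upper
  z_eq <- ifelse(is.na(lo), up,
                 ifelse(is.na(up), lo,
                        ifelse(abs(z - lo) <= abs(z - up), lo, up)))
  d <- 3 * z_eq^2 - 1e-3 * config$r
  tau <- ifelse(d > 0, 1 / d, config$tau_max)
  pmin(tau, config$tau_max)
}

#' Render a state trajectory into iEEG-like segment snapshots
#'
#' For each segment time and channel, emits a `segment_length_s` snippet of a
#' stationary AR(1) process whose correlation time is
#' `tau_samples_per_unit * tau(t)` samples, where `tau(t)` is the linearized
#' time constant of the currently occupied equilibrium, plus independent
#' white measurement noise. Innovation variance is fixed, so both the
#' stationary variance and the autocorrelation width of the snippets grow as
#' the drive approaches the fold. Ictal intervals are rendered as
#' large-amplitude oscillations (`seizure_freq_hz`, `seizure_amp_factor` x
#' baseline SD).
#'
#' @param trajectory A `state_trajectory`.
#' @param config The simulator configuration.
#' @param catalog Optional seizure catalog (defaults to
#'   [label_seizures()] of the trajectory).
#' @return A [segment_stream()].
#' @export
synthesize_segments <- function(trajectory, config = trajectory$config,
                                catalog = label_seizures(trajectory, config)) {
  cad_h <- config$cadence_min / 60
  seg_times <- seq(0, config$duration_days * 24 - cad_h, by = cad_h)
  nseg <- length(seg_times)
  nsamp <- round(config$segment_length_s * config$segment_rate_hz)
  tau <- segment_tau(trajectory, seg_times, config)
  a <- exp(-1 / (config$tau_samples_per_unit * tau))

  ictal <- rep(FALSE, nseg)
  if (nrow(catalog) > 0) {
    for (s in seq_len(nrow(catalog))) {
      ictal <- ictal | (seg_times >= catalog$onset_h[s] &
                          seg_times < catalog$onset_h[s] + catalog$duration_s[s] / 3600)
    }
  }
  sd_baseline <- stats::median(config$innovation_sd / sqrt(1 - a[!ictal]^2))
  if (!is.finite(sd_baseline)) sd_baseline <- config$innovation_sd

  rng <- local_rng(config$seed, "segments")
  data <- array(NA_real_, dim = c(nsamp, nseg, config$n_channels))
  sig0 <- config$innovation_sd / sqrt(1 - a^2)
  for (ch in seq_len(config$n_channels)) {
    e <- rng$rnorm(nsamp * nseg)
    dim(e) <- c(nsamp, nseg)
    x <- matrix(0, nsamp, nseg)
    x[1, ] <- e[1, ] * sig0
    for (t in 2:nsamp) x[t, ] <- a * x[t - 1, ] + config$innovation_sd * e[t, ]
    if (config$measurement_noise_sd > 0)
      x <- x + config$measurement_noise_sd * rng$rnorm(nsamp * nseg)
    if (any(ictal)) {
      tt <- (seq_len(nsamp) - 1) / config$segment_rate_hz
      ph <- rng$runif(sum(ictal)) * 2 * pi
      x[, ictal] <- config$seizure_amp_factor * sd_baseline *
        sin(outer(tt, rep(2 * pi * config$seizure_freq_hz, sum(ictal))) +
              matrix(ph, nsamp, sum(ictal), byrow = TRUE)) +
        config$measurement_noise_sd * matrix(rng$rnorm(nsamp * sum(ictal)), nsamp, sum(ictal))
    }
    data[, , ch] <- x
  }
  segment_stream(times_h = seg_times, data = data,
                 rate_hz = config$segment_rate_hz,
                 cadence_min = config$cadence_min,
                 filter_history = "synthetic AR(1) rendering")
}

#' Add template-shaped epileptiform spikes to a segment stream
#'
#' Spike times are Poisson with an hourly rate modulated by the slow drive
#' (`rate(t) = base * (1 + mod * s(t))`, `s(t)` the drive normalized to
#' `[-1, 1]`), thinned to the recorded 1-s windows. Each channel gets an
#' independent lognormal rate factor (spikes are spatially heterogeneous,
#' unlike the shared slow-down signature). Masked segments receive no spikes.
#'
#' @param segments A `segment_stream`.
#' @param config Simulator configuration (template, rates, seed).
#' @param drive Drive values on the segment grid (for rate modulation);
#'   `NULL` gives an unmodulated rate.
#' @return The stream with spikes added, plus attribute `spike_truth`: a
#'   data.frame (channel, segment, offset_sample, time_h).
#' @export
inject_spikes <- function(segments, config, drive = NULL) {
  tpl <- config$spike_template
  nsamp <- dim(segments$data)[1]
  nseg <- dim(segments$data)[2]
  nch <- dim(segments$data)[3]
  if (length(tpl) >= nsamp) stop("config error: spike template longer than segment")
  if (config$spike_rate_base == 0) {
    attr(segments, "spike_truth") <-
      data.frame(channel = integer(0), segment = integer(0),
                 offset_sample = integer(0), time_h = numeric(0))
    return(segments)
  }
  s <- if (is.null(drive) || stats::sd(drive) == 0) rep(0, nseg) else {
    d <- drive - mean(drive); d / max(abs(d))
  }
  rate_h <- pmax(0, config$spike_rate_base * (1 + config$spike_rate_mod * s))
  lambda_seg <- rate_h * (nsamp / segments$rate_hz) / 3600

  rng <- local_rng(config$seed, "spikes")
  chfac <- exp(rng$rnorm(nch) * config$spike_rate_channel_sdlog)
  truth <- vector("list", nch)
  for (ch in seq_len(nch)) {
    counts <- rng$rpois(nseg, lambda_seg * chfac[ch])
    counts[segments$mask] <- 0L
    segs <- rep(seq_len(nseg), counts)
    if (length(segs)) {
      pos <- 1L + floor(rng$runif(length(segs)) * (nsamp - length(tpl)))
      tpl_rms <- sqrt(mean(tpl^2))
      for (i in seq_along(segs)) {
        j <- segs[i]
        # SNR = template RMS relative to background SD
        amp <- config$spike_snr * stats::sd(segments$data[, j, ch]) / tpl_rms
        idx <- pos[i]:(pos[i] + length(tpl) - 1L)
        segments$data[idx, j, ch] <- segments$data[idx, j, ch] + amp * tpl
      }
    }
    truth[[ch]] <- data.frame(channel = ch, segment = segs,
                              offset_sample = if (length(segs)) pos else integer(0))
  }
  truth <- do.call(rbind, truth)
  truth$time_h <- segments$times_h[truth$segment] +
    (truth$offset_sample - 1L) / segments$rate_hz / 3600
  attr(segments, "spike_truth") <- truth
  segments
}

#' Mask data dropouts in a segment stream
#'
#' Either explicit gaps (`data.frame(start_h, length_h)`; overlapping gaps
#' are merged by construction) or a random-gap model drawing lognormal gap
#' lengths ("minutes to days") at uniform starts until a target missing
#' fraction is reached (the last gap is trimmed to land on the target).
#'
#' @param segments A `segment_stream`.
#' @param dropout_spec See [sim_config()].
#' @param seed Seed for the random-gap model.
#' @return The stream with `mask` set and masked samples removed; attribute
#'   `missing_fraction` reports the realized fraction.
#' @export
inject_dropouts <- function(segments, dropout_spec, seed = 1) {
  nseg <- length(segments$times_h)
  mask <- segments$mask
  if (is.null(dropout_spec)) {
    # nothing to do
  } else if (is.data.frame(dropout_spec)) {
    for (i in seq_len(nrow(dropout_spec))) {
      mask <- mask | (segments$times_h >= dropout_spec$start_h[i] &
                        segments$times_h < dropout_spec$start_h[i] + dropout_spec$length_h[i])
    }
  } else if (is.list(dropout_spec)) {
    target <- dropout_spec$target_fraction
    mlog <- if (is.null(dropout_spec$gap_meanlog_h)) log(1) else dropout_spec$gap_meanlog_h
    slog <- if (is.null(dropout_spec$gap_sdlog)) 1.5 else dropout_spec$gap_sdlog
    rng <- local_rng(seed, "dropouts")
    span <- max(segments$times_h)
    goal <- floor(target * nseg)
    guard <- 0L
    while (sum(mask) < goal && guard < 10000L) {
      guard <- guard + 1L
      len_h <- min(exp(mlog + slog * rng$rnorm(1)), span / 4)
      st <- rng$runif(1) * (span - len_h)
      newly <- segments$times_h >= st & segments$times_h < st + len_h & !mask
      over <- (sum(mask) + sum(newly)) - goal
      if (over > 0) { # trim the tail of the last gap
        keep <- which(newly)
        newly[] <- FALSE
        newly[keep[seq_len(length(keep) - over)]] <- TRUE
      }
      mask[newly] <- TRUE
    }
  } else stop("dropout_spec must be NULL, a data.frame, or a list")
  segments$mask <- mask
  if (any(mask)) segments$data[, mask, ] <- NA_real_
  attr(segments, "missing_fraction") <- mean(mask)
  segments
}

#' Generate a complete labelled synthetic recording
#'
#' Runs the bistable state simulation, extracts the seizure catalog, renders
#' segments, applies dropouts, then injects drive-modulated spikes. All
#' randomness descends from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_recording`: `segments`, `seizure_catalog`,
#'   `true_drive`, `true_phases` (circadian/multidien, segment grid),
#'   `true_tau`, `spike_truth`, `trajectory`.
#' @export
simulate_recording <- function(config) {
  traj <- simulate_state(config)
  catalog <- label_seizures(traj, config)
  segments <- synthesize_segments(traj, config, catalog)
  segments <- inject_dropouts(segments, config$dropout_spec, seed = config$seed)
  seg_idx <- pmin(length(traj$times_h),
                  pmax(1L, round(segments$times_h / config$dt) + 1L))
  drive <- traj$k[seg_idx]
  segments <- inject_spikes(segments, config, drive = drive)
  phases <- data.frame(
    circadian = wrap_phase(2 * pi * segments$times_h / config$circadian_period_h +
                             config$circadian_phase0),
    multidien = wrap_phase(2 * pi * segments$times_h / (24 * config$multidien_period_d) +
                             config$multidien_phase0))
  structure(list(segments = segments,
                 seizure_catalog = catalog,
                 true_drive = drive,
                 true_phases = phases,
                 true_tau = segment_tau(traj, segments$times_h, config),
                 spike_truth = attr(segments, "spike_truth"),
                 trajectory = traj,
                 config = config),
            class = "synthetic_recording")
}

#' Render a continuous stretch of signal around a time point
#'
#' Continuous-mode output (no 2-min gaps) used for fine-scale peri-seizure
#' analysis: a single-channel AR(1) signal at `segment_rate_hz` whose
#' correlation time follows the trajectory's linearized tau, with ictal
#' intervals rendered as in [synthesize_segments()].
#'
#' @param trajectory A `state_trajectory`.
#' @param config Simulator configuration.
#' @param t_center_h Center of the span (hours).
#' @param span_h Half-width of the span (hours) on each side.
#' @param catalog Seizure catalog used for ictal rendering.
#' @return List with `time_s` (relative to `t_center_h`, seconds) and `y`.
#' @export
synthesize_continuous <- function(trajectory, config, t_center_h, span_h = 3,
                                  catalog = label_seizures(trajectory, config)) {
  fs <- config$segment_rate_hz
  if (!is.finite(t_center_h)) stop("t_center_h must be a finite time in hours")
  t0 <- max(0, t_center_h - span_h)
  t1 <- min(max(trajectory$times_h), t_center_h + span_h)
  if (t1 <= t0) stop("requested span lies outside the simulated record")
  n <- floor((t1 - t0) * 3600 * fs)
  th <- t0 + (seq_len(n) - 1) / fs / 3600
  idx <- pmin(length(trajectory$times_h), pmax(1L, round(th / config$dt) + 1L))
  tau <- segment_tau(trajectory, th, config)
  a <- exp(-1 / (config$tau_samples_per_unit * tau))
  rng <- local_rng(config$seed, paste0("continuous", round(t_center_h * 1e3)))
  e <- rng$rnorm(n) * config$innovation_sd
  y <- numeric(n)
  y[1] <- e[1] / sqrt(1 - a[1]^2)
  for (i in 2:n) y[i] <- a[i] * y[i - 1] + e[i]
  ictal <- rep(FALSE, n)
  if (nrow(catalog) > 0)
    for (s in seq_len(nrow(catalog)))
      ictal <- ictal | (th >= catalog$onset_h[s] &
                          th < catalog$onset_h[s] + catalog$duration_s[s] / 3600)
  if (any(ictal)) {
    sd_base <- stats::median(config$innovation_sd / sqrt(1 - a[!ictal]^2))
    tt <- (th - t0) * 3600
    y[ictal] <- config$seizure_amp_factor * sd_base *
      sin(2 * pi * config$seizure_freq_hz * tt[ictal])
  }
  if (config$measurement_noise_sd > 0)
    y <- y + config$measurement_noise_sd * rng$rnorm(n)
  list(time_s = (th - t_center_h) * 3600, y = y, ictal = ictal)
}
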