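# Rhythm decomposition: causal moving averages, long/short cycle split,
# Gaussian gap filling, Hilbert phases, dominant-period detection.

#' Causal moving average
#'
#' Output at `t` is the mean of the most recent `window` available samples up
#' to and including `t`. During warm-up (< `window` samples of history) the
#' available history is averaged and the sample is flagged as reduced
#' support. `NA` inputs are skipped; output is `NA` where no sample is
#' available in the window.
#'
#' @param x Numeric series.
#' @param window Window length in samples (>= 1).
#' @return Filtered series with attribute `reduced_support` (logical).
#' @export
causal_moving_average <- function(x, window) {
  stopifnot(window >= 1)
  out <- running_mean_recent(x, window)
  structure(out, reduced_support = seq_along(x) < window)
}

# forward-backward ("anti-causal", zero phase-lag) moving average used by
# Method M1
anticausal_moving_average <- function(x, window) {
  f <- as.numeric(causal_moving_average(x, window))
  rev(as.numeric(causal_moving_average(rev(f), window)))
}

#' Decompose a feature signal into long and short cycles
#'
#' Long cycle: 2-day (1440-sample) moving average of the input. Short cycle:
#' the residual (input minus long cycle) smoothed by a 20-sample (40-min)
#' moving average. Filters are causal by default; `causal = FALSE` uses the
#' forward-backward variant (zero phase lag, Method M1).
#'
#' @param x Feature series on the 2-min grid (may contain `NA`).
#' @param long_window,short_window Window lengths in samples.
#' @param causal Use causal filters (default) or forward-backward.
#' @return List of class `rhythm_set`: `long`, `short`, input `x`, `mask`.
#' @export
decompose_rhythms <- function(x, long_window = 1440, short_window = 20,
                              causal = TRUE) {
  ma <- if (causal) function(v, w) as.numeric(causal_moving_average(v, w))
        else anticausal_moving_average
  long <- ma(x, long_window)
  short <- ma(x - long, short_window)
  structure(list(x = x, long = long, short = short, mask = is.na(x),
                 causal = causal,
                 long_window = long_window, short_window = short_window),
            class = "rhythm_set")
}

#' Fill short data gaps with Gaussian noise
#'
#' Gaps shorter than `max_gap` samples (< 2 h at the 2-min cadence) are
#' replaced by independent Gaussian draws whose mean and SD are computed
#' from the non-missing data; gaps of `max_gap` samples or longer stay
#' missing. Fills are deterministic given `seed` (each gap gets a substream
#' keyed by its start index), so truncating the record never changes fills
#' in the retained prefix.
#'
#' @param x Series with `NA` gaps.
#' @param max_gap Threshold in samples (default 60 = 2 h).
#' @param seed Seed for the fill draws.
#' @return List: `filled` series, `fill_index` (which samples were filled),
#'   `long_gaps` (data.frame start/length of gaps left missing).
#' @export
fill_gaps <- function(x, max_gap = 60, seed = 1) {
  if (all(is.na(x))) stop("series entirely missing")
  mu <- mean(x, na.rm = TRUE)
  sdv <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(sdv)) sdv <- 0
  runs <- true_runs(is.na(x))
  filled <- x
  fill_index <- integer(0)
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    if (runs$length[i] < max_gap) {
      idx <- runs$start[i]:(runs$start[i] + runs$length[i] - 1L)
      rng <- local_rng(seed, paste0("fill", runs$start[i]))
      filled[idx] <- mu + sdv * rng$rnorm(length(idx))
      fill_index <- c(fill_index, idx)
    } else keep[i] <- TRUE
  }
  list(filled = filled, fill_index = fill_index, long_gaps = runs[keep, , drop = FALSE])
}

#' Analytic (Hilbert) phase of a cycle series
#'
#' Remaining long gaps are noise-filled so the transform is computable, the
#' series is mean-removed, and the phase is the argument of the FFT-based
#' analytic signal. Validity is `FALSE` inside long (>= `max_gap`) gaps,
#' within `boundary` samples on either side of them, and within `boundary`
#' samples of the record edges.
#'
#' @param x Cycle series (long gaps may still be `NA`).
#' @param max_gap Gap-length threshold defining long gaps (samples).
#' @param boundary Exclusion zone around long gaps and record edges
#'   (samples, default 60 = 2 h).
#' @param seed Seed for the noise fill.
#' @param exclude_edges `"both"` (default) excludes `boundary` samples at
#'   record start and end, `"start"` only at the start (Method M2's causal
#'   leading edge is kept), `"none"` disables edge exclusion. `TRUE`/`FALSE`
#'   are accepted as `"both"`/`"none"`.
#' @return List: `phase` in `[-pi, pi)`, `validity` logical.
#' @export
analytic_phase <- function(x, max_gap = 60, boundary = 60, seed = 1,
                           exclude_edges = "both") {
  if (is.logical(exclude_edges)) exclude_edges <- if (exclude_edges) "both" else "none"
  n <- length(x)
  validity <- rep(TRUE, n)
  if (anyNA(x)) {
    runs <- true_runs(is.na(x))
    fg <- fill_gaps(x, max_gap = n + 1L, seed = seed)  # fill everything
    x <- fg$filled
    for (i in seq_len(nrow(runs))) {
      if (runs$length[i] >= max_gap) {
        lo <- max(1L, runs$start[i] - boundary)
        hi <- min(n, runs$start[i] + runs$length[i] - 1L + boundary)
        validity[lo:hi] <- FALSE
      }
    }
  }
  if (exclude_edges %in% c("both", "start") && n > 2 * boundary)
    validity[seq_len(boundary)] <- FALSE
  if (exclude_edges == "both" && n > 2 * boundary)
    validity[(n - boundary + 1L):n] <- FALSE
  ph <- Arg(analytic_signal(x - mean(x)))
  list(phase = wrap_phase(ph), validity = validity)
}

#' Dominant periods of a feature series
#'
#' Magnitude FFT spectrum of the (gap-filled, mean-removed) series; local
#' maxima exceeding `prominence_factor` times the median spectral magnitude
#' are returned as periods. Peaks in `[0.9, 1.1]` days are flagged
#' circadian; peaks in `[3, 30]` days are flagged multidien.
#'
#' @param x Feature series (2-min cadence assumed unless `cadence_min` set).
#' @param cadence_min Sample spacing in minutes.
#' @param prominence_factor Peak threshold as a multiple of the median
#'   magnitude (default 8).
#' @param min_period_d,max_period_d Period search range in days.
#' @param seed Seed for the gap fill.
#' @return data.frame `period_d`, `power`, `circadian`, `multidien`,
#'   ordered by decreasing power; attribute `bin_width_d_inv` (frequency
#'   resolution, 1/days).
#' @export
dominant_periods <- function(x, cadence_min = 2, prominence_factor = 8,
                             min_period_d = 0.05, max_period_d = 40,
                             seed = 1) {
  n <- length(x)
  span_d <- n * cadence_min / 60 / 24
  if (span_d < 2 * min(max_period_d, span_d / 2))
    max_period_d <- span_d / 2
  if (span_d <= 2 * min_period_d) stop("insufficient span for the periods sought")
  if (anyNA(x)) x <- fill_gaps(x, max_gap = n + 1L, seed = seed)$filled
  x <- x - mean(x)
  X <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  freq_dinv <- (seq_along(X) - 1) / span_d  # cycles per day
  period_d <- ifelse(freq_dinv > 0, 1 / freq_dinv, Inf)
  thr <- prominence_factor * stats::median(X)
  m <- length(X)
  isloc <- X > thr &
    X >= c(Inf, X[-m]) & X > c(X[-1], -Inf) &
    period_d >= min_period_d & period_d <= max_period_d
  pk <- which(isloc)
  out <- data.frame(period_d = period_d[pk], power = X[pk]^2,
                    circadian = period_d[pk] >= 0.9 & period_d[pk] <= 1.1,
                    multidien = period_d[pk] >= 3 & period_d[pk] <= 30)
  out <- out[order(out$power, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_width_d_inv") <- 1 / span_d
  out
}

#' Causal phase estimate at the leading edge of a cycle series
#'
#' The FFT Hilbert phase is strongly distorted at the final samples of a
#' record (the transform is non-causal), which matters for pseudoprospective
#' scoring: the model is trained on well-estimated mid-record phases but
#' must be looked up at the record's edge. This estimator stabilizes the
#' edge value by extending the series one dominant-cycle ahead with a
#' least-squares sinusoid (frequency refined on a grid around the FFT peak,
#' fit over the last two cycles) before taking the analytic-signal phase at
#' the edge. It is a deterministic function of the prefix, so truncating a
#' record never changes earlier scores.
#'
#' @param x Cycle series (gap-free prefix).
#' @param n_grid Frequency refinement grid size.
#' @param cycles_fit Sinusoid fit window, in cycles.
#' @param period_range Optional `c(min, max)` period in samples restricting
#'   the dominant-frequency search (e.g. the short cycle of a 2-min-cadence
#'   series lives between 2 h and 2 days); keeps the fit from locking onto
#'   whole-record trends or high-frequency noise.
#' @param method `"sinusoid"` (default; extend by a fitted sinusoid) or
#'   `"reflect"` (odd point-reflection about the endpoint, which continues
#'   the local trend and works better for slow smooth cycles).
#' @param reflect_len Reflection length in samples (`"reflect"` method).
#' @return Phase in `[-pi, pi)` at the last sample.
#' @export
edge_phase <- function(x, n_grid = 41, cycles_fit = 2, period_range = NULL,
                       method = c("sinusoid", "reflect"),
                       reflect_len = 1440) {
  method <- match.arg(method)
  m <- length(x)
  x <- x - mean(x)
  half <- floor(m / 2)
  if (half < 4 || all(x == 0))
    return(wrap_phase(Arg(analytic_signal(x))[m]))
  if (method == "reflect") {
    L <- min(m - 1L, reflect_len)
    # trailing chunk only: the Hilbert phase at the edge is local for a
    # narrowband cycle and full-prefix FFTs dominate runtime otherwise
    C <- min(m, 6L * reflect_len)
    xc <- x[(m - C + 1L):m]
    xe <- c(xc, 2 * xc[C] - rev(xc[(C - L):(C - 1L)]))
    xe <- c(xe, rep(0, nice_length_ceiling(length(xe)) - length(xe)))
    return(wrap_phase(Arg(analytic_signal(xe - mean(xe)))[C]))
  }
  # dominant frequency from a downsampled spectrum
  ds <- max(1L, floor(if (is.null(period_range)) m / 4096 else period_range[1] / 16))
  xd <- x[seq(1L, m, by = ds)]
  md <- length(xd)
  X <- Mod(stats::fft(xd))
  halfd <- floor(md / 2)
  klo <- 1L; khi <- halfd - 1L
  if (!is.null(period_range)) {
    klo <- max(1L, floor(m / period_range[2]))
    khi <- min(halfd - 1L, ceiling(m / period_range[1]))
    if (khi < klo) khi <- klo
  }
  kk <- klo + which.max(X[(klo + 1L):(khi + 1L)]) - 1L  # cycles per record
  fg <- seq(max(0.5, kk - 1), kk + 1, length.out = n_grid) / m
  sub <- max(1L, ds %/% 2L)
  best <- NULL; best_rss <- Inf
  for (f0 in fg) {
    W <- min(m, max(16L, round(cycles_fit / f0)))
    idx <- seq(m - W + 1L, m, by = sub)
    ang <- 2 * pi * f0 * idx
    cw <- cos(ang); sw <- sin(ang); xv <- x[idx]
    G <- matrix(c(length(idx), sum(cw), sum(sw),
                  0, sum(cw^2), sum(cw * sw),
                  0, 0, sum(sw^2)), 3, 3)
    G[lower.tri(G)] <- t(G)[lower.tri(G)]
    b <- c(sum(xv), sum(xv * cw), sum(xv * sw))
    cf <- tryCatch(solve(G, b), error = function(e) NULL)
    if (is.null(cf)) next
    rss <- sum(xv^2) - sum(cf * b)
    if (rss < best_rss) { best_rss <- rss; best <- list(f0 = f0, cf = cf) }
  }
  if (is.null(best)) return(wrap_phase(Arg(analytic_signal(x))[m]))
  per <- round(1 / best$f0)
  # Hilbert on the trailing ~3 cycles plus a one-cycle sinusoid extension
  C <- min(m, 3L * per)
  xc <- x[(m - C + 1L):m]
  L <- nice_length_ceiling(C + per) - C
  te <- (m + 1):(m + L)
  ext <- best$cf[1] + best$cf[2] * cos(2 * pi * best$f0 * te) +
    best$cf[3] * sin(2 * pi * best$f0 * te)
  xe <- c(xc, ext)
  wrap_phase(Arg(analytic_signal(xe - mean(xe)))[C])
}

#' Full rhythm-and-phase extraction for one feature signal
#'
#' Convenience wrapper used by the forecasters: fill short gaps, decompose
#' into long/short cycles, and attach Hilbert phases with validity flags.
#'
#' @param x Feature series for one (signal, channel).
#' @param causal Causal (M2) or forward-backward (M1) filtering.
#' @param max_gap,boundary Missing-data parameters (samples).
#' @param seed Fill seed.
#' @param exclude_edges See [analytic_phase()].
#' @return A `rhythm_set` with `long_phase`, `short_phase`, `long_valid`,
#'   `short_valid`.
#' @export
signal_rhythms <- function(x, causal = TRUE, max_gap = 60, boundary = 60,
                           seed = 1, exclude_edges = "both") {
  n <- length(x)
  fg <- fill_gaps(x, max_gap = max_gap, seed = seed)
  rs <- decompose_rhythms(fg$filled, causal = causal)
  lp <- analytic_phase(rs$long, max_gap = max_gap, boundary = boundary,
                       seed = seed + 1, exclude_edges = exclude_edges)
  sp <- analytic_phase(rs$short, max_gap = max_gap, boundary = boundary,
                       seed = seed + 2, exclude_edges = exclude_edges)
  # long (>= max_gap) dropouts of the input invalidate BOTH cycle phases,
  # with `boundary` samples of margin on each side
  valid <- lp$validity & sp$validity
  if (nrow(fg$long_gaps) > 0) {
    for (i in seq_len(nrow(fg$long_gaps))) {
      lo <- max(1L, fg$long_gaps$start[i] - boundary)
      hi <- min(n, fg$long_gaps$start[i] + fg$long_gaps$length[i] - 1L + boundary)
      valid[lo:hi] <- FALSE
    }
  }
  rs$long_phase <- lp$phase
  rs$short_phase <- sp$phase
  rs$long_valid <- valid
  rs$short_valid <- valid
  rs$fill_index <- fg$fill_index
  rs
}
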