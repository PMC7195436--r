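# Biomarker extraction: per-segment variance, autocorrelation half-width
# (ACFW) and template-matched spike counts, plus the fine-scale peri-seizure
# profile.

#' Windowed-sinc FIR low-pass coefficients
#'
#' Linear-phase Hamming-windowed sinc design (odd tap count), normalized to
#' unit DC gain. Used for the 170 Hz anti-artifact filter.
#'
#' @param cutoff_hz Cutoff (-6 dB) frequency.
#' @param rate_hz Sampling rate.
#' @param n_taps Odd number of taps.
#' @return Numeric coefficient vector.
#' @export
fir_lowpass <- function(cutoff_hz, rate_hz, n_taps = 101) {
  stopifnot(n_taps %% 2 == 1, cutoff_hz < rate_hz / 2)
  m <- (n_taps - 1) / 2
  k <- (-m):m
  fc <- cutoff_hz / rate_hz
  h <- 2 * fc * sinc(2 * fc * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# magnitude response of an FIR at frequency f_hz
fir_response <- function(h, f_hz, rate_hz) {
  k <- seq_along(h) - 1
  Mod(sum(h * exp(-2i * pi * f_hz / rate_hz * k)))
}

#' Low-pass filter a 3-s raw snapshot and keep the central second
#'
#' Applies the 170 Hz FIR filter (linear phase, delay-compensated) to a raw
#' 3-s snapshot, then discards the first and last second so filter
#' transients never reach the analyzed window.
#'
#' @param raw Numeric vector of length `3 * rate_hz`.
#' @param rate_hz Sampling rate (must exceed 2 x 170 Hz).
#' @param cutoff_hz Filter cutoff (default 170).
#' @param n_taps FIR length.
#' @return The filtered central second (`rate_hz` samples).
#' @export
preprocess_segment <- function(raw, rate_hz, cutoff_hz = 170, n_taps = 101) {
  if (length(raw) != 3 * rate_hz)
    stop("malformed segment: expected length 3 * rate_hz")
  if (rate_hz <= 2 * cutoff_hz)
    stop("rate too low for the requested cutoff")
  h <- fir_lowpass(cutoff_hz, rate_hz, n_taps)
  m <- (n_taps - 1) / 2
  y <- stats::convolve(raw, rev(h), type = "open")  # length 3*rate + n_taps - 1
  y <- y[(m + 1):(m + length(raw))]                 # compensate group delay
  y[(rate_hz + 1):(2 * rate_hz)]
}

#' Per-segment variance (population normalization)
#'
#' `V_y = (1/T) sum (y_t - ybar)^2` -- divisor `T`, not `T - 1`.
#'
#' @param y Numeric vector (length >= 2). Any `NA` (masked segment)
#'   propagates to `NA`.
#' @return Variance.
#' @export
segment_variance <- function(y) {
  if (length(y) < 2) stop("segment too short for variance")
  if (anyNA(y)) return(NA_real_)
  mean((y - mean(y))^2)
}

#' Biased segment autocorrelation function
#'
#' `C_lambda = (1/T) * sum_{t=1}^{T-lambda} (y_t - ybar)(y_{t+lambda} - ybar) / V_y`.
#' The sum is truncated at `T - lambda` but the prefactor stays `1/T`
#' (biased estimator, implemented literally); `C_0 = 1` by construction.
#'
#' @param y Numeric vector.
#' @param max_lag Largest lag (default half the segment).
#' @return Numeric vector `C_0 .. C_max_lag`.
#' @export
autocorrelation_function <- function(y, max_lag = floor(length(y) / 2)) {
  T <- length(y)
  if (max_lag >= T) stop("max_lag must be < length(y)")
  if (anyNA(y)) return(rep(NA_real_, max_lag + 1))
  yc <- y - mean(y)
  V <- mean(yc^2)
  if (V == 0) stop("degenerate segment: zero variance, ACF undefined")
  vapply(0:max_lag, function(lag) {
    sum(yc[seq_len(T - lag)] * yc[seq_len(T - lag) + lag]) / (T * V)
  }, numeric(1))
}

#' Width of the autocorrelation function at half maximum (ACFW)
#'
#' First downward crossing of 0.5, with linear interpolation between the
#' bracketing integer lags. If the ACF never reaches 0.5 within the
#' computed lags the maximum lag is returned with attribute
#' `saturated = TRUE`.
#'
#' @param C ACF sequence starting at lag 0 (`C[1] = 1`).
#' @return Positive width in lag-samples; attribute `saturated`.
#' @export
acf_halfwidth <- function(C) {
  if (abs(C[1] - 1) > 1e-8) stop("ACF must start at C_0 = 1")
  below <- which(C <= 0.5)
  if (length(below) == 0) {
    return(structure(length(C) - 1, saturated = TRUE))
  }
  j <- below[1]              # 1-based index; lag = j - 1
  lag_hi <- j - 1
  c_hi <- C[j]; c_lo <- C[j - 1]
  w <- (lag_hi - 1) + (c_lo - 0.5) / (c_lo - c_hi)
  structure(w, saturated = FALSE)
}

# Batch ACFW over segments stored as columns of Y (no NAs). Walks lags
# until the first 0.5-crossing per column (compiled), so cost is
# proportional to the mean width rather than max_lag.
halfwidth_batch <- function(Y, max_lag = 200) {
  .halfwidth_cols(Y, as.integer(max_lag))
}

#' Detect epileptiform spikes by normalized template correlation
#'
#' Slides the template across the segment, computes the signed Pearson
#' correlation at every offset, and counts local maxima above `threshold`
#' with non-overlap suppression of one template length.
#'
#' @param y Segment vector.
#' @param template Spike waveform (shorter than the segment).
#' @param threshold Correlation threshold in (0, 1]; default 0.85.
#' @return List `count`, `positions` (1-based sample offsets),
#'   `correlations`.
#' @export
detect_spikes <- function(y, template, threshold = 0.85) {
  L <- length(template)
  if (L >= length(y)) stop("template must be shorter than the segment")
  if (stats::sd(template) == 0) stop("invalid template: flat waveform")
  stopifnot(threshold > 0, threshold <= 1)
  r <- sliding_correlation(matrix(y, ncol = 1), template)[, 1]
  picks <- pick_peaks(r, threshold, L)
  list(count = length(picks), positions = picks, correlations = r[picks])
}

# Pearson correlation of `template` against every length-L window of each
# column of Y; FFT-based, chunked to bound memory. Returns (T-L+1) x ncol.
sliding_correlation <- function(Y, template, chunk = 4096L) {
  T <- nrow(Y); L <- length(template)
  nw <- T - L + 1
  tc <- template - mean(template)
  st <- sqrt(sum(tc^2))
  P <- stats::nextn(T + L, 2)
  Kt <- Conj(stats::fft(c(tc, rep(0, P - L))))
  K1 <- Conj(stats::fft(c(rep(1, L), rep(0, P - L))))
  out <- matrix(NA_real_, nw, ncol(Y))
  for (s in seq(1, ncol(Y), by = chunk)) {
    e <- min(ncol(Y), s + chunk - 1L)
    Yp <- rbind(Y[, s:e, drop = FALSE], matrix(0, P - T, e - s + 1L))
    F1 <- stats::mvfft(Yp)
    F2 <- stats::mvfft(Yp^2)
    num <- Re(stats::mvfft(F1 * Kt, inverse = TRUE))[seq_len(nw), , drop = FALSE] / P
    ws  <- Re(stats::mvfft(F1 * K1, inverse = TRUE))[seq_len(nw), , drop = FALSE] / P
    ws2 <- Re(stats::mvfft(F2 * K1, inverse = TRUE))[seq_len(nw), , drop = FALSE] / P
    den <- sqrt(pmax(ws2 - ws^2 / L, 0)) * st
    r <- num / den
    r[den < 1e-12] <- 0
    out[, s:e] <- r
  }
  out
}

# local maxima above threshold, greedy non-overlap suppression of width L
pick_peaks <- function(r, threshold, L) {
  n <- length(r)
  if (n == 0) return(integer(0))
  isloc <- r > threshold &
    r >= c(-Inf, r[-n]) & r > c(r[-1], -Inf)
  cand <- which(isloc)
  if (length(cand) <= 1) return(cand)
  cand <- cand[order(r[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand) {
    if (all(abs(p - keep) >= L)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Build a spike template from candidate waveforms
#'
#' Aligns candidates on their absolute peak, averages pointwise, and
#' normalizes to unit peak amplitude.
#'
#' @param candidates List of equal-length numeric waveforms (>= 2).
#' @param align Align on peak before averaging (default TRUE).
#' @return Numeric template.
#' @export
build_spike_template <- function(candidates, align = TRUE) {
  if (length(candidates) < 2) stop("need at least 2 candidates")
  lens <- vapply(candidates, length, integer(1))
  if (length(unique(lens)) != 1) stop("candidate waveforms must have equal length")
  L <- lens[1]
  if (align) {
    peaks <- vapply(candidates, function(x) which.max(abs(x)), integer(1))
    ref <- round(stats::median(peaks))
    candidates <- mapply(function(x, p) {
      s <- p - ref
      if (s > 0) c(x[-seq_len(s)], rep(x[L], s))
      else if (s < 0) c(rep(x[1], -s), x[seq_len(L + s)])
      else x
    }, candidates, peaks, SIMPLIFY = FALSE)
  }
  tpl <- Reduce(`+`, candidates) / length(candidates)
  tpl / max(abs(tpl))
}

#' Feature series container
#'
#' Per (timestamp, channel) ACFW (lag-samples), variance (squared signal
#' units) and spike counts per segment, on the segment time grid, with the
#' stream's missingness mask.
#'
#' @param times_h Timestamps (hours).
#' @param acfw,variance,spike_rate Numeric matrices `[segment, channel]`.
#' @param mask Per-timestamp missing flag.
#' @param saturated Logical matrix: ACFW returned at `max_lag` without
#'   reaching half maximum.
#' @param cadence_min Cadence.
#' @return Object of class `feature_series`.
#' @export
feature_series <- function(times_h, acfw, variance, spike_rate, mask,
                           saturated = NULL, cadence_min = 2) {
  structure(list(times_h = times_h, acfw = acfw, variance = variance,
                 spike_rate = spike_rate, mask = mask, saturated = saturated,
                 cadence_min = cadence_min),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d timestamps x %d channels (%.1f%% missing)\n",
              length(x$times_h), ncol(x$acfw), 100 * mean(x$mask)))
  invisible(x)
}

#' Extract the three biomarker series from a segment stream
#'
#' Computes per-segment ACFW, population variance and template-matched spike
#' counts for every channel. Masked segments yield `NA` in every feature.
#'
#' @param stream A [segment_stream()].
#' @param template Spike template (`NULL` skips spike detection; spike_rate
#'   is then all zero).
#' @param threshold Spike correlation threshold.
#' @param max_lag Maximum ACF lag (default 200 = half a 1-s 400 Hz segment).
#' @return A [feature_series()].
#' @export
extract_features <- function(stream, template = NULL, threshold = 0.85,
                             max_lag = 200) {
  d <- dim(stream$data)
  nseg <- d[2]; nch <- d[3]
  acfw <- variance <- spikes <- matrix(NA_real_, nseg, nch)
  sat <- matrix(FALSE, nseg, nch)
  ok <- !stream$mask
  for (ch in seq_len(nch)) {
    Y <- stream$data[, ok, ch, drop = TRUE]
    if (!is.matrix(Y)) Y <- matrix(Y, ncol = sum(ok))
    hb <- halfwidth_batch(Y, max_lag = max_lag)
    acfw[ok, ch] <- hb$width
    variance[ok, ch] <- hb$variance
    sat[ok, ch] <- hb$saturated
    if (!is.null(template)) {
      spikes[ok, ch] <- .spike_counts_cols(Y, template, threshold)
    } else {
      spikes[ok, ch] <- 0
    }
  }
  feature_series(stream$times_h, acfw, variance, spikes, stream$mask,
                 saturated = sat, cadence_min = stream$cadence_min)
}

#' Fine-scale peri-seizure biomarker profile
#'
#' ACFW and variance in a moving window over a continuous stretch of signal
#' spanning +/- `span_h` hours around a seizure onset, normalized by the
#' mean of a pre-onset baseline. The peak is the maximum of the normalized
#' ACFW in `[-5 min, onset + seizure duration]` and the trough the minimum
#' after the peak within the post-onset search window.
#'
#' @param time_s Sample times in seconds relative to onset.
#' @param y Continuous signal.
#' @param duration_s Seizure duration.
#' @param rate_hz Sampling rate.
#' @param window_s Moving-window length (default 5 s).
#' @param overlap Either `"share"` (consecutive windows share 0.5 s; 4.5 s
#'   step, the literal reading) or `"step"` (0.5 s step).
#' @param baseline_min Pre-onset baseline length in minutes (default 5;
#'   set 1 for the 1-min convention).
#' @param post_search_s Search window after onset for the trough (default
#'   `duration_s + 300`).
#' @return List of class `periseizure_profile`: `rel_time_s`, `acfw_norm`,
#'   `var_norm`, `peak`, `trough`, `baseline_window`, `baseline_shrunk`.
#' @export
periseizure_profile <- function(time_s, y, duration_s, rate_hz,
                                window_s = 5, overlap = c("share", "step"),
                                baseline_min = 5,
                                post_search_s = duration_s + 300) {
  overlap <- match.arg(overlap)
  step_s <- if (overlap == "share") window_s - 0.5 else 0.5
  wlen <- round(window_s * rate_hz)
  starts <- seq(1, length(y) - wlen + 1, by = round(step_s * rate_hz))
  centers <- time_s[starts] + window_s / 2
  Y <- vapply(starts, function(s) y[s:(s + wlen - 1)], numeric(wlen))
  hb <- halfwidth_batch(Y, max_lag = floor(wlen / 2))
  bl <- centers >= -baseline_min * 60 & centers < 0
  shrunk <- FALSE
  if (sum(bl) < 2) {
    bl <- centers < 0
    shrunk <- TRUE
  }
  if (sum(bl) < 1) stop("no pre-onset data for baseline")
  acfw_norm <- hb$width / mean(hb$width[bl])
  var_norm <- hb$variance / mean(hb$variance[bl])
  sw <- centers >= -300 & centers <= duration_s
  peak_i <- which(sw)[which.max(acfw_norm[sw])]
  post <- centers >= centers[peak_i] & centers <= post_search_s
  trough_i <- which(post)[which.min(acfw_norm[post])]
  structure(list(rel_time_s = centers, acfw_norm = acfw_norm,
                 var_norm = var_norm,
                 peak = list(value = acfw_norm[peak_i], time_s = centers[peak_i]),
                 trough = list(value = acfw_norm[trough_i], time_s = centers[trough_i]),
                 baseline_window = c(-baseline_min * 60, 0),
                 baseline_shrunk = shrunk),
            class = "periseizure_profile")
}

#' Export a feature series as CSV
#'
#' Long format: `timestamp_h, channel, acfw, variance, spikes, masked`.
#'
#' @param features A `feature_series`.
#' @param path Output path.
#' @export
write_feature_series <- function(features, path) {
  nch <- ncol(features$acfw)
  out <- do.call(rbind, lapply(seq_len(nch), function(ch) {
    data.frame(timestamp_h = features$times_h, channel = ch,
               acfw = features$acfw[, ch], variance = features$variance[, ch],
               spikes = features$spike_rate[, ch], masked = features$mask)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_series
#' @export
read_feature_series <- function(path) {
  x <- utils::read.csv(path)
  chs <- sort(unique(x$channel))
  times <- sort(unique(x$timestamp_h))
  grab <- function(col) {
    m <- matrix(NA_real_, length(times), length(chs))
    for (i in seq_along(chs)) {
      xi <- x[x$channel == chs[i], ]
      m[match(xi$timestamp_h, times), i] <- xi[[col]]
    }
    m
  }
  mask <- x$masked[x$channel == chs[1]][match(times, x$timestamp_h[x$channel == chs[1]])]
  feature_series(times, grab("acfw"), grab("variance"), grab("spikes"),
                 as.logical(mask))
}
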