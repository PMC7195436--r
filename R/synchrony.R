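# Phase-locking quantification: synchronization index, seizure-phase
# sampling and histograms, channel selection, electrode similarity.

#' Synchronization index of a set of phases
#'
#' Modulus of the mean unit phasor `|1/N sum exp(i theta_n)|`: 1 when all
#' phases coincide, 0 for uniform phases. The mean phase is the argument of
#' the phasor sum.
#'
#' @param phases Numeric vector of radians (N >= 1, finite).
#' @return List `si` in `[0, 1]` and `mean_phase` in `[-pi, pi)`.
#' @export
synchronization_index <- function(phases) {
  if (length(phases) == 0) stop("empty phase set")
  if (any(!is.finite(phases))) stop("phases must be finite")
  s <- sum(exp(1i * phases))
  list(si = Mod(s) / length(phases), mean_phase = wrap_phase(Arg(s)))
}

#' Phase of a cycle at the sample prior to each seizure
#'
#' For each onset, takes the last timestamp strictly before the onset. If
#' that sample's phase is invalid (dropout exclusion) the seizure is
#' excluded and counted.
#'
#' @param times_h Timestamps of the phase series (hours).
#' @param phase Phase series.
#' @param validity Logical validity flags.
#' @param onsets_h Seizure onset times (hours).
#' @return List: `phase` (one per retained seizure), `seizure_index`,
#'   `sample_index`, `n_excluded`.
#' @export
seizure_phases <- function(times_h, phase, validity, onsets_h) {
  idx <- findInterval(onsets_h - 1e-9, times_h)
  ok <- idx >= 1
  excl <- 0L
  keep <- logical(length(onsets_h))
  for (i in seq_along(onsets_h)) {
    if (!ok[i]) { excl <- excl + 1L; next }
    if (!validity[idx[i]] || !is.finite(phase[idx[i]])) { excl <- excl + 1L; next }
    keep[i] <- TRUE
  }
  list(phase = phase[idx[keep]], seizure_index = which(keep),
       sample_index = idx[keep], n_excluded = excl)
}

#' Seizure-phase histogram
#'
#' Counts per equal-width phase bin over `[-pi, pi)` (half-open bins;
#' `-pi` falls in bin 1, values just below `pi` in bin `n_bins`), the
#' normalized distribution, and the SI of the raw (unbinned) phases.
#'
#' @param phases Seizure phases (radians).
#' @param n_bins Number of bins (default 20).
#' @return List: `counts`, `density` (sums to 1), `breaks`, `si`,
#'   `mean_phase`.
#' @export
seizure_phase_histogram <- function(phases, n_bins = 20) {
  if (length(phases) == 0) stop("no valid seizure phases")
  b <- phase_bin(phases, n_bins)
  counts <- tabulate(b, nbins = n_bins)
  s <- synchronization_index(phases)
  list(counts = counts, density = counts / sum(counts),
       breaks = seq(-pi, pi, length.out = n_bins + 1),
       si = s$si, mean_phase = s$mean_phase)
}

# half-open bin index over [-pi, pi)
phase_bin <- function(theta, n_bins = 20) {
  b <- floor((wrap_phase(theta) + pi) / (2 * pi / n_bins)) + 1L
  pmin(b, n_bins)
}

#' Phase uniformity of a signal
#'
#' The SI of all valid phases of the signal itself (near 0 for a pure
#' sinusoid whose phase sweeps uniformly; > 0 for asymmetric cycles).
#'
#' @param phase Phase series.
#' @param validity Logical validity flags (default all valid).
#' @return SI in `[0, 1]`.
#' @export
signal_phase_uniformity <- function(phase, validity = rep(TRUE, length(phase))) {
  synchronization_index(phase[validity & is.finite(phase)])$si
}

#' Select the best channel per (signal, cycle) by seizure SI
#'
#' Argmax of the seizure-phase SI across channels; exact ties break to the
#' lowest channel index (recorded in the result).
#'
#' @param si_table Numeric matrix of SIs `[channel, (signal, cycle)]` or a
#'   vector for a single (signal, cycle).
#' @return Integer vector of selected channel indices with attribute
#'   `tie` (logical per column).
#' @export
select_channel <- function(si_table) {
  m <- if (is.matrix(si_table)) si_table else matrix(si_table, ncol = 1)
  sel <- integer(ncol(m)); tie <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    v[!is.finite(v)] <- -Inf
    if (all(v == -Inf)) stop("all channels missing for column ", j)
    mx <- max(v)
    w <- which(v == mx)
    sel[j] <- w[1]
    tie[j] <- length(w) > 1
  }
  structure(sel, tie = tie)
}

#' Mean cross-electrode similarity of a biomarker signal
#'
#' Each channel's series is smoothed with a causal 20-sample moving
#' average, timestamps with a missing value on any channel are removed
#' (listwise), and the Pearson correlation matrix across channels is
#' averaged over its strictly-upper-triangle entries.
#'
#' @param features A [feature_series()].
#' @param signal One of `"acfw"`, `"variance"`, `"spike_rate"`.
#' @param smooth_window Smoothing window (samples).
#' @return Mean off-diagonal correlation; attributes `n_pairs`,
#'   `n_excluded_pairs`, `matrix`.
#' @export
electrode_similarity <- function(features, signal = c("acfw", "variance", "spike_rate"),
                                 smooth_window = 20) {
  signal <- match.arg(signal)
  X <- features[[signal]]
  if (ncol(X) < 2) stop("need at least 2 channels")
  S <- apply(X, 2, function(v) as.numeric(causal_moving_average(v, smooth_window)))
  keep <- stats::complete.cases(S)
  S <- S[keep, , drop = FALSE]
  if (nrow(S) < 2) stop("fewer than 2 overlapping valid samples")
  cm <- suppressWarnings(stats::cor(S))
  ut <- cm[upper.tri(cm)]
  excluded <- sum(!is.finite(ut))
  structure(mean(ut[is.finite(ut)]),
            n_pairs = sum(is.finite(ut)), n_excluded_pairs = excluded,
            matrix = cm)
}

#' Seizure-phase SI table across channels for all six (signal, cycle) pairs
#'
#' Computes rhythms per channel and signal, samples phases at the sample
#' prior to each onset, and tabulates seizure SIs. The workhorse behind
#' channel selection for forecasting and cluster analysis.
#'
#' @param features A `feature_series`.
#' @param onsets_h Seizure onsets (hours).
#' @param causal Filtering variant.
#' @param seed Gap-fill seed.
#' @return List with `si` (channels x 6 matrix, columns
#'   `acfw.long, acfw.short, variance.long, ...`), `mean_phase` (same
#'   shape), `signal_si` (phase-uniformity of each series), and `rhythms`
#'   (nested list `[[signal]][[channel]]`).
#' @export
si_table <- function(features, onsets_h, causal = TRUE, seed = 1) {
  signals <- c("acfw", "variance", "spike_rate")
  nch <- ncol(features$acfw)
  cols <- as.vector(outer(c("long", "short"), signals,
                          function(cyc, sg) paste(sg, cyc, sep = ".")))
  si <- mp <- ssi <- matrix(NA_real_, nch, length(cols),
                            dimnames = list(NULL, cols))
  rhythms <- stats::setNames(vector("list", length(signals)), signals)
  for (sg in signals) {
    rhythms[[sg]] <- vector("list", nch)
    for (ch in seq_len(nch)) {
      x <- features[[sg]][, ch]
      if (all(is.na(x))) next
      rs <- signal_rhythms(x, causal = causal, seed = seed)
      rhythms[[sg]][[ch]] <- rs
      for (cyc in c("long", "short")) {
        col <- paste(sg, cyc, sep = ".")
        sp <- seizure_phases(features$times_h, rs[[paste0(cyc, "_phase")]],
                             rs[[paste0(cyc, "_valid")]], onsets_h)
        if (length(sp$phase) > 0) {
          s <- synchronization_index(sp$phase)
          si[ch, col] <- s$si
          mp[ch, col] <- s$mean_phase
        }
        ssi[ch, col] <- signal_phase_uniformity(rs[[paste0(cyc, "_phase")]],
                                                rs[[paste0(cyc, "_valid")]])
      }
    }
  }
  list(si = si, mean_phase = mp, signal_si = ssi, rhythms = rhythms)
}
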