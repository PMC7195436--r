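# Shared fixtures, all generated in code.

# stationary AR(1) sample path
make_ar1 <- function(n, a, sd = 1, seed = 1) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = a), n, sd = sd))
}

# quick simulator config: small, single-channel, no spikes unless asked
quick_config <- function(..., duration_days = 5, n_channels = 1,
                         spike_rate_base = 0, seed = 1) {
  sim_config(duration_days = duration_days, n_channels = n_channels,
             spike_rate_base = spike_rate_base, seed = seed, ...)
}

# Cheap rhythmic feature series + planted phase-locked seizures, bypassing
# the heavy segment renderer: used by forecaster/cluster tests where only
# the 2-min-grid biomarker series matter. Seizures are placed at the peaks
# of the combined modulation with optional jitter.
make_rhythmic_features <- function(days = 60, seed = 1,
                                   circadian_h = 24, multidien_d = 10,
                                   n_seiz = 40, jitter_h = 1,
                                   locked = TRUE, n_channels = 1) {
  set.seed(seed)
  cad_h <- 2 / 60
  times <- seq(0, days * 24 - cad_h, by = cad_h)
  n <- length(times)
  base_c <- cos(2 * pi * times / circadian_h)
  base_m <- cos(2 * pi * times / (24 * multidien_d))
  mk <- function(amp_c, amp_m, noise) {
    m <- matrix(NA_real_, n, n_channels)
    for (ch in seq_len(n_channels))
      m[, ch] <- 10 + amp_c * base_c + amp_m * base_m + noise * rnorm(n)
    m
  }
  acfw <- mk(3, 2, 0.8)
  variance <- mk(2, 1.5, 0.8)
  spikes <- matrix(rpois(n * n_channels,
                         lambda = pmax(0.05, 0.5 + 0.4 * base_c + 0.3 * base_m)),
                   n, n_channels)
  feats <- feature_series(times, acfw, variance, spikes,
                          mask = rep(FALSE, n))
  if (locked) {
    score <- base_c + base_m
    # onsets just after the strongest combined peaks, jittered
    peak_days <- which(diff(sign(diff(score))) == -2) + 1
    ord <- order(score[peak_days], decreasing = TRUE)
    take <- peak_days[ord[seq_len(min(n_seiz, length(peak_days)))]]
    onsets <- sort(times[take]) + stats::runif(length(take), 0, jitter_h)
  } else {
    onsets <- sort(stats::runif(n_seiz, 2 * 24, days * 24 - 1))
  }
  catalog <- data.frame(onset_h = onsets, duration_s = 60)
  list(features = feats, catalog = catalog)
}
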