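# Phase-conditioned seizure forecasting: probability-given-phase tables,
# multiplicative combination, brute-force threshold optimization, the
# within-sample (M1) and pseudoprospective (M2) schemes, and the random
# Markov chance model.

#' Seizure probability given phase bin
#'
#' `P(S | theta) = S_theta / N_theta`: the number of seizures whose
#' prior-sample phase fell in the bin, divided by the number of valid
#' signal samples in the bin. Bins never visited get probability 0 and are
#' flagged.
#'
#' @param phase Signal phase series.
#' @param validity Validity flags for the phase series.
#' @param seizure_phase Phases at the sample prior to each seizure.
#' @param n_bins Number of equal phase bins over `[-pi, pi)`.
#' @param smoothing Laplace pseudo-count added to `S_theta` (with
#'   `smoothing * n_bins` added to `N_theta`). Default 0: the literal
#'   estimator, under which a bin no training seizure visited has
#'   probability exactly 0. The pseudoprospective forecaster enables a
#'   small pseudo-count because its tables are refit on few seizures and a
#'   multiplicative model is destroyed by spurious zeros.
#' @return List of class `phase_prob_table`: `p`, `S`, `N`, `empty`,
#'   `breaks`.
#' @export
probability_given_phase <- function(phase, validity, seizure_phase,
                                    n_bins = 20, smoothing = 0) {
  if (length(seizure_phase) == 0) stop("untrainable: zero valid seizures")
  ok <- validity & is.finite(phase)
  N <- tabulate(phase_bin(phase[ok], n_bins), nbins = n_bins)
  S <- tabulate(phase_bin(seizure_phase, n_bins), nbins = n_bins)
  p <- ifelse(N > 0, (S + smoothing) / (N + smoothing * n_bins), 0)
  structure(list(p = p, S = S, N = N, empty = N == 0,
                 breaks = seq(-pi, pi, length.out = n_bins + 1)),
            class = "phase_prob_table")
}

#' Combine per-cycle probability tables into a probability trace
#'
#' Pointwise product of the bin-looked-up probabilities of all component
#' (signal, cycle) tables, under the independence assumption. Timestamps
#' where any component phase is invalid are `NA`.
#'
#' @param model Named list of `phase_prob_table`s.
#' @param phases Named list (same names) of lists with `phase` and
#'   `validity` on a common time grid.
#' @return Numeric probability trace (`NA` where masked).
#' @export
combine_probabilities <- function(model, phases) {
  stopifnot(length(model) >= 1, all(names(model) %in% names(phases)))
  n <- length(phases[[names(model)[1]]]$phase)
  out <- rep(1, n)
  bad <- rep(FALSE, n)
  for (nm in names(model)) {
    ph <- phases[[nm]]
    nb <- length(model[[nm]]$p)
    bad <- bad | !ph$validity | !is.finite(ph$phase)
    idx <- phase_bin(ifelse(is.finite(ph$phase), ph$phase, 0), nb)
    out <- out * model[[nm]]$p[idx]
  }
  out[bad] <- NA_real_
  out
}

#' Brute-force optimization of the two risk thresholds
#'
#' Exhaustive search over candidate pairs `Th1 <= Th2` drawn from the
#' unique values of the probability trace, maximizing
#' `(fraction of time in low risk) x (fraction of seizures in high risk)`
#' (criteria C1 x C2). In `strict` mode, grid points violating the
#' occupancy ordering C3 (`time_low > time_med > time_high`) or the seizure
#' ordering C4 (`seiz_low <= seiz_med <= seiz_high`, with strictly more in
#' high than in low) are zeroed, and an empty feasible set is an error.
#' Ties break toward larger time-in-low, then larger `Th2`.
#'
#' @param trace Probability trace (`NA` = masked).
#' @param seizure_p Probability values at the seizure scoring samples.
#' @param mode `"strict"` (C1*C2 with C3/C4 constraints) or `"relaxed"`
#'   (C1*C2 only).
#' @param max_grid Cap on the number of candidate thresholds; above it the
#'   unique values are thinned evenly (the objective is a step function of
#'   the thresholds, so thinning only coarsens the search).
#' @return List: `th1`, `th2`, `objective`, `mode`, `degenerate`,
#'   `n_candidates`.
#' @export
optimize_thresholds <- function(trace, seizure_p,
                                mode = c("strict", "relaxed"),
                                max_grid = 500) {
  mode <- match.arg(mode)
  p <- trace[is.finite(trace)]
  sz <- seizure_p[is.finite(seizure_p)]
  if (length(sz) == 0) stop("no seizures to optimize against")
  n <- length(p); S <- length(sz)
  u0 <- sort(unique(p))
  ncum <- c(0, cumsum(tabulate(match(p, u0), nbins = length(u0))))
  u <- c(u0, max(u0) * (1 + 1e-9) + 1e-300)  # allows the all-low partition
  if (length(u) > max_grid)
    u <- unique(c(u[round(seq(1, length(u), length.out = max_grid))],
                  u[length(u)]))
  K <- length(u)
  # exact strict counts #(p < u_i), #(sz < u_i) -- no epsilon tricks, the
  # trace values can be arbitrarily small products
  n_lt <- ifelse(is.na(match(u, u0)), length(p), ncum[match(u, u0)])
  szs <- sort(sz)
  s_lt <- vapply(u, function(v) sum(szs < v), numeric(1))
  t_low <- matrix(n_lt / n, K, K)               # rows: Th1
  s_high <- matrix((S - s_lt) / S, K, K, byrow = TRUE)  # cols: Th2
  obj <- t_low * s_high
  obj[lower.tri(obj)] <- -Inf                   # enforce Th1 <= Th2 (i <= j)
  if (mode == "strict") {
    nl <- matrix(n_lt, K, K); nh <- matrix(n - n_lt, K, K, byrow = TRUE)
    nm <- n - nl - nh
    sl <- matrix(s_lt, K, K); sh <- matrix(S - s_lt, K, K, byrow = TRUE)
    sm <- S - sl - sh
    # C3 strict; C4 non-strict with high > low (ties at zero seizures in the
    # lower states must not veto an otherwise ordered solution)
    feas <- nl > nm & nm > nh & sl <= sm & sm <= sh & sh > sl
    obj[!feas] <- -Inf
    if (all(obj == -Inf))
      stop("no-solution: strict criteria C3/C4 are infeasible for this trace")
  }
  best <- max(obj)
  w <- which(obj == best, arr.ind = TRUE)
  # ties: larger time-in-low (larger i), then larger Th2 (larger j)
  w <- w[order(-w[, 1], -w[, 2]), , drop = FALSE]
  i <- w[1, 1]; j <- w[1, 2]
  degenerate <- length(unique(p)) <= 1 || best <= 0
  list(th1 = u[i], th2 = u[j], objective = best, mode = mode,
       degenerate = degenerate, n_candidates = K)
}

#' Three-state risk trace from a probability trace
#'
#' Level 1 (low) where `p < Th1`, 2 (medium) where `Th1 <= p < Th2`,
#' 3 (high) where `p >= Th2` (right-closed at `Th2`).
#'
#' @param times_h Timestamps.
#' @param trace Probability trace.
#' @param th1,th2 Thresholds, `th1 <= th2`.
#' @return List of class `risk_trace`: `times_h`, `probability`, `level`
#'   (`NA` where masked), `thresholds`.
#' @export
risk_trace <- function(times_h, trace, th1, th2) {
  stopifnot(th1 <= th2)
  level <- ifelse(trace >= th2, 3L, ifelse(trace >= th1, 2L, 1L))
  structure(list(times_h = times_h, probability = trace,
                 level = level, thresholds = c(th1 = th1, th2 = th2)),
            class = "risk_trace")
}

#' Score a forecast
#'
#' Time fractions per risk level over valid samples, seizure fractions per
#' level (level at the sample prior to onset), their product (the
#' performance product: seizures-in-high x time-in-low), the mean numeric
#' risk level at seizures (low=1, medium=2, high=3), and an ROC curve from
#' sweeping one threshold over the probability trace (seizure sensitivity
#' vs fraction of time above threshold).
#'
#' @param levels Risk level per time sample (`NA` = masked).
#' @param seizure_levels Risk level at each scored seizure.
#' @param trace Probability trace (for the ROC; optional).
#' @param seizure_p Probabilities at seizure scoring samples (for the ROC).
#' @param method Tag: `"M1"`, `"M2"` or `"random"`.
#' @return List of class `forecast_report`.
#' @export
score_forecast <- function(levels, seizure_levels, trace = NULL,
                           seizure_p = NULL, method = "M1") {
  sl <- seizure_levels[is.finite(seizure_levels)]
  if (length(sl) == 0) stop("zero scored seizures")
  lv <- levels[is.finite(levels)]
  time_frac <- tabulate(lv, 3) / length(lv)
  seiz_frac <- tabulate(sl, 3) / length(sl)
  roc <- NULL
  if (!is.null(trace) && !is.null(seizure_p)) {
    p <- trace[is.finite(trace)]
    sp <- seizure_p[is.finite(seizure_p)]
    th <- c(-Inf, sort(unique(p)), Inf)
    roc <- data.frame(
      threshold = th,
      fpr = vapply(th, function(t) mean(p >= t), numeric(1)),
      sensitivity = vapply(th, function(t) mean(sp >= t), numeric(1)))
  }
  structure(list(method = method,
                 time_fraction = stats::setNames(time_frac, c("low", "medium", "high")),
                 seizure_fraction = stats::setNames(seiz_frac, c("low", "medium", "high")),
                 performance_product = seiz_frac[3] * time_frac[1],
                 mean_risk_level = mean(sl),
                 n_seizures_scored = length(sl),
                 roc = roc),
            class = "forecast_report")
}

#' @export
print.forecast_report <- function(x, ...) {
  cat(sprintf("<forecast_report %s> seizures high/med/low: %.0f%%/%.0f%%/%.0f%% | time low: %.0f%% | product %.3f | mean risk %.2f\n",
              x$method, 100 * x$seizure_fraction[3], 100 * x$seizure_fraction[2],
              100 * x$seizure_fraction[1], 100 * x$time_fraction[1],
              x$performance_product, x$mean_risk_level))
  invisible(x)
}

# index of the last sample strictly before each onset
prior_sample_index <- function(times_h, onsets_h) findInterval(onsets_h - 1e-9, times_h)

# internal: assemble the six (signal, cycle) phase lists for given channels
# from an si_table() result
phases_from_rhythms <- function(rhythms, channels) {
  out <- list()
  for (nm in names(channels)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    rs <- rhythms[[parts[1]]][[channels[[nm]]]]
    out[[nm]] <- list(phase = rs[[paste0(parts[2], "_phase")]],
                      validity = rs[[paste0(parts[2], "_valid")]])
  }
  out
}

#' Within-sample forecast (Method M1)
#'
#' Forward-backward (zero phase-lag) rhythm filtering, channel selection and
#' probability tables trained on all seizures, strict threshold mode. This
#' measures the ceiling performance of the phase representation, not an
#' out-of-sample forecast.
#'
#' @param features A `feature_series`.
#' @param catalog Seizure catalog (`onset_h`).
#' @param n_bins Phase bins.
#' @param seed Gap-fill seed.
#' @param channels Optional named channel selection (otherwise max-SI).
#' @param fallback_relaxed If the strict C3/C4 constraints are infeasible,
#'   retry in relaxed mode and flag the report (default TRUE).
#' @return List of class `m1_forecast`: `report`, `model`, `trace`,
#'   `risk`, `thresholds`, `channels`, `si`.
#' @export
forecast_m1 <- function(features, catalog, n_bins = 20, seed = 1,
                        channels = NULL, fallback_relaxed = TRUE) {
  onsets <- catalog$onset_h
  if (length(onsets) == 0) stop("untrainable: no seizures")
  stab <- si_table(features, onsets, causal = FALSE, seed = seed)
  if (is.null(channels)) {
    sel <- select_channel(stab$si)
    channels <- as.list(stats::setNames(as.integer(sel), colnames(stab$si)))
  }
  phases <- phases_from_rhythms(stab$rhythms, channels)
  model <- list()
  for (nm in names(phases)) {
    sp <- seizure_phases(features$times_h, phases[[nm]]$phase,
                         phases[[nm]]$validity, onsets)
    model[[nm]] <- probability_given_phase(phases[[nm]]$phase,
                                           phases[[nm]]$validity,
                                           sp$phase, n_bins)
  }
  trace <- combine_probabilities(model, phases)
  pidx <- prior_sample_index(features$times_h, onsets)
  seizure_p <- ifelse(pidx >= 1, trace[pmax(pidx, 1)], NA_real_)
  opt <- tryCatch(optimize_thresholds(trace, seizure_p, mode = "strict"),
                  error = function(e) if (fallback_relaxed)
                    c(optimize_thresholds(trace, seizure_p, mode = "relaxed"),
                      list(fallback = TRUE)) else stop(e))
  rt <- risk_trace(features$times_h, trace, opt$th1, opt$th2)
  seizure_levels <- ifelse(is.finite(seizure_p),
                           ifelse(seizure_p >= opt$th2, 3L,
                                  ifelse(seizure_p >= opt$th1, 2L, 1L)), NA)
  report <- score_forecast(rt$level, seizure_levels, trace, seizure_p, "M1")
  report$threshold_fallback <- isTRUE(opt$fallback)
  structure(list(report = report, model = model, trace = trace, risk = rt,
                 thresholds = c(opt$th1, opt$th2), channels = channels,
                 si = stab$si, seizure_levels = seizure_levels),
            class = "m1_forecast")
}

# causal phases on the prefix of the feature series ending before time t_h
# (exclusive); returns phases + the prefix length
m2_prefix_phases <- function(features, channels, t_h, seed) {
  m <- findInterval(t_h - 1e-9, features$times_h)
  # analyze the trailing 5-smooth-length window of the prefix, capped at 60
  # days (43200 samples): FFTs on awkward prefix lengths are catastrophically
  # slow, and data older than the 50-day training window does not enter the
  # fit; trimmed samples are reported as invalid
  off <- m - min(nice_length_floor(m), 43200L)
  pad_phase <- function(v) c(rep(NA_real_, off), v)
  pad_valid <- function(v) c(rep(FALSE, off), v)
  out <- list()
  cache <- list()
  for (nm in names(channels)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    key <- paste(parts[1], channels[[nm]])
    if (is.null(cache[[key]])) {
      x <- features[[parts[1]]][(off + 1L):m, channels[[nm]]]
      cache[[key]] <- signal_rhythms(x, causal = TRUE, seed = seed,
                                     exclude_edges = "start")
    }
    rs <- cache[[key]]
    out[[nm]] <- list(phase = pad_phase(rs[[paste0(parts[2], "_phase")]]),
                      validity = pad_valid(rs[[paste0(parts[2], "_valid")]]))
  }
  # edge estimators chosen per cycle type: sinusoid extension with a
  # band-limited dominant-frequency search for the short cycle, odd
  # reflection (local trend continuation) for the smooth long cycle
  edge <- vapply(names(channels), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    rs <- cache[[paste(parts[1], channels[[nm]])]]
    if (parts[2] == "short")
      edge_phase(rs$short, period_range = c(60, 1440))
    else
      edge_phase(rs$long, method = "reflect")
  }, numeric(1))
  list(phases = out, m = m, edge = edge)
}

# fit tables + thresholds from seizures in the trailing window, using
# phases computed on the prefix ending at t_fit. Seizure phases come from
# `stored`: the edge-phase estimates made when each seizure was scored
# (online consistency -- the model learns the same phase distribution the
# scoring lookup will draw from). N_theta and the occupancy trace use the
# retrospective Hilbert phases of the prefix.
m2_fit <- function(features, channels, onsets, t_fit, window_days, n_bins, seed,
                   stored, pp = NULL, smoothing = 0) {
  if (is.null(pp)) pp <- m2_prefix_phases(features, channels, t_fit, seed)
  w0 <- t_fit - window_days * 24
  win <- which(features$times_h[seq_len(pp$m)] >= w0)
  in_win <- which(onsets > w0 & onsets <= t_fit)
  usable <- in_win[stats::complete.cases(stored[in_win, , drop = FALSE])]
  if (length(usable) == 0) stop("untrainable: no usable seizures in window")
  model <- list()
  for (nm in names(pp$phases)) {
    ph <- pp$phases[[nm]]
    keep <- rep(FALSE, pp$m); keep[win] <- TRUE
    model[[nm]] <- probability_given_phase(
      ifelse(keep, ph$phase, NA_real_), ph$validity & keep,
      stored[usable, nm], n_bins, smoothing = smoothing)
  }
  trace <- combine_probabilities(model, pp$phases)[win]
  seizure_p <- vapply(usable, function(i) {
    p <- 1
    for (nm in names(model))
      p <- p * model[[nm]]$p[phase_bin(stored[i, nm], n_bins)]
    p
  }, numeric(1))
  opt <- optimize_thresholds(trace, seizure_p, mode = "relaxed")
  list(model = model, th1 = opt$th1, th2 = opt$th2, fit_time_h = t_fit)
}

#' Pseudoprospective forecast (Method M2)
#'
#' Strictly causal, iteratively updated forecast: the model and thresholds
#' are bootstrapped from the first 10 seizures; each later seizure is
#' assigned the risk level of the frozen model at the sample prior to its
#' onset, with phases computed only from data preceding the onset; after
#' each seizure the probability tables and thresholds are refit on the
#' trailing 50-day window (relaxed threshold mode). Channel selection is
#' made once, on the bootstrap prefix, and then held fixed.
#'
#' @param features A `feature_series`.
#' @param catalog Seizure catalog.
#' @param n_bins Phase bins.
#' @param window_days Trailing training window (days).
#' @param bootstrap_n Seizures used to bootstrap (default 10; forecasting
#'   starts after the 10th seizure).
#' @param seed Gap-fill seed.
#' @param channels Optional fixed channel selection.
#' @param smoothing Laplace pseudo-count for the iterative tables (see
#'   [probability_given_phase()]); default 4. The iterative tables hold a
#'   few dozen seizures at most while causal edge-phase estimates jitter by
#'   one or two bins, so unvisited-bin zeros would otherwise veto the
#'   product model; a pseudo-count of the same order as the per-bin jitter
#'   mass performed best in development simulations.
#' @return List of class `m2_forecast`: `report`, `seizure_levels` (per
#'   forecast seizure; `NA` = unscorable), `risk_ma5`, `refit_times_h`,
#'   `channels`, `levels` (stitched trace levels), plus the probability
#'   values at scored seizures.
#' @export
forecast_m2 <- function(features, catalog, n_bins = 20, window_days = 50,
                        bootstrap_n = 10, seed = 1, channels = NULL,
                        smoothing = 4) {
  onsets <- catalog$onset_h
  if (length(onsets) < bootstrap_n + 1)
    stop("insufficient history: M2 needs more than ", bootstrap_n, " seizures")
  t_boot <- onsets[bootstrap_n] + 1e-6
  if (is.null(channels)) {
    m <- findInterval(t_boot, features$times_h)
    feat_prefix <- feature_series(features$times_h[seq_len(m)],
                                  features$acfw[seq_len(m), , drop = FALSE],
                                  features$variance[seq_len(m), , drop = FALSE],
                                  features$spike_rate[seq_len(m), , drop = FALSE],
                                  features$mask[seq_len(m)])
    stab <- si_table(feat_prefix, onsets[seq_len(bootstrap_n)],
                     causal = TRUE, seed = seed)
    sel <- select_channel(stab$si)
    channels <- as.list(stats::setNames(as.integer(sel), colnames(stab$si)))
  }
  # scoring-time edge phases for every seizure, filled in as they occur;
  # the bootstrap seizures get theirs retroactively (each still computed
  # from data strictly preceding its own onset)
  comp <- names(channels)
  stored <- matrix(NA_real_, length(onsets), length(comp),
                   dimnames = list(NULL, comp))
  for (i in seq_len(bootstrap_n)) {
    ppi <- m2_prefix_phases(features, channels, onsets[i], seed)
    if (ppi$m >= 1 &&
        all(vapply(ppi$phases, function(ph) ph$validity[ppi$m], logical(1))))
      stored[i, ] <- ppi$edge[comp]
  }
  fit <- m2_fit(features, channels, onsets, t_boot, window_days, n_bins, seed,
                stored = stored, smoothing = smoothing)
  refits <- fit$fit_time_h
  n_fc <- length(onsets) - bootstrap_n
  seizure_levels <- rep(NA_real_, n_fc)
  seizure_p <- rep(NA_real_, n_fc)
  stitched_levels <- list()
  stitched_trace <- list()
  last_m <- findInterval(t_boot, features$times_h)
  for (j in seq_len(n_fc)) {
    onset <- onsets[bootstrap_n + j]
    pp <- m2_prefix_phases(features, channels, onset, seed)
    tr <- combine_probabilities(fit$model, pp$phases)
    # frozen model's levels over the new interval (last_m, pp$m]
    if (pp$m > last_m) {
      seg <- (last_m + 1L):pp$m
      stitched_trace[[j]] <- tr[seg]
      stitched_levels[[j]] <- ifelse(tr[seg] >= fit$th2, 3L,
                                     ifelse(tr[seg] >= fit$th1, 2L, 1L))
    }
    # scoring lookup uses the edge-stabilized causal phase estimates (the
    # raw Hilbert phase is unreliable at the prefix's leading edge)
    p_prior <- NA_real_
    if (pp$m >= 1 &&
        all(vapply(pp$phases, function(ph) ph$validity[pp$m], logical(1)))) {
      stored[bootstrap_n + j, ] <- pp$edge[comp]
      p_prior <- 1
      for (nm in names(fit$model)) {
        nb <- length(fit$model[[nm]]$p)
        p_prior <- p_prior * fit$model[[nm]]$p[phase_bin(pp$edge[[nm]], nb)]
      }
    }
    seizure_p[j] <- p_prior
    if (is.finite(p_prior))
      seizure_levels[j] <- if (p_prior >= fit$th2) 3 else if (p_prior >= fit$th1) 2 else 1
    last_m <- pp$m
    # refit at the seizure time, reusing the phases just computed (the
    # prefix ends at the sample prior to onset in both cases)
    fit <- m2_fit(features, channels, onsets, onset, window_days,
                  n_bins, seed, stored = stored, pp = pp,
                  smoothing = smoothing)
    refits <- c(refits, fit$fit_time_h)
  }
  # tail after the last seizure
  nall <- length(features$times_h)
  if (nall > last_m) {
    pp <- m2_prefix_phases(features, channels,
                           features$times_h[nall] + 1e-6, seed)
    tr <- combine_probabilities(fit$model, pp$phases)
    seg <- (last_m + 1L):nall
    stitched_trace[[n_fc + 1L]] <- tr[seg]
    stitched_levels[[n_fc + 1L]] <- ifelse(tr[seg] >= fit$th2, 3L,
                                           ifelse(tr[seg] >= fit$th1, 2L, 1L))
  }
  levels <- unlist(stitched_levels)
  trace <- unlist(stitched_trace)
  report <- score_forecast(levels, seizure_levels, trace, seizure_p, "M2")
  ma5 <- as.numeric(causal_moving_average(seizure_levels, 5))
  structure(list(report = report, seizure_levels = seizure_levels,
                 seizure_p = seizure_p, risk_ma5 = ma5,
                 refit_times_h = refits, channels = channels,
                 levels = levels, trace = trace),
            class = "m2_forecast")
}

#' Random Markov chance predictor
#'
#' Estimates the 3x3 transition matrix of a reference risk-level sequence,
#' simulates `n_sims` independent chains of the same length, and scores the
#' actual seizures against each simulated chain. The resulting distribution
#' of performance products is the chance benchmark.
#'
#' @param reference_levels Reference risk-level sequence (Method M1's).
#' @param seizure_sample_index Sample index of each seizure's scoring
#'   sample in that sequence.
#' @param n_sims Number of simulated chains.
#' @param seed Seed.
#' @return List of class `random_forecast`: `transition`, `sims`
#'   (data.frame: performance_product, seizure_high, time_low, mean_risk),
#'   and a `forecast_report` for the first chain.
#' @export
random_markov_predictor <- function(reference_levels, seizure_sample_index,
                                    n_sims = 100, seed = 1) {
  lv <- reference_levels
  okpos <- which(is.finite(lv))
  if (length(okpos) < 2) stop("reference trace too short")
  from <- lv[okpos[-length(okpos)]]; to <- lv[okpos[-1]]
  P <- matrix(0, 3, 3)
  for (s in 1:3) {
    tos <- to[from == s]
    if (length(tos) > 0) P[s, ] <- tabulate(tos, 3) / length(tos)
    else P[s, s] <- 1  # state never visited: absorbing placeholder
  }
  absorbing <- any(diag(P) == 1 & rowSums(P > 0) == 1)
  n <- length(lv)
  rng <- local_rng(seed, "markov")
  U <- matrix(rng$runif(n * n_sims), n, n_sims)
  C1 <- cumsum(P[1, ])[1:2]; C2 <- cumsum(P[2, ])[1:2]; C3 <- cumsum(P[3, ])[1:2]
  Ccut1 <- rbind(C1, C2, C3)[, 1]
  Ccut2 <- rbind(C1, C2, C3)[, 2]
  L <- matrix(NA_integer_, n, n_sims)
  s <- rep(lv[okpos[1]], n_sims)
  L[1, ] <- s
  for (t in 2:n) {
    u <- U[t, ]
    s <- 1L + (u > Ccut1[s]) + (u > Ccut2[s])
    L[t, ] <- s
  }
  sidx <- seizure_sample_index[is.finite(seizure_sample_index) &
                                 seizure_sample_index >= 1]
  sims <- data.frame(performance_product = numeric(n_sims),
                     seizure_high = numeric(n_sims),
                     time_low = numeric(n_sims),
                     mean_risk = numeric(n_sims))
  for (k in seq_len(n_sims)) {
    lvk <- L[, k]
    tf <- tabulate(lvk, 3) / n
    slk <- lvk[sidx]
    sf <- tabulate(slk, 3) / length(slk)
    sims$performance_product[k] <- sf[3] * tf[1]
    sims$seizure_high[k] <- sf[3]
    sims$time_low[k] <- tf[1]
    sims$mean_risk[k] <- mean(slk)
  }
  rep1 <- score_forecast(L[, 1], L[sidx, 1], method = "random")
  structure(list(transition = P, sims = sims, report = rep1,
                 absorbing = absorbing),
            class = "random_forecast")
}
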