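# Biomarker estimators: filtering, variance, ACF/ACFW, spike detection,
# peri-seizure profiles.

test_that("the 170 Hz FIR filter passes the band and kills the artifact", {
  fs <- 400
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  # DC passes (within ripple)
  expect_equal(preprocess_segment(rep(7, 3 * fs), fs), rep(7, fs),
               tolerance = 1e-3)
  # 190 Hz (charger-artifact band) attenuated below 5% RMS
  y190 <- sin(2 * pi * 190 * t)
  out <- preprocess_segment(y190, fs)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(y190^2)), 0.05)
  # 10 Hz passband within 2%
  y10 <- sin(2 * pi * 10 * t)
  out10 <- preprocess_segment(y10, fs)
  expect_equal(sqrt(mean(out10^2)), sqrt(mean(y10^2)), tolerance = 0.02)
  expect_error(preprocess_segment(numeric(100), fs), "malformed")
  # analytic response of the designed filter agrees with the measured one
  h <- fir_lowpass(170, fs)
  expect_lt(czdown:::fir_response(h, 190, fs), 0.05)
  expect_equal(czdown:::fir_response(h, 10, fs), 1, tolerance = 0.02)
})

test_that("segment variance is the population variance", {
  expect_equal(segment_variance(c(2, 2, 2, 2)), 0)
  expect_equal(segment_variance(c(1, -1, 1, -1)), 1)
  expect_equal(segment_variance(c(0, 2)), 1)
  expect_true(is.na(segment_variance(c(1, NA, 3))))
  expect_error(segment_variance(3), "too short")
})

test_that("ACF matches a brute-force double loop to 1e-12", {
  set.seed(42)
  for (i in 1:20) {
    y <- rnorm(50)
    C <- autocorrelation_function(y, 20)
    yc <- y - mean(y)
    V <- mean(yc^2)
    brute <- vapply(0:20, function(l) {
      s <- 0
      for (t in seq_len(50 - l)) s <- s + yc[t] * yc[t + l]
      s / (50 * V)
    }, numeric(1))
    expect_lt(max(abs(C - brute)), 1e-12)
    expect_equal(C[1], 1)
  }
  expect_error(autocorrelation_function(rep(3, 10), 5), "degenerate")
})

test_that("cosine and white-noise ACFs look as they should", {
  y <- cos(2 * pi * (0:399) / 60)
  C <- autocorrelation_function(y, 60)
  expect_equal(C[1 + 1:30], cos(2 * pi * (1:30) / 60), tolerance = 0.08)
  set.seed(1)
  worst <- max(vapply(1:100, function(i) {
    C <- autocorrelation_function(rnorm(400), 50)
    max(abs(C[6:51]))
  }, numeric(1)))
  expect_lt(worst, 0.3)  # null bound, loose for the worst of 100 draws
  expect_true(mean(vapply(1:100, function(i) {
    C <- autocorrelation_function(rnorm(400), 50)
    max(abs(C[6:51])) < 0.15
  }, logical(1))) > 0.5)
})

test_that("ACF half-width hits the closed-form crossings", {
  # cosine of period 60: cos(2 pi 10 / 60) = 0.5 exactly at lag 10
  y <- cos(2 * pi * (0:399) / 60)
  w <- acf_halfwidth(autocorrelation_function(y, 200))
  expect_equal(as.numeric(w), 10, tolerance = 0.5)
  # AR(1) a = 0.9: a^lag = 0.5 at lag ln 2 / ln(1/0.9) = 6.58
  y9 <- make_ar1(1e5, 0.9, seed = 2)
  w9 <- acf_halfwidth(autocorrelation_function(y9, 50))
  expect_equal(as.numeric(w9), log(2) / log(1 / 0.9), tolerance = 0.5)
  # monotonicity in a on matched noise
  y95 <- make_ar1(1e5, 0.95, seed = 2)
  w95 <- acf_halfwidth(autocorrelation_function(y95, 100))
  expect_gt(w95, w9)
  # saturation flag
  ws <- acf_halfwidth(c(1, rep(0.9, 10)))
  expect_true(attr(ws, "saturated"))
  expect_equal(as.numeric(ws), 10)
  expect_error(acf_halfwidth(c(0.9, 0.5)), "C_0")
})

test_that("half-width is invariant to scaling and offset", {
  y <- make_ar1(2000, 0.8, seed = 3)
  w0 <- as.numeric(acf_halfwidth(autocorrelation_function(y, 100)))
  w1 <- as.numeric(acf_halfwidth(autocorrelation_function(5 * y + 100, 100)))
  expect_equal(w0, w1, tolerance = 1e-10)
})

test_that("compiled batch half-width equals the per-segment reference", {
  set.seed(4)
  Y <- cbind(matrix(rnorm(400 * 30), 400),
             replicate(10, make_ar1(400, 0.9, seed = sample(1e4, 1))))
  hb <- czdown:::halfwidth_batch(Y, 200)
  ref <- vapply(seq_len(ncol(Y)), function(j)
    as.numeric(acf_halfwidth(autocorrelation_function(Y[, j], 200))),
    numeric(1))
  expect_equal(hb$width, ref, tolerance = 1e-10)
  expect_equal(hb$variance,
               apply(Y, 2, function(v) mean((v - mean(v))^2)),
               tolerance = 1e-12)
  # degenerate column
  Yd <- cbind(Y[, 1], rep(2, 400))
  expect_true(is.na(czdown:::halfwidth_batch(Yd, 200)$width[2]))
})

test_that("spike detection finds exact copies and rejects flipped ones", {
  tpl <- default_spike_template(400)
  set.seed(5)
  y <- rep(0, 400)
  y[100:(99 + length(tpl))] <- tpl
  d <- detect_spikes(y + rnorm(400) * 1e-6, tpl)
  expect_equal(d$count, 1)
  expect_equal(d$positions, 100)
  expect_gt(d$correlations, 0.999)
  # signed correlation: a flipped copy does not match
  d2 <- detect_spikes(-y + rnorm(400) * 1e-6, tpl)
  expect_equal(d2$count, 0)
  expect_error(detect_spikes(y, rep(1, 20)), "flat")
  expect_error(detect_spikes(y[1:50], tpl), "shorter")
})

test_that("detection against simulator ground truth is sensitive and specific", {
  hits <- 0; total <- 0; fp <- 0; nseg <- 0
  for (s in 0:4) {
    cfg <- quick_config(duration_days = 2, spike_rate_base = 200,
                        spike_rate_channel_sdlog = 0, spike_snr = 5,
                        noise_sd = 0, seed = s)
    rec <- simulate_recording(cfg)
    feats <- extract_features(rec$segments, template = cfg$spike_template)
    truth_counts <- tabulate(rec$spike_truth$segment,
                             nbins = length(feats$times_h))
    det <- feats$spike_rate[, 1]
    hits <- hits + sum(pmin(det, truth_counts))
    total <- total + sum(truth_counts)
    fp <- fp + sum(pmax(det - truth_counts, 0))
    nseg <- nseg + length(det)
  }
  expect_gt(hits / total, 0.95)
  expect_lt(fp / nseg, 1)
})

test_that("template building averages and aligns candidates", {
  tpl <- default_spike_template(400)
  expect_equal(build_spike_template(list(tpl, tpl)), tpl, tolerance = 1e-12)
  set.seed(6)
  cands <- lapply(1:30, function(i) tpl + rnorm(length(tpl), sd = 0.4))
  avg <- build_spike_template(cands)
  cor_avg <- cor(avg, tpl)
  cor_each <- vapply(cands, function(c) cor(c, tpl), numeric(1))
  expect_gte(cor_avg, max(cor_each))
  # 3-sample shift corrected by alignment
  shifted <- list(c(tpl[-(1:3)], rep(0, 3)), c(rep(0, 3), tpl[1:(length(tpl) - 3)]))
  expect_gt(cor(build_spike_template(shifted), tpl), 0.99)
  expect_error(build_spike_template(list(tpl)), "at least 2")
  expect_error(build_spike_template(list(tpl, tpl[-1])), "equal length")
})

test_that("masked segments yield missing features, never numbers", {
  cfg <- quick_config(duration_days = 1)
  rec <- simulate_recording(cfg)
  segs <- inject_dropouts(rec$segments, data.frame(start_h = 5, length_h = 3))
  feats <- extract_features(segs)
  expect_true(all(is.na(feats$acfw[segs$mask, ])))
  expect_true(all(is.na(feats$variance[segs$mask, ])))
  expect_true(all(is.na(feats$spike_rate[segs$mask, ])))
  expect_false(anyNA(feats$acfw[!segs$mask, ]))
})

test_that("measured ACFW recovers the configured correlation time within 15%", {
  # directly rendered AR(1) segments at known a; expected half-width is
  # the first 0.5-crossing of a^lag (approx, finite-segment bias shrinks it)
  set.seed(7)
  for (a in c(0.7, 0.85, 0.92)) {
    Y <- replicate(300, as.numeric(stats::arima.sim(list(ar = a), 400)))
    w <- mean(czdown:::halfwidth_batch(Y, 200)$width)
    expect_equal(w, log(2) / log(1 / a), tolerance = 0.15 * log(2) / log(1 / a))
  }
})

test_that("peri-seizure profiles normalize and locate peak/trough", {
  # stationary input, fake onset: flat normalized profile
  set.seed(8)
  fs <- 400
  y <- as.numeric(stats::arima.sim(list(ar = 0.8), 2 * 3600 * fs / 10))  # 12 min
  tm <- seq_along(y) / fs - 360
  pp <- periseizure_profile(tm, y, duration_s = 60, rate_hz = fs)
  bl <- pp$rel_time_s >= -300 & pp$rel_time_s < 0
  expect_equal(mean(pp$acfw_norm[bl]), 1, tolerance = 1e-9)
  expect_lt(abs(mean(pp$acfw_norm) - 1), 0.15)
  expect_true(pp$peak$time_s <= pp$trough$time_s)

  # both overlap readings produce the advertised window steps
  pp_share <- periseizure_profile(tm, y, 60, fs, overlap = "share")
  pp_step <- periseizure_profile(tm, y, 60, fs, overlap = "step")
  expect_equal(diff(pp_share$rel_time_s[1:2]), 4.5, tolerance = 1e-6)
  expect_equal(diff(pp_step$rel_time_s[1:2]), 0.5, tolerance = 1e-6)

  # simulator slow-approach seizure: ACFW rises into the onset, drops after
  cfg <- quick_config(duration_days = 2, noise_sd = 0, k_ramp = c(-50, 210),
                      measurement_noise_sd = 0.05)
  traj <- simulate_state(cfg)
  cat <- label_seizures(traj)
  cs <- synthesize_continuous(traj, cfg, cat$onset_h[1], span_h = 0.5,
                              catalog = cat)
  pp2 <- periseizure_profile(cs$time_s, cs$y, cat$duration_s[1], cfg$segment_rate_hz)
  expect_gt(pp2$peak$value, 1)
  expect_lt(pp2$trough$value, pp2$peak$value)
})
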