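# Moving averages, cycle decomposition, gap filling, Hilbert phases,
# dominant periods.

test_that("causal moving average: identity, constants, steps, warm-up", {
  x <- rnorm(50)
  expect_equal(as.numeric(causal_moving_average(x, 1)), x)
  expect_equal(as.numeric(causal_moving_average(rep(3, 20), 7)), rep(3, 20))
  step <- c(rep(0, 10), rep(1, 10))
  out <- as.numeric(causal_moving_average(step, 4))
  expect_equal(out[11:14], c(0.25, 0.5, 0.75, 1))
  expect_true(all(attr(causal_moving_average(x, 10), "reduced_support")[1:9]))
})

test_that("causal filters never look ahead (truncation property)", {
  set.seed(9)
  x <- rnorm(3000)
  full <- decompose_rhythms(x)
  pre <- decompose_rhythms(x[1:2000])
  expect_equal(full$long[1:2000], pre$long)
  expect_equal(full$short[1:2000], pre$short)
})

test_that("decomposition separates long and short periods", {
  cad <- 2 / 60  # hours
  t_h <- seq(0, 60 * 24 - cad, by = cad)
  # 10-day sinusoid stays in the long cycle
  x10 <- sin(2 * pi * t_h / (24 * 10))
  d10 <- decompose_rhythms(x10)
  n <- length(t_h)
  late <- (n %/% 2):n  # skip warm-up
  # analytic amplitude response of a W-point MA at frequency f (per sample)
  ma_gain <- function(W, period_samples) {
    f <- 1 / period_samples
    abs(sin(pi * f * W) / (W * sin(pi * f)))
  }
  g <- ma_gain(1440, 10 * 720)
  expect_equal(stats::sd(d10$long[late]) * sqrt(2), g, tolerance = 0.05)
  # the causal MA lags by ~half a window, so the residual (hence the short
  # cycle) retains the lag-induced leakage |1 - g e^{-i phi}| of the long
  # period; the zero-phase (forward-backward) variant suppresses it < 15%
  phi <- 2 * pi * 719.5 / 7200
  leak <- Mod(1 - g * exp(-1i * phi)) * ma_gain(20, 7200)
  expect_equal(max(abs(d10$short[late])), leak, tolerance = 0.1)
  d10z <- decompose_rhythms(x10, causal = FALSE)
  # exclude the backward-pass warm-up at the record end
  late_z <- late[late <= n - 1440]
  expect_lt(max(abs(d10z$short[late_z])), 0.15)

  # 24-h sinusoid: the 2-day MA window holds exactly two periods -> null
  x24 <- sin(2 * pi * t_h / 24)
  d24 <- decompose_rhythms(x24)
  expect_lt(stats::sd(d24$long[late]), 0.02)
  expect_equal(stats::sd(d24$short[late]) * sqrt(2),
               ma_gain(20, 720), tolerance = 0.05)

  # white noise: variance reduction ~ window length
  set.seed(10)
  w <- rnorm(n)
  dw <- decompose_rhythms(w)
  expect_lt(stats::var(dw$long[late]), stats::var(dw$short[late]))
})

test_that("gap filling follows the < 2 h rule exactly", {
  set.seed(11)
  x <- rnorm(5000, mean = 5, sd = 2)
  x[1001:1059] <- NA  # 59 samples: filled
  x[3001:3061] <- NA  # 61 samples: left missing
  fg <- fill_gaps(x, max_gap = 60, seed = 1)
  expect_false(anyNA(fg$filled[1001:1059]))
  expect_true(all(is.na(fg$filled[3001:3061])))
  expect_equal(nrow(fg$long_gaps), 1)
  expect_equal(fg$long_gaps$start, 3001)
  # exactly 60 stays missing (< 2 h rule is strict)
  x2 <- rnorm(1000); x2[101:160] <- NA
  expect_true(all(is.na(fill_gaps(x2, 60, 1)$filled[101:160])))
  # no gaps: identity
  y <- rnorm(100)
  expect_identical(fill_gaps(y, 60, 1)$filled, y)
  expect_error(fill_gaps(rep(NA_real_, 10)), "entirely missing")
})

test_that("fill values are deterministic and match the global statistics", {
  x <- rnorm(20000, mean = 7, sd = 3)
  x[5001:5050] <- NA
  f1 <- fill_gaps(x, seed = 4)
  f2 <- fill_gaps(x, seed = 4)
  expect_identical(f1$filled, f2$filled)
  # across seeds, fill mean/sd consistent with global stats (3 sigma)
  fills <- unlist(lapply(0:19, function(s) fill_gaps(x, seed = s)$filled[5001:5050]))
  expect_lt(abs(mean(fills) - mean(x, na.rm = TRUE)),
            3 * sd(x, na.rm = TRUE) / sqrt(length(fills)))
  expect_equal(sd(fills), sd(x, na.rm = TRUE), tolerance = 0.2)
})

test_that("analytic phase follows the cosine convention", {
  n <- 10000; P <- 500
  x <- cos(2 * pi * (0:(n - 1)) / P)
  ap <- analytic_phase(x, exclude_edges = "none")
  maxima <- seq(1, n, by = P)
  expect_lt(max(abs(ap$phase[maxima[5:15]])), 0.05)
  # phase advances 2 pi per period
  expect_equal(diff(ap$phase[c(2000, 2100)]), 2 * pi * 100 / P, tolerance = 0.02)
  # sine lags cosine by pi/2 (phase at the same sample differs by -pi/2)
  aps <- analytic_phase(sin(2 * pi * (0:(n - 1)) / P), exclude_edges = "none")
  mid <- 3000:7000
  d <- czdown:::wrap_phase(aps$phase[mid] - ap$phase[mid])
  expect_equal(mean(d), -pi / 2, tolerance = 0.02)
  # rising zero-crossing of the cosine has phase -pi/2
  rising <- maxima[10] - P / 4
  expect_equal(ap$phase[rising], -pi / 2, tolerance = 0.05)
  # circular mean of the phase at the cosine's own maxima is ~0
  mm <- maxima[maxima > 60 & maxima < n - 60]
  expect_lt(abs(synchronization_index(ap$phase[mm])$mean_phase), 0.05)
})

test_that("phase validity excludes long gaps, their margins, and edges", {
  n <- 5000
  x <- cos(2 * pi * (0:(n - 1)) / 700) + rnorm(n, sd = 0.1)
  x[2001:2100] <- NA  # 100 >= 60: long gap
  ap <- analytic_phase(x, max_gap = 60, boundary = 60, exclude_edges = "both")
  expect_true(all(!ap$validity[(2001 - 60):(2100 + 60)]))
  expect_true(all(ap$validity[(2100 + 61):(n - 60)]))
  expect_true(all(!ap$validity[1:60]))
  expect_true(all(!ap$validity[(n - 59):n]))
  expect_true(all(is.finite(ap$phase)))  # noise-filled, computable everywhere
  # "start" mode keeps the trailing edge valid (M2)
  ap2 <- analytic_phase(x, exclude_edges = "start")
  expect_true(ap2$validity[n])
  expect_false(ap2$validity[1])
})

test_that("dominant periods recover injected cycles within one FFT bin", {
  cad_h <- 2 / 60
  t_h <- seq(0, 60 * 24 - cad_h, by = cad_h)  # 60-day record
  set.seed(12)
  x <- 3 * sin(2 * pi * t_h / 24) + 2 * sin(2 * pi * t_h / (24 * 10)) +
    rnorm(length(t_h), sd = 0.5)
  dp <- dominant_periods(x)
  bin <- attr(dp, "bin_width_d_inv")
  expect_true(any(dp$circadian))
  expect_true(any(dp$multidien))
  p1 <- dp$period_d[dp$circadian][1]
  p10 <- dp$period_d[dp$multidien][1]
  expect_lt(abs(1 / p1 - 1), bin + 1e-9)
  expect_lt(abs(1 / p10 - 1 / 10), bin + 1e-9)

  # pure circadian: no multidien flag
  xp <- sin(2 * pi * t_h / 24)
  dpp <- dominant_periods(xp)
  expect_true(any(dpp$circadian))
  expect_false(any(dpp$multidien))

  # white noise: no peaks at all over seeds
  for (s in 1:5) {
    set.seed(s)
    expect_equal(nrow(dominant_periods(rnorm(43200))), 0)
  }
  # a 3-hour record cannot support a multidien search
  expect_error(dominant_periods(rnorm(100), cadence_min = 2, min_period_d = 3),
               "insufficient")
})

test_that("decompose after fill is idempotent on gap-free input", {
  set.seed(13)
  x <- rnorm(4000)
  fg <- fill_gaps(x)
  expect_identical(fg$filled, x)
  d1 <- decompose_rhythms(x)
  d2 <- decompose_rhythms(fill_gaps(x)$filled)
  expect_identical(d1$long, d2$long)
  expect_identical(d1$short, d2$short)
})

test_that("simulator multidien period is recovered from features", {
  cfg <- quick_config(duration_days = 60, noise_sd = 0.05,
                      multidien_period_d = 10, seed = 2)
  rec <- simulate_recording(cfg)
  feats <- extract_features(rec$segments)
  dp <- dominant_periods(feats$acfw[, 1])
  expect_true(any(dp$multidien))
  bin <- attr(dp, "bin_width_d_inv")
  p <- dp$period_d[dp$multidien][1]
  expect_lt(abs(1 / p - 1 / 10), bin + 1e-9)
})
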