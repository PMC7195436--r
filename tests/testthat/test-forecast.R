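# Probability tables, threshold optimization, risk scoring, M1/M2,
# random predictor.

test_that("probability given phase matches arithmetic and a counting oracle", {
  # 10 seizures in one bin visited 100 times
  phase <- rep(0.05, 100)  # bin 11 of 20
  seiz <- rep(0.05, 10)
  tab <- probability_given_phase(phase, rep(TRUE, 100), seiz)
  b <- czdown:::phase_bin(0.05, 20)
  expect_equal(tab$p[b], 0.1)
  expect_equal(sum(tab$S), 10)
  expect_true(all(tab$p[tab$empty] == 0))
  # visited bin with no seizures -> 0
  expect_equal(tab$p[czdown:::phase_bin(0.05, 20)] > 0, TRUE)
  ph2 <- c(rep(0.05, 50), rep(2, 50))
  tab2 <- probability_given_phase(ph2, rep(TRUE, 100), seiz)
  expect_equal(tab2$p[czdown:::phase_bin(2, 20)], 0)

  # counting oracle on random data (exact)
  set.seed(22)
  ph <- runif(5000, -pi, pi)
  v <- runif(5000) > 0.1
  sz <- runif(60, -pi, pi)
  tab3 <- probability_given_phase(ph, v, sz)
  for (b in 1:20) {
    lo <- -pi + (b - 1) * 2 * pi / 20
    hi <- lo + 2 * pi / 20
    Nb <- sum(ph >= lo & ph < hi & v)
    Sb <- sum(sz >= lo & sz < hi)
    expect_equal(tab3$N[b], Nb)
    expect_equal(tab3$S[b], Sb)
    expect_equal(tab3$p[b], if (Nb > 0) Sb / Nb else 0)
  }

  # uniform phases and seizures: bins approach N_seiz / N_samples
  expect_equal(mean(tab3$p), length(sz) / sum(v), tolerance = 0.3)
  expect_error(probability_given_phase(ph, v, numeric(0)), "untrainable")
})

test_that("Laplace smoothing floors empty visited bins without reordering", {
  phase <- runif(2000, -pi, pi)
  sz <- rep(0.05, 10)
  t0 <- probability_given_phase(phase, rep(TRUE, 2000), sz, smoothing = 0)
  t1 <- probability_given_phase(phase, rep(TRUE, 2000), sz, smoothing = 0.5)
  expect_true(all(t1$p[t1$N > 0] > 0))
  expect_equal(which.max(t0$p), which.max(t1$p))
})

test_that("combining probabilities multiplies and masks", {
  mk <- function(p) structure(list(p = rep(p, 20)), class = "phase_prob_table")
  phases <- list(a = list(phase = rep(0, 5), validity = rep(TRUE, 5)),
                 b = list(phase = rep(0, 5), validity = c(TRUE, TRUE, FALSE, TRUE, TRUE)))
  tr <- combine_probabilities(list(a = mk(1), b = mk(1)), phases)
  expect_equal(tr, c(1, 1, NA, 1, 1))
  tr2 <- combine_probabilities(list(a = mk(0.1), b = mk(0.5)), phases)
  expect_equal(tr2[1], 0.05)
  tr3 <- combine_probabilities(list(a = mk(0), b = mk(0.5)), phases)
  expect_equal(tr3[1], 0)
})

test_that("threshold optimization solves the 3-level example exactly", {
  # trace: 0.1 (90%), 0.5 (7%), 0.9 (3%); all seizures at 0.9
  trace <- c(rep(0.1, 900), rep(0.5, 70), rep(0.9, 30))
  sz <- rep(0.9, 10)
  opt <- optimize_thresholds(trace, sz, mode = "strict")
  expect_equal(as.numeric(opt$objective), 0.9, tolerance = 1e-12)
  expect_true(opt$th1 > 0.1 && opt$th1 <= 0.5)
  expect_true(opt$th2 > 0.5 && opt$th2 <= 0.9)
  rt <- risk_trace(seq_along(trace), trace, opt$th1, opt$th2)
  expect_equal(as.numeric(table(rt$level)) / 1000, c(0.9, 0.07, 0.03))

  # all seizures at the minimum: C4 unsatisfiable in strict mode
  expect_error(optimize_thresholds(trace, rep(0.1, 5), mode = "strict"),
               "no-solution")
  # constant trace: degenerate
  opt2 <- optimize_thresholds(rep(0.3, 100), rep(0.3, 4), mode = "relaxed")
  expect_true(opt2$degenerate)
})

test_that("the optimizer equals an independent exhaustive search", {
  set.seed(23)
  for (i in 1:10) {
    trace <- sample(seq(0, 1, by = 0.05), 200, replace = TRUE)
    sz <- sample(trace, 8)
    opt <- optimize_thresholds(trace, sz, mode = "relaxed")
    # brute force over all candidate pairs, straight from the definitions
    cand <- c(sort(unique(trace)), max(trace) + 1)
    best <- -1
    for (a in cand) for (b in cand) {
      if (a > b) next
      obj <- mean(trace < a) * mean(sz >= b)
      if (obj > best) best <- obj
    }
    expect_equal(opt$objective, best, tolerance = 1e-12)
  }
})

test_that("risk trace boundaries are right-closed at the thresholds", {
  rt <- risk_trace(1:5, c(0.05, 0.2, 0.5, 0.7, NA), th1 = 0.2, th2 = 0.7)
  expect_equal(rt$level[1:4], c(1L, 2L, 2L, 3L))  # p = Th1 -> medium, p = Th2 -> high
  expect_true(is.na(rt$level[5]))
  expect_error(risk_trace(1:2, c(0.1, 0.2), 0.5, 0.4))
})

test_that("scoring computes the performance product and a sane ROC", {
  # Patient-1-style proportions: 90% of seizures high, 95% of time low
  levels <- c(rep(1L, 950), rep(2L, 20), rep(3L, 30))
  seiz <- c(rep(3L, 18), rep(2L, 1), rep(1L, 1))
  rep1 <- score_forecast(levels, seiz, trace = runif(1000),
                         seizure_p = runif(20), method = "M1")
  expect_equal(sum(rep1$time_fraction), 1)
  expect_equal(sum(rep1$seizure_fraction), 1)
  expect_equal(as.numeric(rep1$performance_product), 0.9 * 0.95,
               tolerance = 1e-12)
  expect_equal(rep1$mean_risk_level, mean(seiz))
  roc <- rep1$roc
  expect_equal(roc$fpr[1], 1); expect_equal(roc$sensitivity[1], 1)
  expect_equal(roc$fpr[nrow(roc)], 0); expect_equal(roc$sensitivity[nrow(roc)], 0)
  expect_true(all(diff(roc$fpr) <= 0))
  expect_error(score_forecast(levels, numeric(0)), "zero scored")
})

test_that("the random Markov predictor reproduces chain structure", {
  # near-identity transitions: the chain stays at its start
  ref <- c(rep(1L, 500), rep(2L, 10), rep(3L, 10), rep(1L, 480))
  rmp <- random_markov_predictor(rep(c(1L, 1L, 1L, 1L), 250), c(10, 500),
                                 n_sims = 3, seed = 1)
  expect_true(all(rmp$sims$time_low == 1))

  # uniform transitions: long-run occupancy ~ 1/3 each
  set.seed(24)
  ref_u <- sample(1:3, 20000, replace = TRUE)
  rmp_u <- random_markov_predictor(ref_u, sample(20000, 50), n_sims = 10, seed = 2)
  expect_equal(mean(rmp_u$sims$time_low), 1 / 3, tolerance = 0.05)
  expect_true(all(abs(rmp_u$transition - 1 / 3) < 0.02))

  # chance sensitivity ~ chain's own time-in-high
  expect_equal(mean(rmp_u$sims$seizure_high), mean(1 - rmp_u$sims$time_low) / 2,
               tolerance = 0.06)
})

test_that("M1 separates phase-locked seizures and sums its fractions", {
  fx <- make_rhythmic_features(days = 60, seed = 25, n_seiz = 45)
  m1 <- forecast_m1(fx$features, fx$catalog, seed = 1)
  r <- m1$report
  expect_equal(sum(r$time_fraction), 1, tolerance = 1e-9)
  expect_gt(r$seizure_fraction["high"], r$seizure_fraction["low"])
  expect_gt(r$performance_product, 0.2)
})

test_that("M1 collapses toward chance when seizures are phase-uniform", {
  fx_l <- make_rhythmic_features(days = 60, seed = 26, n_seiz = 45)
  fx_u <- make_rhythmic_features(days = 60, seed = 26, n_seiz = 100,
                                 locked = FALSE)
  m1_l <- forecast_m1(fx_l$features, fx_l$catalog, seed = 1)
  m1_u <- forecast_m1(fx_u$features, fx_u$catalog, seed = 1)
  # the uniform case retains only in-sample optimism, far below real locking
  expect_lt(m1_u$report$performance_product,
            0.6 * m1_l$report$performance_product)
})

test_that("M2 is causal: truncation after seizure j preserves earlier levels", {
  fx <- make_rhythmic_features(days = 50, seed = 27, n_seiz = 30)
  m2 <- forecast_m2(fx$features, fx$catalog, seed = 1)
  expect_equal(m2$refit_times_h[-1], fx$catalog$onset_h[-(1:10)])
  n_seiz <- nrow(fx$catalog)
  expect_gte(n_seiz, 20)
  for (j in c(14, 17, n_seiz - 1)) {
    cut_h <- fx$catalog$onset_h[j] + 0.2
    keep <- fx$features$times_h < cut_h
    f2 <- feature_series(fx$features$times_h[keep],
                         fx$features$acfw[keep, , drop = FALSE],
                         fx$features$variance[keep, , drop = FALSE],
                         fx$features$spike_rate[keep, , drop = FALSE],
                         fx$features$mask[keep])
    c2 <- fx$catalog[fx$catalog$onset_h < cut_h, ]
    m2t <- forecast_m2(f2, c2, seed = 1)
    expect_identical(m2t$seizure_levels, m2$seizure_levels[seq_len(j - 10)])
  }
})

test_that("M2 assigns high risk under strong stationary locking", {
  fx <- make_rhythmic_features(days = 60, seed = 28, n_seiz = 45,
                               jitter_h = 0.5)
  m2 <- forecast_m2(fx$features, fx$catalog, seed = 1)
  expect_gt(m2$report$mean_risk_level, 2)
  expect_gt(m2$report$seizure_fraction["high"],
            m2$report$seizure_fraction["low"])
  expect_equal(length(m2$seizure_levels), nrow(fx$catalog) - 10)
  expect_error(forecast_m2(fx$features, fx$catalog[1:10, ], seed = 1),
               "insufficient history")
})
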