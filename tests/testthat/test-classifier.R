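test_that("feature signal of a constant segment is zero", {
  x <- signal1d(rep(5, 4000), 5000)
  f <- feature_signal(x, 1500, 2000, morph_params())
  expect_equal(max(abs(f$samples)), 0)
})

test_that("feature extraction: narrow vs wide pulses against the morphology oracle", {
  fs <- 5000
  # smoothing disabled (1-sample window) so the pulse width in the feature
  # domain is the pulse width in |diff|
  mp <- morph_params(smooth_ms = 0.1, close_ms = 1, open_ms = 4)
  n <- 4000L
  base <- numeric(n)
  # pulse narrower than the opening window -> truncated to ~background;
  # plateau wider than the opening window -> opening cannot remove it.
  narrow <- base; narrow[2001:2005] <- 10          # 1 ms wide
  wide <- base; wide[1800:2200] <- 10              # 80 ms wide
  for (v in list(narrow, wide)) {
    x <- signal1d(cumsum(v) / fs, fs)  # integrate so |diff| reproduces v shape
    fe <- extract_features(x, 1900, 2300, mp)
    expect_lte(fe$truncated_level, fe$envelope_peak + 1e-12)
  }
  fn <- extract_features(signal1d(cumsum(narrow) / fs, fs), 1900, 2300, mp)
  fw <- extract_features(signal1d(cumsum(wide) / fs, fs), 1900, 2300, mp)
  # narrow pulse: opening removes nearly everything
  expect_lt(fn$truncated_level, 0.35 * fn$envelope_peak)
  # wide plateau: opening leaves the level nearly intact
  expect_gt(fw$truncated_level, 0.9 * fw$envelope_peak)
  # zero segment
  fz <- extract_features(signal1d(base + 1, fs), 1900, 2300, mp)
  expect_equal(fz$envelope_peak, 0)
  expect_equal(fz$truncated_level, 0)
})

test_that("truncated_level <= envelope_peak on random events", {
  set.seed(77)
  x <- rand_signal(20000, 5000)
  for (i in 1:25) {
    s <- sample(1000:15000, 1)
    w <- sample(100:2000, 1)
    mp <- morph_params(open_ms = sample(c(1, 2, 4, 8), 1))
    fe <- extract_features(x, s, s + w, mp)
    expect_lte(fe$truncated_level, fe$envelope_peak + 1e-12)
  }
})

test_that("context clamps at recording bounds instead of erroring", {
  x <- rand_signal(3000, 5000)
  expect_no_error(extract_features(x, 10, 300, morph_params()))
  expect_no_error(extract_features(x, 2700, 2995, morph_params()))
  expect_error(extract_features(x, 2700, 3500, morph_params()), "outside")
})

test_that("fit_threshold is the max truncated level and is monotone in the set", {
  rec <- default_recording()
  cand <- default_candidates()
  mp <- morph_params()
  fe <- morphripple:::features_for_events(rec$signal, cand, mp)
  th_all <- fit_threshold(rec$signal, cand, mp)
  expect_equal(th_all$value, max(fe$truncated_level))
  expect_equal(th_all$n_training_events, nrow(cand))
  th_one <- fit_threshold(rec$signal, cand[1, ], mp)
  expect_equal(th_one$value, fe$truncated_level[1])
  # adding events never lowers the threshold
  for (k in c(5, 10, nrow(cand))) {
    th_k <- fit_threshold(rec$signal, cand[1:k, ], mp)
    expect_gte(th_all$value, th_k$value)
  }
  expect_error(fit_threshold(rec$signal, cand[0, ], mp), "at least one")
})

test_that("classification is monotone in the threshold with trivial extremes", {
  rec <- default_recording()
  cand <- default_candidates()
  mp <- morph_params()
  f <- extract_features(rec$signal, cand$start_sample[1], cand$end_sample[1], mp)
  th_inf <- structure(list(value = Inf, n_training_events = 1L, open_ms = mp$open_ms),
                      class = "dynamic_threshold")
  th_zero <- structure(list(value = 0, n_training_events = 1L, open_ms = mp$open_ms),
                       class = "dynamic_threshold")
  expect_equal(classify_event(f, th_inf), "ripple")
  expect_equal(classify_event(f, th_zero), "spike")  # features strictly positive
  th_wrong <- structure(list(value = 1, n_training_events = 1L, open_ms = 2),
                        class = "dynamic_threshold")
  expect_error(classify_event(f, th_wrong), "different opening")
  # monotonicity: raising the threshold never converts ripple -> spike
  values <- sort(c(f$envelope_peak * c(0.5, 0.99, 1.01, 2)))
  calls <- vapply(values, function(v) {
    th <- structure(list(value = v, n_training_events = 1L, open_ms = mp$open_ms),
                    class = "dynamic_threshold")
    classify_event(f, th)
  }, character(1))
  expect_true(all(diff(calls == "spike") <= 0))
})

test_that("fitted threshold separates synthetic spikes from ripples", {
  rec <- default_recording()
  cand <- default_candidates()
  expect_gte(sum(cand$label == "spike"), 5)
  expect_gte(sum(cand$label == "ripple"), 15)
  mp <- morph_params()  # 4 ms opening
  fe <- morphripple:::features_for_events(rec$signal, cand, mp)
  # separability by construction: spike envelope peaks above all ripple peaks
  expect_gt(min(fe$envelope_peak[cand$label == "spike"]),
            max(fe$envelope_peak[cand$label == "ripple"]))
  th <- fit_threshold(rec$signal, cand, mp)
  pred <- classify_events(rec$signal, cand, th, mp)
  cc <- confusion(pred$label, cand$label)
  expect_gte(sensitivity(cc), 0.9)
  expect_equal(cc$FP, 0)
})

test_that("sweep covers the default windows and satisfies count invariants", {
  rec <- default_recording()
  cand <- default_candidates()
  expect_equal(default_sweep_windows(), c(1, 2, 3, 3.4, 4, 4.6, 5, 5.4, 6, 7, 8))
  sw <- sweep_open_windows(rec$signal, cand)
  expect_equal(nrow(sw), 11)
  n_spikes <- sum(cand$label == "spike")
  expect_true(all(sw$TP + sw$FN == n_spikes))
  expect_true(all(sw$TP + sw$FP + sw$TN + sw$FN == nrow(cand)))
  # SE non-decreasing in the window on the seeded default set
  expect_true(all(diff(sw$sensitivity) >= -1e-12))
  one <- sweep_open_windows(rec$signal, cand, windows_ms = 4)
  expect_equal(nrow(one), 1)
  expect_equal(one$sensitivity, sw$sensitivity[sw$window_ms == 4])
  ripples_only <- cand[cand$label == "ripple", ]
  expect_error(sweep_open_windows(rec$signal, ripples_only), "no spikes")
})

test_that("thresholds and labels are deterministic", {
  rec <- default_recording()
  cand <- default_candidates()
  mp <- morph_params()
  th1 <- fit_threshold(rec$signal, cand, mp)
  th2 <- fit_threshold(rec$signal, cand, mp)
  expect_identical(th1, th2)
  expect_identical(classify_events(rec$signal, cand, th1, mp),
                   classify_events(rec$signal, cand, th2, mp))
})
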