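test_that("run extraction: merging precedes the duration test", {
  fs <- 5000
  v <- numeric(1000)
  thr <- 0.5
  # single 29-sample run = 5.8 ms < 6 ms -> rejected; 30 samples kept
  v29 <- v; v29[101:129] <- 1
  expect_equal(nrow(morphripple:::threshold_runs(v29, thr, fs, 6, 10)), 0)
  v30 <- v; v30[101:130] <- 1
  runs <- morphripple:::threshold_runs(v30, thr, fs, 6, 10)
  expect_equal(unname(runs[1, ]), c(100, 130))
  # two 4 ms runs separated by 8 ms (< 10 ms) merge into one 16 ms event
  v2 <- v; v2[101:120] <- 1; v2[161:180] <- 1
  runs <- morphripple:::threshold_runs(v2, thr, fs, 6, 10)
  expect_equal(nrow(runs), 1)
  expect_equal(unname(runs[1, ]), c(100, 180))
  # same runs 12 ms apart stay separate and both fail the duration test
  v3 <- v; v3[101:120] <- 1; v3[181:200] <- 1
  expect_equal(nrow(morphripple:::threshold_runs(v3, thr, fs, 6, 10)), 0)
})

test_that("degenerate signals yield an empty event list, not an error", {
  fs <- 5000
  z <- signal1d(numeric(2 * fs), fs)
  expect_equal(nrow(detect_candidates(z)), 0)
  expect_equal(nrow(staba_detect(z)), 0)
})

test_that("raising candidate_sd shrinks the supra-threshold set monotonically", {
  # note a higher threshold can FRAGMENT a run into several, so the run
  # count itself is not monotone; the supra-threshold sample set is, and
  # every high-threshold run must be contained in a low-threshold run.
  set.seed(31)
  fs <- 5000
  x <- generate_recording(synth_spec(duration_s = 10, n_spikes = 2, n_ripples = 4,
                                     seed = 13L))$signal
  rms <- rms_envelope(bandpass(x, bandpass_spec(fs = fs)), 3)$samples
  prev_above <- rep(TRUE, length(rms))
  prev_runs <- NULL
  for (sdm in c(3, 5, 8, 12)) {
    thr <- mean(rms) + sdm * stats::sd(rms)
    above <- rms > thr
    expect_true(all(prev_above | !above))  # above(high) subset of above(low)
    runs <- morphripple:::logical_runs(above)
    if (!is.null(prev_runs) && nrow(runs) > 0) {
      contained <- vapply(seq_len(nrow(runs)), function(i) {
        any(prev_runs[, "start"] <= runs[i, "start"] &
              prev_runs[, "end"] >= runs[i, "end"])
      }, logical(1))
      expect_true(all(contained))
    }
    prev_above <- above
    prev_runs <- runs
  }
})

test_that("an inserted burst in white noise is detected as exactly one event", {
  set.seed(5)
  fs <- 5000
  v <- rnorm(10 * fs)
  burst <- make_ripple(150, 50, 10, fs)  # 10x the noise SD
  at <- 20000L
  v[(at + 1):(at + length(burst))] <- v[(at + 1):(at + length(burst))] + burst
  ev <- detect_candidates(signal1d(v, fs))
  expect_equal(nrow(ev), 1)
  expect_gt(morphripple:::overlap_samples(ev$start_sample, ev$end_sample,
                                          at, at + length(burst)), 0)
})

test_that("confirm_hfo applies the 6-peak boundary exactly", {
  fs <- 5000
  # quiet alternating baseline, then k tall alternating peaks inside the event
  base <- rep(c(0.1, -0.1), 2500)
  build <- function(k) {
    v <- base
    pos <- seq(1001, by = 10, length.out = k)
    v[pos] <- 10 * (-1)^(seq_len(k))
    signal1d(v, fs)
  }
  p <- detector_params(min_peaks = 6)
  expect_true(confirm_hfo(build(6), 990, 1105, p))
  expect_false(confirm_hfo(build(5), 990, 1105, p))
  expect_false(confirm_hfo(signal1d(base, fs), 990, 1105, p))  # flat segment
  expect_error(confirm_hfo(build(6), 4000, 6000, p), "outside")
})

test_that("a long oscillatory burst is confirmed (peak count = duration x frequency)", {
  set.seed(6)
  fs <- 5000
  v <- rnorm(10 * fs)
  burst <- make_ripple(140, 60, 10, fs)
  v[10001:(10000 + length(burst))] <- v[10001:(10000 + length(burst))] + burst
  x <- signal1d(v, fs)
  xf <- bandpass(x, bandpass_spec(fs = fs))
  expect_true(confirm_hfo(xf, 10000, 10000 + length(burst), detector_params()))
})

test_that("staba_detect output is self-consistent and deterministic", {
  rec <- generate_recording(synth_spec(duration_s = 20, n_spikes = 3, n_ripples = 6,
                                       seed = 17L))
  p <- detector_params(band = bandpass_spec(fs = rec$signal$fs))
  ev <- staba_detect(rec$signal, p)
  expect_gt(nrow(ev), 0)
  # every event satisfies duration, gap and confirmation rules by re-check
  dur <- event_duration_ms(ev, rec$signal$fs)
  expect_true(all(dur >= p$min_duration_ms))
  if (nrow(ev) > 1) {
    gaps_ms <- (ev$start_sample[-1] - ev$end_sample[-nrow(ev)]) / rec$signal$fs * 1000
    expect_true(all(gaps_ms >= p$merge_gap_ms))
  }
  xf <- bandpass(rec$signal, p$band)
  for (i in seq_len(nrow(ev))) {
    expect_true(confirm_hfo(xf, ev$start_sample[i], ev$end_sample[i], p))
  }
  ev2 <- staba_detect(rec$signal, p)
  expect_identical(ev, ev2)
})

test_that("ripples-only recording: at least 9 of 10 ripples recovered", {
  spec <- synth_spec(duration_s = 30, n_spikes = 0, n_ripples = 10,
                     ripple_duration_ms_range = c(50, 100), seed = 1L)
  rec <- generate_recording(spec)
  det <- staba_detect(rec$signal)
  expect_gte(recovery_fraction(det, rec$truth, "ripple"), 0.9)
})

test_that("spikes-only recording produces false candidates (filter ringing)", {
  spec <- synth_spec(duration_s = 30, n_spikes = 6, n_ripples = 0, seed = 7L)
  rec <- generate_recording(spec)
  expect_gte(nrow(staba_detect(rec$signal)), 1)
})
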