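test_that("ms -> odd sample conversion rounds to nearest odd, ties upward", {
  fs <- 5000
  expect_identical(ms_to_samples_odd(1, fs), 5L)     # 5 samples exactly
  expect_identical(ms_to_samples_odd(0.8, fs), 5L)   # 4 -> tie between 3 and 5
  expect_identical(ms_to_samples_odd(0.4, fs), 3L)   # 2 -> tie between 1 and 3
  expect_identical(ms_to_samples_odd(1.18, fs), 5L)  # 5.9 closer to 5 than 7
  expect_identical(ms_to_samples_odd(1.2, fs), 7L)   # 6 -> tie upward
  expect_identical(ms_to_samples_odd(0.01, fs), 1L)  # floors at 1
  expect_identical(struct_window(10, 5000)$width_samples, 51L)
})

test_that("erode and dilate match frozen worked examples", {
  x <- signal1d(c(1, 3, 2, 5, 0), fs = 1000)
  expect_equal(erode(x, 3)$samples, c(1, 1, 2, 0, 0))
  expect_equal(dilate(x, 3)$samples, c(3, 3, 5, 5, 5))
  # identity window and constant signal
  expect_equal(erode(x, 1)$samples, x$samples)
  cst <- signal1d(rep(4.2, 17), 1000)
  expect_equal(erode(cst, 7)$samples, cst$samples)
  expect_equal(dilate(cst, 7)$samples, cst$samples)
})

test_that("opening removes narrow peaks, closing fills narrow valleys", {
  peak <- signal1d(c(0, 0, 1, 0, 0), 1000)
  expect_equal(morph_open(peak, 3)$samples, rep(0, 5))
  expect_equal(morph_close(peak, 3)$samples, peak$samples)  # peak preserved by closing
  valley <- signal1d(c(1, 1, 0, 1, 1), 1000)
  expect_equal(morph_close(valley, 3)$samples, rep(1, 5))
  plateau <- signal1d(c(0, 0, 1, 1, 1, 1, 1, 0, 0), 1000)
  expect_equal(morph_open(plateau, 3)$samples, plateau$samples)
})

test_that("morphology input validation", {
  x <- signal1d(1:5, 1000)
  expect_error(signal1d(numeric(), 1000), "non-empty")
  expect_error(signal1d(1:3, -1), "positive")
  expect_error(erode(x, 4), "odd")
  expect_error(erode(x, -3), "positive")
  expect_error(erode(x, 99), "wider")
  expect_error(ms_to_samples_odd(0, 1000), "positive")
})

test_that("fast path exactly equals the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(60:200, 1)
    k <- 2L * sample.int(25, 1) - 1L
    x <- rand_signal(n)
    expect_identical(erode(x, k)$samples,
                     brute_force_extremum(x, k, "min")$samples)
    expect_identical(dilate(x, k)$samples,
                     brute_force_extremum(x, k, "max")$samples)
  }
})

test_that("oracle trivia: whole-signal window gives the global extremum", {
  set.seed(3)
  x <- rand_signal(21)
  k <- 41L  # spans everything from every centre
  expect_equal(brute_force_extremum(x, k, "max")$samples, rep(max(x$samples), 21))
  expect_equal(dilate(x, k)$samples, rep(max(x$samples), 21))
})

test_that("morphological identities hold on randomized inputs", {
  set.seed(202)
  for (i in 1:40) {
    x <- rand_signal(sample(80:160, 1))
    k1 <- 2L * sample.int(10, 1) - 1L
    k2 <- k1 + 2L * sample.int(10, 1)  # strictly wider window
    op <- morph_open(x, k1)$samples
    cl <- morph_close(x, k1)$samples
    # anti-extensivity / extensivity
    expect_true(all(op <= x$samples + 1e-15))
    expect_true(all(cl >= x$samples - 1e-15))
    # idempotence
    expect_identical(morph_open(signal1d(op, x$fs), k1)$samples, op)
    expect_identical(morph_close(signal1d(cl, x$fs), k1)$samples, cl)
    # duality: open(-x) = -close(x), dilate(x) = -erode(-x)
    neg <- signal1d(-x$samples, x$fs)
    expect_identical(morph_open(neg, k1)$samples, -cl)
    expect_identical(dilate(x, k1)$samples, -erode(neg, k1)$samples)
    # nesting in the window
    expect_true(all(morph_open(x, k2)$samples <= op + 1e-15))
    expect_true(all(morph_close(x, k2)$samples >= cl - 1e-15))
  }
})
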