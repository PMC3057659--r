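test_that("explicit step boundaries are echoed unchanged", {
  b <- cbind(first = c(1L, 101L, 201L, 301L, 401L),
             last = c(100L, 200L, 300L, 400L, 500L))
  rec <- pulse_record(rnorm(500), 100, step_boundaries = b,
                      step_pressures = c(37, 73, 108, 143, 181))
  seg <- segment_steps(rec)
  expect_equal(unname(seg$boundaries), unname(b))
  expect_equal(seg$pressures, c(37, 73, 108, 143, 181))
})

test_that("a clean five-level staircase segments exactly at its levels", {
  levels <- c(37, 73, 108, 143, 181)
  trace <- staircase_trace(levels)
  rec <- pulse_record(rep(0, length(trace)), 100, pressure_trace = trace)
  seg <- segment_steps(rec)
  expect_equal(seg$pressures, levels)
  expect_equal(nrow(seg$boundaries), 5L)
  expect_true(all(seg$boundaries[, "last"] >= seg$boundaries[, "first"]))
  # plateaus disjoint and ordered
  expect_true(all(diff(as.vector(t(seg$boundaries))) > 0))
})

test_that("noisy staircases are recovered within 1 mmHg", {
  levels <- c(37, 73, 108, 143, 181)
  for (seed in 1:5) {
    set.seed(seed)
    trace <- staircase_trace(levels) + rnorm(2700, 0, 2)
    rec <- pulse_record(rep(0, 2700), 100, pressure_trace = trace)
    seg <- segment_steps(rec)
    expect_lt(max(abs(seg$pressures - levels)), 1)
  }
})

test_that("segmentation fails loudly when plateaus are missing", {
  trace <- staircase_trace(c(37, 73, 108, 143))   # only four steps
  rec <- pulse_record(rep(0, length(trace)), 100, pressure_trace = trace)
  expect_error(segment_steps(rec), "found 4")
})

test_that("detrending removes a pure polynomial baseline", {
  x <- seq(0, 1, length.out = 450)
  drift <- 3 + 2 * x - 5 * x^2 + 4 * x^3 - x^4 + 0.5 * x^5
  ptp <- max(drift) - min(drift)
  expect_lt(max(abs(detrend_baseline(drift, robust = FALSE))), 1e-9 * ptp)
  # the robust baseline model removes a pulse-free polynomial too
  expect_lt(max(abs(detrend_baseline(drift))), 1e-6 * ptp)
  expect_equal(detrend_baseline(rep(4, 100), robust = FALSE), rep(0, 100))
})

test_that("detrending preserves pulse amplitude under polynomial drift", {
  period <- 80
  pulse <- rep_len(beat_tile(period), 450) * 10
  x <- seq(0, 1, length.out = 450)
  drift <- 8 * (x - 0.4)^2 - 6 * x^3 + 3 * x   # magnitude below pulse amp
  y <- detrend_baseline(pulse + drift)
  expect_lt(abs((max(y) - min(y)) - 10) / 10, 0.05)
  # the symmetric least-squares form absorbs a slice of the beat train
  # itself, so its amplitude error is visibly larger
  y_plain <- detrend_baseline(pulse + drift, robust = FALSE)
  expect_lt(abs((max(y_plain) - min(y_plain)) - 10) / 10, 0.15)
  expect_gt(abs((max(y_plain) - min(y_plain)) - 10) / 10,
            abs((max(y) - min(y)) - 10) / 10)
})

test_that("detrending is idempotent", {
  set.seed(11)
  sig <- rep_len(beat_tile(75), 440) * 5 + cumsum(rnorm(440, 0, 0.02))
  once <- detrend_baseline(sig)
  twice <- detrend_baseline(once)
  expect_lt(max(abs(twice - once)), 0.02 * (max(once) - min(once)))
  once_raw <- detrend_baseline(sig, robust = FALSE)
  expect_equal(detrend_baseline(once_raw, robust = FALSE), once_raw,
               tolerance = 1e-10)
})

test_that("detrending rejects segments shorter than the fit", {
  expect_error(detrend_baseline(rnorm(6), order = 5), "too short")
})

test_that("averaging identical beats reproduces one beat", {
  tile <- beat_tile(80)
  seg <- rep(tile, 6)
  avg <- average_beat(seg, 100)
  expect_gte(attr(avg, "n_beats"), 4)
  expect_equal(attr(avg, "period"), 80)
  # averaged samples match the template cycle exactly
  expect_equal(max(avg) - min(avg), max(tile) - min(tile),
               tolerance = 1e-12)
  expect_equal(max(avg), max(tile), tolerance = 1e-12)
})

test_that("ensemble averaging shrinks additive beat noise", {
  set.seed(31)
  tile <- beat_tile(80)
  sigma <- 0.05
  resid_for <- function(n_periods) {
    seg <- rep(tile, n_periods) + rnorm(80 * n_periods, 0, sigma)
    avg <- average_beat(seg, 100)
    peak <- which.max(avg)
    clean <- rep(tile, 3)
    cpeak <- which.max(tile) + 80
    pre <- peak - 1
    post <- length(avg) - peak
    # +-2 samples of alignment slack: noise can move the detected peak
    min(sapply(-2:2, function(s)
      sd(avg - clean[(cpeak + s - pre):(cpeak + s + post)])))
  }
  few <- replicate(20, resid_for(5))
  many <- replicate(20, resid_for(20))
  # averaging pushes the residual well below the raw noise level, and
  # more beats keep shrinking it (~ sigma/sqrt(n) plus alignment smear)
  expect_lt(median(few), 0.75 * sigma)
  expect_lt(median(many), median(few))
  expect_lt(median(many), 3 * sigma / sqrt(18))
})

test_that("a single beat is not enough", {
  tile <- beat_tile(300)
  expect_error(average_beat(tile, 100), "beats")
})

test_that("pulse strength is the peak-to-trough of the beat", {
  expect_equal(pulse_strength(rep(2, 50)), 0)
  tile <- beat_tile(90) * 7.5
  expect_equal(pulse_strength(tile), 7.5)
  expect_error(pulse_strength(numeric(0)), "non-empty")
})

test_that("noisy beats still yield strength within 10%", {
  set.seed(21)
  tile <- beat_tile(80)
  a <- 3
  ok <- replicate(25, {
    seg <- rep(tile * a, 10) + rnorm(800, 0, 0.05 * a)
    abs(pulse_strength(average_beat(seg, 100)) - a) / a
  })
  expect_lt(quantile(ok, 0.9), 0.10)
})

test_that("build_profile recovers injected strengths from a clean record", {
  h <- c(2, 5, 8, 5, 2)
  rec <- staircase_record(h)
  prof <- build_profile(rec)
  expect_s3_class(prof, "step_profile")
  expect_equal(prof$pressures, c(37, 73, 108, 143, 181))
  expect_lt(max(abs(prof$strengths - h) / h), 0.02)
})

test_that("build_profile propagates a missing plateau as an error", {
  trace <- staircase_trace(c(37, 73, 108, 143))
  rec <- pulse_record(rep_len(beat_tile(80), length(trace)), 100,
                      pressure_trace = trace)
  expect_error(build_profile(rec), "plateaus")
})

test_that("the acquisition chain is amplitude-linear", {
  h <- c(3, 6, 9, 6, 3)
  rec <- staircase_record(h)
  rec2 <- rec
  rec2$samples <- rec$samples * 4.2
  p1 <- build_profile(rec)
  p2 <- build_profile(rec2)
  expect_equal(p2$strengths, 4.2 * p1$strengths, tolerance = 1e-10)
})

test_that("location averaging is the element-wise mean and symmetric", {
  hmat <- rbind(c(3, 3, 3, 3, 3), c(6, 6, 6, 6, 6), c(9, 9, 9, 9, 9))
  m <- measurement_with(hmat)
  avg <- location_average(m$profiles)
  expect_equal(avg$strengths, rep(6, 5))
  expect_equal(avg$location, "averaged")
  # permutation invariance
  perm <- location_average(m$profiles[c(3, 1, 2)])
  expect_equal(perm$strengths, avg$strengths)
  # identical profiles average to themselves
  same <- measurement_with(rbind(c(1, 2, 3, 2, 1), c(1, 2, 3, 2, 1),
                                 c(1, 2, 3, 2, 1)))
  expect_equal(location_average(same$profiles)$strengths, c(1, 2, 3, 2, 1))
  expect_error(location_average(m$profiles[c(1, 1, 2)]), "one profile per")
})

test_that("h_max equals a brute-force scan", {
  expect_equal(h_max(c(1, 5, 3, 2, 1)), 5)
  expect_equal(h_max(rep(4.4, 5)), 4.4)
  set.seed(3)
  for (i in 1:20) {
    h <- runif(5, 0, 200)
    mx <- h[1]
    for (v in h[-1]) if (v > mx) mx <- v
    expect_equal(h_max(h), mx)
  }
})
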