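test_that("PSTH estimation counts spikes correctly", {
  # exactly 10 Hz periodic train over 10 s: every window reads ~10 Hz
  train <- tibble::tibble(time_s = seq(0.05, 9.95, by = 0.1))
  p <- estimate_psth(train, t_end = 10)
  expect_true(all(abs(p$rate_hz - 10) <= 5))  # +/- 1 edge count per window
  expect_true(mean(abs(p$rate_hz - 10) < 1e-9) > 0.9)

  empty <- tibble::tibble(time_s = numeric())
  expect_true(all(estimate_psth(empty, t_end = 2)$rate_hz == 0))

  # duplicating identical trials leaves the normalized rate unchanged
  p2 <- estimate_psth(list(train, train), t_end = 10)
  expect_equal(p2$rate_hz, p$rate_hz)
  expect_error(estimate_psth(list()), "at least one")
  expect_error(estimate_psth(train, window = 0.1, overlap = 0.2), "window")

  # spike-count conservation within boundary effects
  hop <- 0.1
  expect_within(sum(p$rate_hz) * hop, nrow(train), 2)
})

test_that("jump detection finds staircase transitions and survives noise", {
  w <- make_staircase(c(0, 100, 0), 1, dt = 1e-3)
  j <- detect_jump_times(w)
  expect_equal(j$sign, c(1, -1))
  expect_within(j$time_s[1], 1, 0.01)
  expect_within(j$time_s[2], 2, 0.01)

  const <- make_staircase(5, 2, dt = 1e-3)
  expect_equal(nrow(detect_jump_times(const)), 0)

  # moderate noise moves detections by < 50 ms
  for (seed in 1:5) {
    wn <- add_white_noise(w, 4, seed)
    jn <- detect_jump_times(wn)
    expect_equal(nrow(jn), 2)
    expect_true(all(abs(jn$time_s - j$time_s) <= 0.05))
  }
})

test_that("decomposition is exact on piecewise-constant input", {
  dt <- 1e-3
  y <- rep(c(0, 50, 0), each = 1000)
  d <- decompose_response(y, c(1, 2), dt = dt)
  expect_equal(attr(d, "segments"), c(0, 50, 0))
  expect_true(all(d$transient == 0))
  # exact additive identity and rectification partition, any input
  set.seed(4)
  y2 <- rnorm(3000, 20, 10)
  d2 <- decompose_response(y2, c(1, 2), dt = dt)
  expect_identical(d2$on + d2$off, d2$transient)   # exact partition
  expect_equal(d2$steady + d2$transient, d2$signal)
  expect_true(all(d2$on >= 0) && all(d2$off <= 0))
})

test_that("decomposition recovers steady levels under decaying transients", {
  dt <- 1e-3
  t <- seq(0, 3 - dt, dt)
  steady <- ifelse(t < 1, 10, ifelse(t < 2, 60, 10))
  trans <- 40 * exp(-(t - 1) / 0.05) * (t >= 1) -
    30 * exp(-(t - 2) / 0.05) * (t >= 2)
  d <- decompose_response(steady + trans, c(1, 2), dt = dt)
  # residual transient mass over the pre-jump window is ~ exp(-0.5/0.05)
  expect_within(attr(d, "segments")[2], 60, 0.1)
  expect_within(attr(d, "segments")[1], 10, 0.1)
  expect_warning(decompose_response(steady, c(1, 1.2, 2), dt = dt),
                 "pre_window")
})

test_that("norms and inner products are duration-normalized", {
  u <- rep(3, 1000)
  expect_equal(l2_norm(u), 3)
  expect_equal(l2_norm(rep(3, 50)), 3)  # duration-free
  expect_equal(inner_product(u, u), l2_norm(u)^2)
  a <- c(rep(1, 500), rep(0, 500))
  b <- c(rep(0, 500), rep(1, 500))
  expect_equal(inner_product(a, b), 0)
  # multi-channel: channels summed inside the integral
  m <- rbind(rep(3, 100), rep(4, 100))
  expect_equal(l2_norm(m), 5)
  expect_error(inner_product(1:3, 1:4), "length|shape")
})

test_that("angular distance is a scale-invariant dissimilarity in [0, 1]", {
  v <- sin(seq(0, 10, 0.01))
  expect_equal(angular_distance(v, v), 0)
  expect_equal(angular_distance(v, 3 * v), 0)
  expect_equal(angular_distance(v, -v), 1)
  a <- c(1, 0); b <- c(0, 1)
  expect_equal(angular_distance(a, b), 1)
  expect_equal(angular_distance(a, b), angular_distance(b, a))
  expect_error(angular_distance(a, c(0, 0)), "zero-norm")
})

test_that("SNR follows its decibel definition", {
  ref <- rep(10, 100)
  expect_equal(snr_db(ref, rep(0, 100)), 0)     # residual norm = ref norm
  expect_equal(snr_db(ref, rep(9, 100)), 20)    # residual = ref / 10
  expect_equal(snr_db(ref, ref), Inf)
  expect_gt(snr_db(ref, rep(9.9, 100)), snr_db(ref, rep(9, 100)))
})

test_that("max cross-correlation localizes shifts", {
  set.seed(8)
  u <- as.numeric(stats::filter(rnorm(4000), rep(1, 50), sides = 1))
  u[is.na(u)] <- 0
  same <- max_cross_correlation(u, u, dt = 1e-3)
  expect_equal(same$lag_s, 0)
  expect_within(same$value, 1, 1e-9)
  v <- c(rep(0, 200), u[1:3800])  # u delayed by 0.2 s
  sh <- max_cross_correlation(u, v, dt = 1e-3, max_lag = 0.5)
  expect_within(sh$lag_s, 0.2, 0.01)
  # independent noise: correlation near zero relative to autocorrelation
  w <- rnorm(4000)
  expect_lt(max_cross_correlation(u, w, dt = 1e-3)$value, 0.2)
})

test_that("step-amplitude CV matches the two-point formula", {
  mk <- function(amps) {
    y <- rep(amps, each = 500)
    decompose_response(y, seq_along(amps)[-length(amps)] * 0.5, dt = 1e-3,
                       pre_window = 0.4)
  }
  expect_equal(step_amplitude_cv(mk(c(80, 80, 80))), 0)
  expect_within(step_amplitude_cv(mk(c(50, 100))), 25 * sqrt(2) / 75, 1e-9)
  expect_error(step_amplitude_cv(mk(42)), "segments")
})
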