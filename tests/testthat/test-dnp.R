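test_that("zero-drive DNP decays exponentially (closed form)", {
  p <- dnp_params(alpha = 5, beta = 1, kappa = 0, mode = "feedforward")
  tr <- simulate_dnp(p, drive = rep(0, 20000), dt = 1e-4, x0 = 0.5)
  # exponential-Euler is exact for the linear decay dx/dt = -beta x
  expect_within(tr$x[nrow(tr)], 0.5 * exp(-(2 - 1e-4)), 1e-9)
  expect_within(tr$x[10001], 0.5 * exp(-1), 1e-9)
})

test_that("simulated terminal states match the closed-form fixed points", {
  # feedforward: x_inf = a v / (a v + b + k g); feedback: positive quadratic
  # root of k x^2 + (a v + b) x - a v = 0, checked against a root-finding
  # oracle as well as the closed form
  set.seed(11)
  for (i in 1:20) {
    a <- 10^runif(1, -0.5, 1.5); b <- 10^runif(1, -0.5, 1.5)
    k <- 10^runif(1, -0.5, 1.5); v <- 10^runif(1, -0.5, 1)
    g <- runif(1, 0, 2)
    p_ff <- dnp_params(a, b, k, "feedforward")
    t_end <- 50 / min(b, 1)
    n <- round(t_end / 1e-3)
    tr <- simulate_dnp(p_ff, rep(v, n), rep(g, n), dt = 1e-3)
    expect_within(tr$x[n], steady_state_ff(p_ff, v, g), 1e-4)

    p_fb <- dnp_params(a, b, k, "feedback")
    trb <- simulate_dnp(p_fb, rep(v, n), dt = 1e-3)
    root <- uniroot(function(x) a * v * (1 - x) - b * x - k * x^2,
                    c(0, 1), tol = 1e-12)$root
    expect_within(trb$x[n], root, 1e-4)
    expect_within(steady_state_fb(p_fb, v), root, 1e-10)
  }
})

test_that("steady-state formulas handle the documented special cases", {
  p <- dnp_params(1, 1, 1)
  expect_equal(steady_state_ff(p, drive = 2, pooled = 1), 0.5)
  expect_equal(steady_state_ff(p, drive = 0, pooled = 1), 0)
  # kappa -> 0 recovers the plain feedforward limit a v / (b + a v)
  p0 <- dnp_params(2, 3, 0)
  expect_equal(steady_state_ff(p0, 5, 100), 10 / 13)
  expect_error(steady_state_ff(dnp_params(1, 0, 0), 0, 0), "denominator")
})

test_that("trajectories stay inside [0, 1] and kappa is monotone", {
  set.seed(3)
  for (i in 1:10) {
    p <- dnp_params(10^runif(1, 0, 2), 10^runif(1, 0, 2), 10^runif(1, 0, 2),
                    sample(c("feedback", "feedforward"), 1))
    drive <- abs(rnorm(2000, 2, 3))
    norm <- abs(rnorm(2000, 1, 2))
    tr <- simulate_dnp(p, drive, norm, dt = 1e-3, x0 = runif(1))
    expect_true(all(tr$x >= 0 & tr$x <= 1))
  }
  # raising kappa never increases the terminal steady state
  ks <- c(0, 1, 10, 100)
  term <- vapply(ks, function(k) {
    p <- dnp_params(5, 1, k, "feedforward")
    tail(simulate_dnp(p, rep(2, 5000), rep(1, 5000), dt = 1e-3)$x, 1)
  }, numeric(1))
  expect_true(all(diff(term) <= 0))
})

test_that("global DNP reduces to single-channel at R = 1 and is equivariant", {
  p <- dnp_params(3, 1, 2, "global_feedforward")
  drive <- abs(sin(seq(0, 10, by = 1e-3))) * 4
  g1 <- simulate_global_dnp(p, matrix(drive, 1), pooled = drive, dt = 1e-3)
  s1 <- simulate_dnp(dnp_params(3, 1, 2, "feedforward"), drive, drive,
                     dt = 1e-3)
  expect_equal(g1$x, s1$x)

  drives <- rbind(drive, 2 * drive, 0.3 * drive)
  ga <- simulate_global_dnp(p, drives, dt = 1e-3)
  gb <- simulate_global_dnp(p, drives[c(3, 1, 2), ], dt = 1e-3)
  for (ch in 1:3)
    expect_equal(ga$x[ga$channel == ch], gb$x[gb$channel == c(2, 3, 1)[ch]])
})

test_that("strong global normalization recovers channel ratios", {
  # two channels with drives (a, 3a), kappa >> alpha, beta: terminal ratio 3
  p <- dnp_params(alpha = 1, beta = 0.01, kappa = 1000, "global_feedforward")
  n <- 50000
  drives <- rbind(rep(2, n), rep(6, n))
  tr <- simulate_global_dnp(p, drives, dt = 1e-3)
  xe <- tr$x[tr$time_s == max(tr$time_s)]
  expect_within(xe[2] / xe[1], 3, 0.01)
})

test_that("normalized-affinity steady state is concentration invariant", {
  expect_equal(steady_state_normalized_affinity(c(1, 3), u = 10),
               c(0.25, 0.75))
  expect_equal(steady_state_normalized_affinity(c(1, 3), u = 1000),
               c(0.25, 0.75))
  # single channel: identity information is lost, output is the constant 1
  expect_equal(steady_state_normalized_affinity(5, u = 100), 1)
  expect_error(steady_state_normalized_affinity(c(0, 0)), "positive")
  expect_error(steady_state_normalized_affinity(c(1, 2), u = 0), "u")
})

test_that("global feedforward in the strong-kappa regime matches the
           normalized affinity across three decades of concentration", {
  set.seed(21)
  aff <- 10^rnorm(24, -1, 1)
  p <- dnp_params(alpha = 1, beta = 0.5, kappa = 1e4, "global_feedforward")
  outs <- lapply(c(10, 100, 1000), function(u) {
    drives <- matrix(rep(aff * u, 2000), nrow = 24)
    tr <- simulate_global_dnp(p, drives, dt = 1e-3)
    tr$x[tr$time_s == max(tr$time_s)]
  })
  target <- steady_state_normalized_affinity(aff)
  for (x in outs) expect_lt(angular_distance(x, target), 0.05)
  expect_lt(angular_distance(outs[[1]], outs[[3]]), 0.02)
})
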