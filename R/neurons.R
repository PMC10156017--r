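#' Noisy Connor-Stevens biophysical spike generators
#'
#' All spiking neurons in the circuit models are Connor-Stevens point
#' neurons (Type-I excitability through the transient A-current), with
#' optional additive Gaussian membrane noise. The frequency-current (F-I)
#' curve of the model and its monotone inverse connect PSTHs to injected
#' synaptic currents.
#'
#' @name neurons
NULL

#' Connor-Stevens parameters
#'
#' Standard textbook constants; conductances in mS/cm^2, reversal potentials
#' in mV, capacitance in uF/cm^2. `noise_sigma` is the dimensionless noise
#' intensity multiplying the frozen calibration scale (see the methods
#' vignette); the published circuit uses `noise_sigma = 0.0013849367` for the
#' PN and 0 for all LNs.
#'
#' @param C membrane capacitance
#' @param gNa,gK,gA,gL maximal conductances
#' @param ENa,EK,EA,EL reversal potentials
#' @param noise_sigma membrane noise intensity (>= 0)
#' @export
connor_stevens_params <- function(C = 1, gNa = 120, gK = 20, gA = 47.7,
                                  gL = 0.3, ENa = 55, EK = -72, EA = -75,
                                  EL = -17, noise_sigma = 0) {
  if (any(c(gNa, gK, gA, gL) < 0)) abort("conductances must be >= 0")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  structure(list(C = C, gNa = gNa, gK = gK, gA = gA, gL = gL, ENa = ENa,
                 EK = EK, EA = EA, EL = EL, noise_sigma = noise_sigma),
            class = "cs_params")
}

cs_vector <- function(p) {
  c(p$C, p$gNa, p$gK, p$gA, p$gL, p$ENa, p$EK, p$EA, p$EL)
}

#' The published PN noise intensity
#' @export
SIGMA_PN <- 0.0013849367

#' Simulate a Connor-Stevens spike generator
#'
#' Exponential-Euler integration at fixed `dt` with additive Gaussian
#' voltage noise of per-step standard deviation
#' `noise_sigma * scale * sqrt(dt)` (scale frozen in the package
#' configuration). Spikes are the times of local voltage maxima above 0 mV
#' with a 1 ms refractory guard. With `noise_sigma = 0` the simulation is
#' bit-reproducible.
#'
#' @param input_current injected current time series (uA) or a single value
#'   recycled over `duration`
#' @param dt time step (s); 1e-4 or smaller recommended
#' @param params a [connor_stevens_params()]
#' @param seed integer seed for the membrane noise
#' @param duration used when `input_current` is scalar
#' @return list with `spikes` (tibble `time_s`) and `trajectory` (tibble
#'   `time_s`, `v_mV`, `n`, `i_uA`)
#' @export
simulate_bsg <- function(input_current, dt = 1e-4,
                         params = connor_stevens_params(), seed = 1L,
                         duration = NULL) {
  if (length(input_current) == 1 && !is.null(duration))
    input_current <- rep(input_current, round(duration / dt))
  if (any(!is.finite(input_current))) abort("input current must be finite")
  res <- cpp_simulate_cs(input_current, dt, params$noise_sigma, NOISE_SCALE,
                         as.integer(seed), cs_vector(params), TRUE)
  if (any(!is.finite(res$V)))
    abort("Connor-Stevens integration diverged (non-finite voltage)")
  traj <- tibble(time_s = seq_along(input_current) * dt - dt,
                 v_mV = res$V, n = res$n, i_uA = input_current)
  class(traj) <- c("phase_trajectory", class(traj))
  list(spikes = tibble(time_s = res$spikes), trajectory = traj)
}

#' Detect spikes as thresholded local voltage maxima
#'
#' @param traj a trajectory tibble with `time_s` and `v_mV`
#' @param threshold voltage threshold (mV); default 0
#' @param refractory minimum separation between detections (s)
#' @return tibble with column `time_s`
#' @export
spike_detect <- function(traj, threshold = 0, refractory = 1e-3) {
  v <- traj$v_mV
  n <- length(v)
  if (n < 3) return(tibble(time_s = numeric()))
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
              FALSE) & v > threshold
  times <- traj$time_s[is_max]
  if (length(times) > 1) {
    keep <- rep(TRUE, length(times))
    last <- times[1]
    for (i in 2:length(times)) {
      if (times[i] - last < refractory) keep[i] <- FALSE else last <- times[i]
    }
    times <- times[keep]
  }
  tibble(time_s = times)
}

#' Frequency-current curve of a Connor-Stevens neuron
#'
#' Noise-free tabulation: each grid current is held for `sim_time` seconds
#' and spikes during the first `discard` seconds are ignored. Numerical
#' jitter is removed by an isotonic (non-decreasing) cleanup; a violation of
#' monotonicity beyond `tol` Hz is an error since the curve could not then be
#' inverted.
#'
#' @param params a [connor_stevens_params()]
#' @param current_grid sorted currents (uA); default 200 points on \[0, 100\]
#' @param sim_time,discard simulation and transient-discard times (s)
#' @param dt time step (s)
#' @param tol isotonic-cleanup tolerance (Hz)
#' @return an `fi_curve` tibble with columns `current_uA`, `rate_hz`
#' @export
fi_curve <- function(params = connor_stevens_params(),
                     current_grid = seq(0, 100, length.out = 200),
                     sim_time = 4, discard = 1, dt = 1e-4, tol = 3) {
  if (is.unsorted(current_grid)) abort("current_grid must be sorted")
  rates <- cpp_fi_rates(current_grid, cs_vector(params), sim_time, discard, dt)
  iso <- isoreg(current_grid, rates)$yf
  if (max(abs(iso - rates)) > tol)
    abort("F-I curve is non-monotone beyond tolerance; unusable for inversion")
  out <- tibble(current_uA = current_grid, rate_hz = iso)
  class(out) <- c("fi_curve", class(out))
  out
}

#' Invert an F-I curve: map firing rates to injected currents
#'
#' Monotone linear interpolation of the tabulated curve. Rates at or below
#' the smallest positive tabulated rate map to the rheobase-floor current
#' (the largest tabulated current with zero rate); rates above the table are
#' an error.
#'
#' @param fi an [fi_curve()]
#' @param rate firing rate(s), Hz (>= 0)
#' @return current(s), uA
#' @export
fi_inverse <- function(fi, rate) {
  if (any(rate < 0)) abort("rates must be >= 0")
  if (any(rate > max(fi$rate_hz)))
    abort("rate above the tabulated F-I range; extend the current grid")
  zero <- fi$rate_hz <= 0
  floor_current <- if (any(zero)) max(fi$current_uA[zero]) else min(fi$current_uA)
  pos <- !zero
  # strictly increasing table for interpolation
  tb <- tibble(r = fi$rate_hz[pos], i = fi$current_uA[pos]) %>%
    group_by(.data$r) %>% summarise(i = min(.data$i), .groups = "drop")
  out <- rep(floor_current, length(rate))
  if (nrow(tb) > 0) {
    hi <- rate > min(tb$r)
    if (any(hi))
      out[hi] <- approx(c(0, tb$r), c(floor_current, tb$i), xout = rate[hi],
                        rule = 2, ties = "ordered")$y
  }
  out
}

#' Evaluate an F-I curve at arbitrary currents (linear interpolation)
#' @param fi an [fi_curve()]
#' @param current current(s), uA
#' @export
fi_rate <- function(fi, current) {
  approx(fi$current_uA, fi$rate_hz, xout = current, rule = 2)$y
}

#' Extract one period of the stable limit cycle at a constant current
#'
#' Simulates noise-free for `settle + capture` seconds, discards the
#' transient and returns the samples between the last two spike peaks: one
#' period of the attracting periodic orbit, with the constant current
#' recorded alongside (V, n) for phase-space plots.
#'
#' @param params a [connor_stevens_params()]
#' @param constant_current injected current (uA), above rheobase
#' @param settle transient discard time (s)
#' @param dt time step (s); a fine step gives a smoother orbit
#' @return a `phase_trajectory` tibble (one period) with attribute
#'   `period_s`
#' @export
extract_limit_cycle <- function(params = connor_stevens_params(),
                                constant_current, settle = 1.5, dt = 1e-5) {
  p2 <- params; p2$noise_sigma <- 0
  sim <- simulate_bsg(constant_current, dt = dt, params = p2,
                      duration = settle + 0.6)
  spk <- sim$spikes$time_s
  spk <- spk[spk > settle]
  if (length(spk) < 2)
    abort("no sustained spiking at this current; below rheobase?")
  t1 <- spk[length(spk) - 1]; t2 <- spk[length(spk)]
  idx <- which(sim$trajectory$time_s >= t1 & sim$trajectory$time_s <= t2)
  out <- sim$trajectory[idx, ]
  attr(out, "period_s") <- t2 - t1
  class(out) <- c("phase_trajectory", class(out))
  out
}

#' Write spike trains as two-column CSV (neuron_id, spike_time_s)
#' @param trains list of spike tibbles (or a single tibble)
#' @param path output path
#' @export
write_spikes_csv <- function(trains, path) {
  if (is.data.frame(trains)) trains <- list(trains)
  d <- purrr::imap_dfr(trains, function(tr, i)
    tibble(neuron_id = i, spike_time_s = tr$time_s))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
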