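#' PSTH estimation, response decomposition and signal metrics
#'
#' The PN response is decomposed into a concentration-invariant piecewise
#' constant (steady) component anchored at the stimulus jump times, and a
#' contrast-boosting transient residual further split by rectification into
#' ON (positive) and OFF (negative) parts. Metrics use duration-normalized
#' L2 geometry, so the angular distance is a scale-invariant dissimilarity
#' in \[0, 1\].
#'
#' @name signal
NULL

#' Estimate a peri-stimulus time histogram from spike trains
#'
#' Counting windows of length `window` hop by `window - overlap`; the rate at
#' each window center is the spike count across trials in
#' \[center - window/2, center + window/2) divided by `window * n_trials`.
#'
#' @param trains a list of spike tibbles (trials); each has a `time_s`
#'   column and optionally a `channel` column for multi-channel trains. A
#'   single tibble is treated as one trial.
#' @param window window size (s); default 0.2
#' @param overlap window overlap (s); default 0.1
#' @param t_end recording duration (s); default the trains' `duration`
#'   attribute or the last spike time
#' @return an `al_psth` tibble with columns `time_s`, `channel`, `rate_hz`
#' @export
estimate_psth <- function(trains, window = 0.2, overlap = 0.1, t_end = NULL) {
  if (is.data.frame(trains)) trains <- list(trains)
  if (length(trains) == 0) abort("need at least one spike train")
  if (window <= overlap || overlap < 0) abort("need window > overlap >= 0")
  t_end <- t_end %||% attr(trains[[1]], "duration") %||%
    max(c(0, purrr::map_dbl(trains, ~ max(c(0, .x$time_s)))))
  channels <- sort(unique(unlist(purrr::map(
    trains,
    ~ if ("channel" %in% names(.x)) unique(.x$channel) else 1L))))
  hop <- window - overlap
  centers <- seq(window / 2, t_end - window / 2 + 1e-12, by = hop)
  n_trials <- length(trains)
  out <- purrr::map_dfr(channels, function(ch) {
    counts <- numeric(length(centers))
    for (tr in trains) {
      tm <- if ("channel" %in% names(tr)) tr$time_s[tr$channel == ch]
            else tr$time_s
      for (i in seq_along(centers)) {
        counts[i] <- counts[i] +
          sum(tm >= centers[i] - window / 2 & tm < centers[i] + window / 2)
      }
    }
    tibble(time_s = centers, channel = ch,
           rate_hz = counts / (window * n_trials))
  })
  attr(out, "window") <- window
  attr(out, "overlap") <- overlap
  attr(out, "n_trials") <- n_trials
  attr(out, "t_end") <- t_end
  class(out) <- c("al_psth", class(out))
  out
}

#' PSTH of a circuit simulation's spike trains
#' @param traces an `al_traces`
#' @param population `"pn"`, `"preln"`, `"eln"` or `"iln"`
#' @inheritParams estimate_psth
#' @export
traces_psth <- function(traces, population = "pn", window = 0.2,
                        overlap = 0.1) {
  lst <- traces$spikes[[population]]
  tr <- purrr::imap_dfr(lst, ~ tibble(channel = .y, time_s = as.numeric(.x)))
  estimate_psth(list(tr), window, overlap, t_end = traces$duration)
}

#' Linearly interpolate a PSTH onto a uniform fine grid
#' @param psth an `al_psth`
#' @param times target times (s)
#' @return matrix channels x length(times)
#' @export
psth_interpolate <- function(psth, times) {
  channels <- sort(unique(psth$channel))
  t(vapply(channels, function(ch) {
    sub <- psth[psth$channel == ch, ]
    approx(sub$time_s, sub$rate_hz, xout = times, rule = 2)$y
  }, numeric(length(times))))
}

#' Detect concentration jump times from the contrast signal
#'
#' Local extrema of the concentration contrast whose magnitude is at least
#' `rel_threshold` times the maximum magnitude; detections closer than
#' `min_separation` are merged keeping the strongest. Each jump is labeled
#' +1 (onset) or -1 (offset).
#'
#' @param w a `conc_waveform`
#' @param eps contrast bias (ppm)
#' @param min_separation merge radius (s)
#' @param rel_threshold relative magnitude threshold
#' @return tibble with columns `time_s`, `sign`; empty for constant input
#' @export
detect_jump_times <- function(w, eps = 1, min_separation = 0.2,
                              rel_threshold = 0.2) {
  ct <- concentration_contrast(w, eps)
  find_signal_peaks(ct$contrast, ct$time_s, rel_threshold, min_separation)
}

# shared thresholded-peak detector: local extrema of |values| above
# rel_threshold * max|values|, merged within min_separation keeping the
# strongest; also used for ON/OFF event extraction from pathway currents
find_signal_peaks <- function(values, times, rel_threshold = 0.2,
                              min_separation = 0.2) {
  a <- abs(values)
  mx <- max(a)
  if (mx == 0) return(tibble(time_s = numeric(), sign = numeric()))
  n <- length(a)
  is_pk <- a >= rel_threshold * mx &
    a >= c(0, a[-n]) & a >= c(a[-1], 0)
  idx <- which(is_pk)
  if (length(idx) == 0) return(tibble(time_s = numeric(), sign = numeric()))
  tms <- times[idx]
  keep_t <- numeric(); keep_s <- numeric()
  grp_start <- 1
  for (i in seq_along(idx)) {
    if (i == length(idx) || tms[i + 1] - tms[i] > min_separation) {
      g <- grp_start:i
      best <- g[which.max(a[idx[g]])]
      keep_t <- c(keep_t, tms[best])
      keep_s <- c(keep_s, sign(values[idx[best]]))
      grp_start <- i + 1
    }
  }
  tibble(time_s = keep_t, sign = keep_s)
}

#' Decompose a response into steady, transient and ON/OFF components
#'
#' Each inter-jump segment receives the piecewise-constant amplitude equal to
#' the signal mean over the `pre_window` immediately before the jump that
#' ends the segment; the final segment uses the mean over the record's last
#' `pre_window`. The transient is the exact residual and is partitioned into
#' non-negative ON and non-positive OFF parts by rectification, so
#' steady + on + off reconstructs the input bit-exactly.
#'
#' @param signal tibble with `time_s` and a value column (second column), or
#'   a numeric vector with `dt` supplied
#' @param jump_times numeric jump times (s) or the tibble from
#'   [detect_jump_times()]
#' @param pre_window averaging window before each jump (s); default 0.5
#' @param dt sample interval, needed when `signal` is a bare vector
#' @return an `al_decomposition` tibble with columns `time_s`, `signal`,
#'   `steady`, `transient`, `on`, `off`; attribute `segments` holds the
#'   per-segment amplitudes
#' @export
decompose_response <- function(signal, jump_times, pre_window = 0.5,
                               dt = NULL) {
  if (is.data.frame(signal)) {
    tm <- signal$time_s
    y <- signal[[setdiff(names(signal), "time_s")[1]]]
  } else {
    if (is.null(dt)) abort("dt is required for vector input")
    y <- signal
    tm <- seq_along(y) * dt - dt
  }
  if (is.data.frame(jump_times)) jump_times <- jump_times$time_s
  jump_times <- sort(jump_times)
  if (length(jump_times) > 0 &&
      (min(jump_times) < tm[1] || max(jump_times) > tm[length(tm)]))
    abort("jump times must lie within the signal support")
  bounds <- c(tm[1], jump_times, tm[length(tm)] + (tm[2] - tm[1]))
  steady <- numeric(length(y))
  amps <- numeric(length(bounds) - 1)
  for (i in seq_len(length(bounds) - 1)) {
    seg <- tm >= bounds[i] & tm < bounds[i + 1]
    # averaging window: before the segment-ending jump, or the record tail
    ref_end <- bounds[i + 1]
    w0 <- ref_end - pre_window
    if (w0 < bounds[i]) {
      warn("pre_window longer than segment; truncating averaging window")
      w0 <- bounds[i]
    }
    win <- tm >= w0 & tm < ref_end
    amps[i] <- mean(y[win])
    steady[seg] <- amps[i]
  }
  transient <- y - steady
  on <- pmax(transient, 0)
  out <- tibble(time_s = tm, signal = y, steady = steady,
                transient = transient, on = on, off = transient - on)
  attr(out, "segments") <- amps
  attr(out, "jump_times") <- jump_times
  class(out) <- c("al_decomposition", class(out))
  out
}

as_signal_matrix <- function(u) {
  if (is.data.frame(u)) u <- u[[setdiff(names(u), "time_s")[1]]]
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  u
}

#' Duration-normalized L2 norm
#'
#' sqrt of the time-average of the squared signal; multi-channel inputs
#' (matrix rows = channels) sum across channels inside the integral. The 1/T
#' normalization makes the norm of a constant c equal |c| for any duration.
#'
#' @param u numeric vector, channels x time matrix, or tibble with a value
#'   column
#' @export
l2_norm <- function(u) {
  u <- as_signal_matrix(u)
  sqrt(sum(u^2) / ncol(u))
}

#' Duration-normalized inner product
#' @param u,v signals with common sampling (vectors or channels x time
#'   matrices)
#' @export
inner_product <- function(u, v) {
  u <- as_signal_matrix(u); v <- as_signal_matrix(v)
  if (!all(dim(u) == dim(v))) abort("signals must have the same shape")
  sum(u * v) / ncol(u)
}

#' Angular distance between signals
#'
#' (2/pi) arccos of the normalized inner product: 0 for proportional signals
#' with a positive factor, 1 for orthogonal signals. Scale-invariant.
#'
#' @inheritParams inner_product
#' @export
angular_distance <- function(u, v) {
  nu <- l2_norm(u); nv <- l2_norm(v)
  if (nu == 0 || nv == 0) abort("angular distance undefined for zero-norm signals")
  c_ <- inner_product(u, v) / (nu * nv)
  min(max(2 / pi * acos(min(max(c_, -1), 1)), 0), 1)
}

#' Signal-to-noise ratio in decibel
#'
#' 20 log10(||reference|| / ||reference - estimate||); +Inf for an exact
#' estimate.
#'
#' @param reference,estimate signals with common sampling
#' @export
snr_db <- function(reference, estimate) {
  resid <- as_signal_matrix(reference) - as_signal_matrix(estimate)
  rn <- l2_norm(resid)
  if (rn == 0) return(Inf)
  20 * log10(l2_norm(reference) / rn)
}

#' Maximum cross-correlation over lags
#'
#' Signals are mean-subtracted and unit-normalized before the lag scan (so
#' identical signals score 1 at zero lag); the maximum of sum u(t + tau) v(t)
#' over tau in \[-max_lag, max_lag\] is returned with its lag.
#'
#' @param u,v numeric vectors with common sampling
#' @param dt sample interval (s)
#' @param max_lag lag range (s); default 0.5
#' @param normalize mean-subtract and unit-normalize first (default TRUE)
#' @return list with `value` and `lag_s`
#' @export
max_cross_correlation <- function(u, v, dt, max_lag = 0.5, normalize = TRUE) {
  if (length(u) != length(v)) abort("signals must have the same length")
  if (normalize) {
    u <- u - mean(u); v <- v - mean(v)
    if (sum(u^2) > 0) u <- u / sqrt(sum(u^2))
    if (sum(v^2) > 0) v <- v / sqrt(sum(v^2))
  }
  L <- min(length(u) - 1, round(max_lag / dt))
  lags <- -L:L
  # positive lag means v trails u by lag seconds
  vals <- vapply(lags, function(k) {
    if (k >= 0) sum(u[1:(length(u) - k)] * v[(1 + k):length(v)])
    else sum(u[(1 - k):length(u)] * v[1:(length(v) + k)])
  }, numeric(1))
  best <- which.max(vals)
  list(value = vals[best], lag_s = lags[best] * dt)
}

#' Coefficient of variation of steady-segment amplitudes
#'
#' Standard deviation over mean of the piecewise-constant segment amplitudes
#' of a decomposition. Near-baseline segments (amplitude below `rel_floor`
#' times the maximum) are excluded so the statistic reflects the stimulated
#' steady states; a low CV at the PN relative to the OSN is the
#' concentration-invariance proxy.
#'
#' @param decomp an [decompose_response()] result
#' @param rel_floor baseline-exclusion threshold (fraction of max amplitude)
#' @return the CV, or NA if fewer than 2 segments remain or the mean is 0
#' @export
step_amplitude_cv <- function(decomp, rel_floor = 0.05) {
  amps <- attr(decomp, "segments")
  if (length(amps) < 2) abort("need at least 2 segments")
  amps <- amps[amps > rel_floor * max(amps)]
  if (length(amps) < 2 || mean(amps) == 0) return(NA_real_)
  sd(amps) / mean(amps)
}
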