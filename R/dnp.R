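#' Differential Divisive Normalization Processors
#'
#' The differential DNP is the first-order gating equation
#' \deqn{dx/dt = \alpha \cdot v \cdot (1 - x) - \beta x - \kappa \cdot g \cdot x}
#' where v is the (transformed) input drive and g the normalizing signal. In
#' the *feedback* configuration the normalizer is the gating variable itself;
#' in the *feedforward* configuration it is a transform of the input. The
#' *global* (spatio-temporal) variants share parameters across R channels and
#' normalize by a pooled cross-channel signal: the across-channel sum of x
#' (global feedback) or a pooled input signal (global feedforward).
#'
#' @name dnp
NULL

DNP_MODES <- c("feedback", "feedforward", "global_feedback", "global_feedforward")

#' DNP parameter set
#'
#' @param alpha amplification rate (1/s)
#' @param beta decay rate (1/s)
#' @param kappa normalization strength (1/s per unit of normalizer)
#' @param mode one of `"feedback"`, `"feedforward"`, `"global_feedback"`,
#'   `"global_feedforward"`
#' @export
dnp_params <- function(alpha, beta, kappa, mode = "feedforward") {
  if (any(c(alpha, beta, kappa) < 0)) abort("alpha, beta, kappa must be >= 0")
  mode <- match.arg(mode, DNP_MODES)
  structure(list(alpha = alpha, beta = beta, kappa = kappa, mode = mode),
            class = "dnp_params")
}

#' Simulate a single-channel differential DNP
#'
#' Fixed-step exponential-Euler integration; the trajectory stays in
#' \[0, 1\] for x0 in \[0, 1\] and non-negative drive/normalizer by
#' construction of the scheme. In feedback mode the `normalizer` argument is
#' ignored and replaced by the gating variable itself.
#'
#' @param params a [dnp_params()] object
#' @param drive input drive time series (numeric vector, >= 0)
#' @param normalizer normalizing time series (feedforward mode only)
#' @param dt sample interval (s)
#' @param x0 initial gating value in \[0, 1\]
#' @return tibble with columns `time_s`, `x`
#' @export
simulate_dnp <- function(params, drive, normalizer = NULL, dt = 1e-4, x0 = 0) {
  if (x0 < 0 || x0 > 1) abort("x0 must be in [0, 1]")
  feedback <- params$mode %in% c("feedback", "global_feedback")
  if (is.null(normalizer)) normalizer <- numeric(length(drive))
  if (length(normalizer) != length(drive))
    abort("drive and normalizer must have the same length")
  x <- cpp_simulate_dnp(drive, normalizer, params$alpha, params$beta,
                        params$kappa, feedback, dt, x0)
  tibble(time_s = seq_along(drive) * dt - dt, x = x)
}

#' Simulate a global (spatio-temporal) differential DNP
#'
#' All channels share (alpha, beta, kappa); the normalizer is pooled across
#' channels: the across-channel sum of the gating variables in
#' `global_feedback` mode (the T6 pooling, a sum by convention), or the
#' supplied `pooled` series (default: the across-channel sum of the drives)
#' in `global_feedforward` mode.
#'
#' @param params a [dnp_params()]
#' @param drives R x T matrix of per-channel drives (rows = channels)
#' @param pooled pooled feedforward normalizer (length T); default column
#'   sums of `drives`
#' @param dt sample interval (s)
#' @param x0 shared initial value
#' @return tibble with columns `time_s`, `channel`, `x`
#' @export
simulate_global_dnp <- function(params, drives, pooled = NULL, dt = 1e-4,
                                x0 = 0) {
  drives <- as.matrix(drives)
  feedback <- params$mode %in% c("feedback", "global_feedback")
  if (is.null(pooled)) pooled <- colSums(drives)
  if (length(pooled) != ncol(drives)) abort("pooled length must match drives")
  x <- cpp_simulate_global_dnp(drives, pooled, params$alpha, params$beta,
                               params$kappa, feedback, dt, x0)
  tibble(
    time_s = rep(seq_len(ncol(drives)) * dt - dt, each = nrow(drives)),
    channel = rep(seq_len(nrow(drives)), ncol(drives)),
    x = as.vector(x)
  ) %>% arrange(.data$channel, .data$time_s)
}

#' Feedforward steady state of the (global) differential DNP
#'
#' x_inf = alpha * drive / (beta + alpha * drive + kappa * pooled).
#'
#' @param params a [dnp_params()]
#' @param drive drive value(s)
#' @param pooled pooled normalizer value(s)
#' @export
steady_state_ff <- function(params, drive, pooled = 0) {
  den <- params$beta + params$alpha * drive + params$kappa * pooled
  if (any(den <= 0)) abort("steady-state denominator must be positive")
  params$alpha * drive / den
}

#' Feedback steady state of the differential DNP
#'
#' With the feedback normalizer equal to the gating variable, the fixed point
#' solves the quadratic kappa x^2 + (alpha v + beta) x - alpha v = 0; the
#' root in \[0, 1\] is returned.
#'
#' @param params a [dnp_params()]
#' @param drive drive value(s)
#' @export
steady_state_fb <- function(params, drive) {
  av <- params$alpha * drive
  k <- params$kappa
  if (k == 0) return(av / (av + params$beta))
  bq <- av + params$beta
  (-bq + sqrt(bq^2 + 4 * k * av)) / (2 * k)
}

#' Concentration-invariant normalized affinity (strong-normalization limit)
#'
#' In the kappa >> alpha, beta regime the global feedforward DNP steady state
#' is proportional to affinity / ||affinity||_1, independent of the
#' concentration u: the circuit recovers the odorant identity. For a single
#' channel (R = 1) the output is the constant 1 and identity information is
#' lost.
#'
#' @param affinity non-negative affinity vector with at least one positive
#'   entry
#' @param u concentration (> 0); does not affect the result (invariance)
#' @export
steady_state_normalized_affinity <- function(affinity, u = 100) {
  if (u <= 0) abort("u must be > 0")
  if (all(affinity == 0)) abort("need at least one positive affinity")
  if (any(affinity < 0)) abort("affinities must be >= 0")
  affinity / sum(affinity)
}
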