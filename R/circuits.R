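#' Antennal-lobe circuit assembly
#'
#' The single-channel circuit chains an OSN spike train through three local
#' neuron pathways onto a projection neuron (PN): presynaptic Pre-LN
#' inhibition of the OSN axon terminal (concentration invariance), and
#' postsynaptic excitatory/inhibitory LNs (ON/OFF contrast boosting). The
#' multi-channel circuit replicates the Post-LN pathways per glomerulus with
#' shared parameters and pools the Pre-LN pathway across channels.
#'
#' @name circuits
NULL

PRELN_VARIANTS <- c("none", "local_feedback", "local_feedforward",
                    "global_feedback", "global_feedforward")

THETA1_NAMES <- c("alpha1", "beta1", "g_OL", "alpha2", "beta2", "kappa2",
                  "NT_max")
THETA2_NAMES <- c("alpha3", "beta3", "kappa3", "alpha4", "beta4", "alpha5",
                  "beta5", "g_OeL")
THETA3_NAMES <- c("alpha6", "beta6", "kappa6", "alpha7", "beta7", "alpha8",
                  "beta8", "g_OiL")

#' Free circuit parameters theta = (theta1, theta2, theta3)
#'
#' The circuit has exactly 23 free parameters: 7 in the Pre-LN pathway
#' (OSN-to-Pre-LN synapse rates and conductance, axon-terminal rates and
#' maximal neurotransmitter concentration), 8 in the Post-eLN pathway and 8
#' in the Post-iLN pathway (dual input filters, gated synapse, conductance).
#' The OSN-to-PN and LN-to-PN synapses are fixed (alpha = 1, beta = 100,
#' gmax = 100) and are not free. All free values must lie within `bounds`
#' (default \[1, 1e6\], the stable range for the 0.1 ms integration step).
#'
#' @param theta1,theta2,theta3 named numeric vectors (see
#'   `aldnp:::THETA1_NAMES` etc. for the canonical names)
#' @param bounds length-2 numeric; allowed range for every free parameter
#' @return a `circuit_params` object
#' @export
circuit_params <- function(theta1, theta2, theta3, bounds = c(1, 1e6)) {
  chk <- function(x, nms, lbl) {
    if (!all(nms %in% names(x)))
      abort(paste0(lbl, " must contain: ", paste(nms, collapse = ", ")))
    x <- x[nms]
    if (any(x < bounds[1] | x > bounds[2]))
      abort(paste0(lbl, " entries out of bounds [", bounds[1], ", ",
                   bounds[2], "]"))
    x
  }
  out <- structure(list(theta1 = chk(theta1, THETA1_NAMES, "theta1"),
                        theta2 = chk(theta2, THETA2_NAMES, "theta2"),
                        theta3 = chk(theta3, THETA3_NAMES, "theta3"),
                        bounds = bounds),
                   class = "circuit_params")
  stopifnot(free_parameter_count(out) == 23L)
  out
}

#' Number of free parameters of a circuit parameterization
#' @param theta a `circuit_params`
#' @export
free_parameter_count <- function(theta) {
  length(theta$theta1) + length(theta$theta2) + length(theta$theta3)
}

# canonical 23-vector in engine order
theta_vector <- function(theta) {
  unname(c(theta$theta1[THETA1_NAMES], theta$theta2[THETA2_NAMES],
           theta$theta3[THETA3_NAMES]))
}

theta_from_vector <- function(v, bounds = c(1, 1e6)) {
  circuit_params(setNames(v[1:7], THETA1_NAMES),
                 setNames(v[8:15], THETA2_NAMES),
                 setNames(v[16:23], THETA3_NAMES), bounds = bounds)
}

#' Reference (hand-tuned) circuit parameters
#'
#' A feasible parameter set used as the generating truth of the
#' pseudo-physiology module and as a worked-example default. It was tuned
#' once so that the reference PN response shows visible concentration
#' invariance (strong presynaptic normalization, axon-terminal gating well
#' below saturation) and clear ON/OFF transients; it is a fixture of this
#' package, not a published estimate.
#' @export
default_circuit_params <- function() {
  circuit_params(
    theta1 = c(alpha1 = 300, beta1 = 5, g_OL = 1, alpha2 = 1.2e3,
               beta2 = 40, kappa2 = 2e3, NT_max = 2.1),
    theta2 = c(alpha3 = 200, beta3 = 50, kappa3 = 2000, alpha4 = 2e4,
               beta4 = 80, alpha5 = 120, beta5 = 2, g_OeL = 1),
    theta3 = c(alpha6 = 100, beta6 = 50, kappa6 = 1000, alpha7 = 50,
               beta7 = 2, alpha8 = 2e4, beta8 = 100, g_OiL = 2.5)
  )
}

#' Reference stimulus: return-to-baseline three-level staircase
#'
#' Each concentration level is presented from clean air, so every level has
#' a distinct onset and offset event; the recording continues for
#' `tail_duration` after the last offset so the final OFF response is fully
#' captured. The pseudo-physiology and acceptance runs use this stimulus.
#' @param levels the three step levels (ppm)
#' @param step_duration s per segment
#' @param dt sample interval (s)
#' @param tail_duration s of clean air after the last offset
#' @export
reference_staircase <- function(levels = c(100, 500, 1000),
                                step_duration = 0.75, dt = 1e-4,
                                tail_duration = 1.25) {
  lv <- c(0, levels[1], 0, levels[2], 0, levels[3], 0)
  make_staircase(lv, step_duration = c(rep(step_duration, 6), tail_duration),
                 dt = dt)
}

#' Declarative wiring plan for the Pre-LN inhibition architecture
#'
#' Five variants: no inhibition; per-channel (local) feedback or feedforward
#' Pre-LNs; and panglomerular (global) feedback or feedforward Pre-LNs.
#' Feedforward Pre-LNs are driven by the OSN spike trains; feedback Pre-LNs
#' by the axon-terminal neurotransmitter concentration. Local variants
#' instantiate one Pre-LN per channel sharing parameters; global variants a
#' single Pre-LN pooling all channels and inhibiting every terminal.
#'
#' @param variant one of `"none"`, `"local_feedback"`, `"local_feedforward"`,
#'   `"global_feedback"`, `"global_feedforward"`
#' @param R number of channels (>= 1)
#' @return an `al_architecture` list with the wiring plan
#' @export
build_architecture <- function(variant = "global_feedforward", R = 1) {
  variant <- match.arg(variant, PRELN_VARIANTS)
  if (R < 1) abort("R must be >= 1")
  n_preln <- switch(variant, none = 0L,
                    local_feedback = as.integer(R),
                    local_feedforward = as.integer(R), 1L)
  structure(list(
    variant = variant, R = as.integer(R), n_preln = n_preln,
    preln_input = switch(variant, none = NULL,
                         local_feedback = "NT_same_channel",
                         global_feedback = "NT_all_channels",
                         local_feedforward = "osn_spikes_same_channel",
                         global_feedforward = "osn_spikes_all_channels"),
    inhibition_target = if (variant == "none") NULL
                        else if (n_preln == 1L) "all_axon_terminals"
                        else "own_axon_terminal"
  ), class = "al_architecture")
}

variant_code <- function(variant) {
  match(match.arg(variant, PRELN_VARIANTS), PRELN_VARIANTS) - 1L
}

#' Simplified OSN front-end parameters
#'
#' Stand-in for the odorant transduction process: the bound-receptor ratio
#' v = a u / (1 + a u) drives a transduction gate with a slow calcium-like
#' feedback normalizer, producing the characteristic transient overshoot
#' after concentration steps; the gating drives a noiseless Connor-Stevens
#' spike generator through a flat gain (uA per unit gating).
#' @param alpha,beta,kappa fast transduction gate rates (1/s)
#' @param alpha_s,beta_s slow calcium feedback rates (1/s)
#' @param spont spontaneous receptor activity added to the bound-receptor
#'   ratio (subthreshold on its own)
#' @param noise_sigma OSN membrane-noise intensity; with the subthreshold
#'   spontaneous drive it produces the characteristic low-rate background
#'   firing of the sensory neurons
#' @param gain current gain (uA)
#' @export
osn_frontend_params <- function(alpha = 30, beta = 5, kappa = 60,
                                alpha_s = 3, beta_s = 1.5, gain = 45,
                                spont = 0.3, noise_sigma = 0.004) {
  list(alpha = alpha, beta = beta, kappa = kappa, alpha_s = alpha_s,
       beta_s = beta_s, gain = gain, spont = spont,
       noise_sigma = noise_sigma)
}

#' OSN front-end: per-channel stimulus drives to OSN spike trains
#'
#' @param drive R x T matrix of per-channel drives (affinity * u), or the
#'   tidy output of [stimulus_drive()]
#' @param dt sample interval (s)
#' @param params an [osn_frontend_params()]
#' @param cs a [connor_stevens_params()] for the OSN spike generator
#' @param seed master seed for the OSN membrane noise (per-channel sub-seeds
#'   are derived from it)
#' @return an `al_spikes` tibble with columns `channel`, `time_s`; attributes
#'   `duration`, `dt`, `R`, and `gating` (R x T matrix of the transduction
#'   gate, for inspection)
#' @export
osn_frontend <- function(drive, dt = 1e-4, params = osn_frontend_params(),
                         cs = connor_stevens_params(), seed = 1L) {
  if (is.data.frame(drive)) {
    rec <- unique(drive$receptor)
    drive <- t(vapply(rec, function(r) drive$drive[drive$receptor == r],
                      numeric(sum(drive$receptor == rec[1]))))
  }
  drive <- as.matrix(drive)
  if (any(drive < 0)) abort("stimulus drive must be non-negative")
  v <- (drive + params$spont) / (1 + drive + params$spont)
  x <- cpp_osn_gating(v, params$alpha, params$beta, params$kappa,
                      params$alpha_s, params$beta_s, dt, warmup_s = 3)
  spk <- purrr::map(seq_len(nrow(x)), function(r) {
    res <- cpp_simulate_cs(params$gain * x[r, ], dt, params$noise_sigma,
                           NOISE_SCALE, as.integer(seed) * 131L + r,
                           cs_vector(cs), FALSE)
    res$spikes
  })
  out <- tibble(channel = rep(seq_along(spk), lengths(spk)),
                time_s = unlist(spk) %||% numeric())
  attr(out, "duration") <- ncol(drive) * dt
  attr(out, "dt") <- dt
  attr(out, "R") <- nrow(drive)
  attr(out, "gating") <- x
  class(out) <- c("al_spikes", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bin an al_spikes tibble into an R x T delta matrix (amplitude 1/dt)
spikes_to_deltas <- function(spikes, R, n, dt) {
  m <- matrix(0, R, n)
  for (r in seq_len(R)) {
    tm <- spikes$time_s[spikes$channel == r]
    m[r, ] <- cpp_bin_deltas(tm, n, dt)
  }
  m
}

al_engine <- function(osn_delta, theta, variant, pathways, dt, sigma_P, seed,
                      record, rev = al_reversals(),
                      cs = connor_stevens_params(), warmup_s = 3,
                      warmup_epoch_s = 0.5) {
  cpp_simulate_circuit(osn_delta, theta_vector(theta), variant_code(variant),
                       pathways, dt, sigma_P, NOISE_SCALE, as.integer(seed),
                       rev, cs_vector(cs), record, warmup_s, warmup_epoch_s)
}

as_al_traces <- function(res, theta, variant, R, dt, n) {
  structure(list(
    R = R, dt = dt, duration = n * dt, variant = variant, theta = theta,
    x_AxT = res$x_AxT, NT = res$NT, I_OP = res$I_OP, I_eLP = res$I_eLP,
    I_iLP = res$I_iLP, V_P = res$V_P, x_OP = res$x_OP, x_OeL = res$x_OeL,
    x_OiL = res$x_OiL,
    spikes = list(pn = res$pn_spikes, preln = res$preln_spikes,
                  eln = res$eln_spikes, iln = res$iln_spikes)
  ), class = "al_traces")
}

#' Simulate the single-channel antennal-lobe circuit
#'
#' Co-integrates all synapse gating ODEs and Connor-Stevens spike generators
#' on one fixed time grid: OSN to Pre-LN synapse and Pre-LN spike generator;
#' the axon terminal with presynaptic inhibition; the dual-filter OSN to
#' Post-eLN and Post-iLN synapses with their spike generators; and the three
#' fixed synapses onto the PN, whose input current is the sum of the
#' axon-terminal, Post-eLN and Post-iLN currents.
#'
#' @param theta a [circuit_params()]
#' @param osn_spikes an `al_spikes` tibble (single channel) from
#'   [osn_frontend()], or a tibble with a `time_s` column
#' @param dt time step (s)
#' @param seed master seed for the PN membrane noise
#' @param sigma_P PN noise intensity; default the published value
#' @return an `al_traces` object
#' @export
simulate_single_channel <- function(theta, osn_spikes, dt = 1e-4, seed = 1L,
                                    sigma_P = SIGMA_PN) {
  dur <- attr(osn_spikes, "duration") %||% max(osn_spikes$time_s) + 0.1
  n <- round(dur / dt)
  if (!"channel" %in% names(osn_spikes)) osn_spikes$channel <- 1L
  deltas <- spikes_to_deltas(osn_spikes, 1L, n, dt)
  res <- al_engine(deltas, theta, "global_feedforward", c(TRUE, TRUE, TRUE),
                   dt, sigma_P, seed, TRUE)
  as_al_traces(res, theta, "single_channel", 1L, dt, n)
}

#' Simulate the multi-channel antennal-lobe circuit
#'
#' Post-eLN/Post-iLN pathways are replicated per channel with shared
#' parameters; the Pre-LN pathway follows the architecture plan (none,
#' local, or global/panglomerular; feedforward or feedback). The global
#' Pre-LN dendrite sums the OSN-to-Pre-LN synaptic currents across channels
#' into one spike generator whose spike train inhibits every axon terminal.
#'
#' @param theta a [circuit_params()]
#' @param arch an [build_architecture()] plan
#' @param osn_spikes an `al_spikes` tibble with R channels
#' @param dt time step (s)
#' @param seed master seed (per-neuron seeds are derived by stable hashing
#'   of population and channel, so channel permutations are exact)
#' @param sigma_P PN noise intensity
#' @param pathways logical length-3: simulate (Pre-LN, Post-eLN, Post-iLN)
#' @return an `al_traces` object
#' @export
simulate_multi_channel <- function(theta, arch, osn_spikes, dt = 1e-4,
                                   seed = 1L, sigma_P = SIGMA_PN,
                                   pathways = c(TRUE, TRUE, TRUE)) {
  R <- arch$R
  dur <- attr(osn_spikes, "duration") %||% max(osn_spikes$time_s) + 0.1
  n <- round(dur / dt)
  deltas <- spikes_to_deltas(osn_spikes, R, n, dt)
  res <- al_engine(deltas, theta, arch$variant, pathways, dt, sigma_P, seed,
                   TRUE)
  as_al_traces(res, theta, arch$variant, R, dt, n)
}

# pathway-only simulation used by the optimization objectives; returns the
# relevant PN-input current component (R x T) and the max axon-terminal
# gating. Noise-free so objectives are deterministic.
simulate_pathway <- function(pathway, theta, osn_delta, variant, dt,
                             seed = 0L) {
  pathway <- match.arg(pathway, c("preln", "post_eln", "post_iln",
                                  "preln_multichannel"))
  flags <- switch(pathway,
                  preln = c(TRUE, FALSE, FALSE),
                  preln_multichannel = c(TRUE, FALSE, FALSE),
                  post_eln = c(FALSE, TRUE, FALSE),
                  post_iln = c(FALSE, FALSE, TRUE))
  res <- al_engine(osn_delta, theta, variant, flags, dt, 0, seed, FALSE)
  I <- switch(pathway, post_eln = res$I_eLP, post_iln = res$I_iLP, res$I_OP)
  list(I = I, max_gating = max(res$x_AxT))
}

#' Tidy the PN-input currents of a circuit simulation
#' @param traces an `al_traces` object
#' @return tibble with columns `time_s`, `channel`, `i_op`, `i_elp`, `i_ilp`
#' @export
al_currents <- function(traces) {
  n <- ncol(traces$I_OP)
  has_e <- !is.null(traces$I_eLP) && length(traces$I_eLP) > 0
  has_i <- !is.null(traces$I_iLP) && length(traces$I_iLP) > 0
  tibble(
    time_s = rep(seq_len(n) * traces$dt - traces$dt, traces$R),
    channel = rep(seq_len(traces$R), each = n),
    i_op = as.vector(t(traces$I_OP)),
    i_elp = if (has_e) as.vector(t(traces$I_eLP)) else 0,
    i_ilp = if (has_i) as.vector(t(traces$I_iLP)) else 0
  )
}

#' Tidy the spike trains of a circuit simulation
#' @param traces an `al_traces` object
#' @return tibble with columns `population`, `channel`, `time_s`
#' @export
al_spike_trains <- function(traces) {
  purrr::imap_dfr(traces$spikes, function(lst, pop)
    purrr::imap_dfr(lst, function(tm, ch)
      tibble(population = pop, channel = ch, time_s = as.numeric(tm))))
}

#' @export
print.al_traces <- function(x, ...) {
  cat("<al_traces> ", x$variant, ": R = ", x$R, ", duration = ", x$duration,
      " s, dt = ", x$dt, " s\n", sep = "")
  npn <- sum(lengths(x$spikes$pn))
  cat("  PN spikes: ", npn, " (", round(npn / x$duration / x$R, 1),
      " Hz/channel)\n", sep = "")
  invisible(x)
}
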