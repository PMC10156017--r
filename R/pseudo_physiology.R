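#' Pseudo-physiology: synthetic reference recordings
#'
#' The electrophysiology dataset behind the original analysis (Or59b OSN /
#' DM4 PN staircase recordings) is not redistributable, so this module
#' emulates it: a reference circuit with known parameters theta* is
#' simulated for repeated trials, PSTHs are estimated exactly as for real
#' recordings, and the target synaptic-current components are derived from
#' the PN PSTH by frequency-current inversion and steady/transient
#' decomposition. Fits against these targets are parameter-recovery
#' experiments with a known ground truth.
#'
#' @name pseudo_physiology
NULL

#' Generate a reference recording from a known circuit
#'
#' @param theta_star generating parameters ([circuit_params()]); default the
#'   hand-tuned reference set
#' @param waveform a `conc_waveform` stimulus
#' @param identity an `odor_identity`; default a single channel with
#'   affinity 0.005 (mid dynamic range of the front-end; the
#'   recorded-glomerulus stand-in)
#' @param n_trials repeated simulations with distinct PN-noise sub-seeds
#' @param seed master seed
#' @param dt simulation step (s)
#' @param fi an [fi_curve()] for the PN inversion; computed if missing
#' @return an `al_reference` object: stimulus, OSN/PN PSTHs, target current
#'   components (`target_I_OP`, `target_I_eLP`, `target_I_iLP` matrices on
#'   the simulation grid), the OSN spikes, theta_star and seeds
#' @export
generate_reference <- function(theta_star = default_circuit_params(),
                               waveform,
                               identity = odorant_identity("reference", 0.005, 1),
                               n_trials = 20, seed = 1L, dt = 1e-4,
                               fi = NULL) {
  R <- nrow(identity)
  arch <- build_architecture("global_feedforward", R)
  osn <- osn_frontend(drive_matrix(identity, waveform), dt = dt)
  trials <- purrr::map(seq_len(n_trials), function(k) {
    tr <- simulate_multi_channel(theta_star, arch, osn, dt = dt,
                                 seed = seed * 1000L + k)
    purrr::imap_dfr(tr$spikes$pn,
                    ~ tibble(channel = .y, time_s = as.numeric(.x)))
  })
  dur <- attr(osn, "duration")
  pn_psth <- estimate_psth(trials, t_end = dur)
  osn_psth <- estimate_psth(list(osn), t_end = dur)
  if (is.null(fi)) fi <- fi_curve()
  targets <- targets_from_psth(pn_psth, fi, waveform)
  structure(list(
    stimulus = waveform, identity = identity, osn_spikes = osn,
    osn_psth = osn_psth, pn_psth = pn_psth,
    target_I_OP = targets$I_OP, target_I_eLP = targets$I_eLP,
    target_I_iLP = targets$I_iLP, jump_times = targets$jump_times,
    valid = targets$valid,
    theta_star = theta_star, n_trials = n_trials, seed = seed, dt = dt,
    fi = fi
  ), class = "al_reference")
}

#' Scale a single-channel PN PSTH across channels by affinity
#'
#' The multi-channel PSTH estimate used when only one glomerulus was
#' recorded: channel q receives (affinity_q / affinity_ref) times the
#' reference-channel PSTH, so the L1-normalized spatial profile at any time
#' equals the L1-normalized affinity vector.
#'
#' @param pn_psth_single a single-channel `al_psth`
#' @param id an `odor_identity` providing the affinity vector
#' @param reference_channel index of the recorded channel (positive
#'   affinity)
#' @return a multi-channel `al_psth`
#' @export
scale_psth_by_affinity <- function(pn_psth_single, id,
                                   reference_channel = 1L) {
  aref <- id$affinity[reference_channel]
  if (aref <= 0) abort("reference channel must have positive affinity")
  base <- pn_psth_single[pn_psth_single$channel == pn_psth_single$channel[1], ]
  out <- purrr::map_dfr(seq_len(nrow(id)), function(q)
    tibble(time_s = base$time_s, channel = q,
           rate_hz = id$affinity[q] / aref * base$rate_hz))
  for (at in c("window", "overlap", "n_trials", "t_end"))
    attr(out, at) <- attr(pn_psth_single, at)
  class(out) <- class(pn_psth_single)
  out
}

#' Derive target current components from a PN PSTH
#'
#' Inverts the PSTH through the frequency-current curve to the total PN
#' input current, reports it relative to the rheobase floor (the inversion
#' maps silent stretches to the floor current, which is intrinsic rather
#' than synaptic, so non-responding channels carry zero synaptic target),
#' then decomposes it at the stimulus jump times: the steady component is
#' the axon-terminal (I_OP) target, the positive-rectified transient the
#' Post-eLN (I_eLP) target and the negative-rectified transient the
#' Post-iLN (I_iLP) target. The three targets sum to the full inverted
#' (floor-relative) current exactly.
#'
#' Within half a PSTH window of a concentration jump the windowed rate
#' estimate mixes pre- and post-jump regimes, so the inverted current there
#' is an artifact of the estimator rather than physiology; those samples are
#' flagged invalid in the returned `valid` mask (guard ring `guard_s` around
#' each jump) and objective evaluations exclude them on both sides.
#'
#' @param psth an `al_psth` (one or more channels)
#' @param fi an [fi_curve()]
#' @param stimulus the `conc_waveform` whose jump times anchor the
#'   decomposition
#' @param pre_window steady-amplitude averaging window (s)
#' @param guard_s half-width of the invalid ring around each jump (s);
#'   default just over half the 200 ms PSTH window
#' @return list with `I_OP`, `I_eLP`, `I_iLP` (channels x time matrices on
#'   the stimulus grid), `I_total`, `jump_times`, and the logical `valid`
#'   mask
#' @export
targets_from_psth <- function(psth, fi, stimulus, pre_window = 0.5,
                              guard_s = 0.125) {
  grid <- stimulus$time_s
  dt <- wf_dt(stimulus)
  rates <- psth_interpolate(psth, grid)
  jumps <- detect_jump_times(stimulus)
  valid <- rep(TRUE, length(grid))
  for (j in jumps$time_s)
    valid[abs(grid - j) <= guard_s] <- FALSE
  R <- nrow(rates)
  I_tot <- matrix(0, R, length(grid))
  I_OP <- I_tot; I_e <- I_tot; I_i <- I_tot
  floor_current <- fi_inverse(fi, 0)
  for (r in seq_len(R)) {
    I_tot[r, ] <- fi_inverse(fi, rates[r, ]) - floor_current
    dec <- decompose_response(I_tot[r, ], jumps$time_s,
                              pre_window = pre_window, dt = dt)
    I_OP[r, ] <- dec$steady
    I_e[r, ] <- dec$on
    I_i[r, ] <- dec$off
  }
  list(I_OP = I_OP, I_eLP = I_e, I_iLP = I_i, I_total = I_tot,
       jump_times = jumps$time_s, valid = valid)
}

#' @export
print.al_reference <- function(x, ...) {
  cat("<al_reference> ", nrow(x$identity), " channel(s), ", x$n_trials,
      " trial(s), duration ", attr(x$osn_spikes, "duration"), " s\n",
      sep = "")
  invisible(x)
}
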