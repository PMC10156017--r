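#' Desk-scale headline experiments
#'
#' Reduced-size versions of the headline computational experiments: odorant
#' identity recovery across a panel and concentration range, comparison of
#' the five presynaptic-inhibition architectures on the identity-recovery
#' objective, and robustness of ON/OFF event timing to stimulus noise.
#' Every experiment is a pure function of its configuration and seed.
#'
#' @name experiments
NULL

#' Identity recovery across an odorant panel and concentration range
#'
#' For each odorant and step-concentration level the multi-channel circuit
#' is simulated and the steady-window population responses of OSNs and PNs
#' (mean firing rate per channel) are compared, by angular distance, to the
#' L1-normalized odorant affinity vector. Lower PN than OSN distance means
#' the circuit moved the population response toward the odorant identity.
#'
#' @param panel an `odor_panel`
#' @param conc_levels step concentration levels (ppm)
#' @param theta a [circuit_params()]
#' @param arch an [build_architecture()]; its R must match the panel
#' @param seed integer seed
#' @param dt simulation step (s)
#' @param t_pre,t_on baseline and stimulus durations (s); the steady window
#'   is the last second of stimulation
#' @return tibble: `odorant`, `conc_ppm`, `osn_distance`, `pn_distance`
#' @export
run_identity_panel <- function(panel, conc_levels, theta = default_circuit_params(),
                               arch = build_architecture("global_feedforward",
                                                         length(unique(panel$receptor))),
                               seed = 1L, dt = 1e-4, t_pre = 0.5, t_on = 2) {
  odors <- unique(panel$odorant)
  if (length(unique(panel$receptor)) != arch$R)
    abort("panel and architecture must share R")
  purrr::map_dfr(odors, function(o) {
    id <- panel_identity(panel, o)
    aff <- steady_state_normalized_affinity(id$affinity)
    purrr::map_dfr(conc_levels, function(u) {
      w <- make_staircase(c(0, u), step_duration = c(t_pre, t_on), dt = dt)
      osn <- osn_frontend(drive_matrix(id, w), dt = dt)
      tr <- simulate_multi_channel(theta, arch, osn, dt = dt, seed = seed)
      win0 <- t_pre + t_on - 1; win1 <- t_pre + t_on
      rate_in_window <- function(times) sum(times >= win0 & times < win1)
      osn_rates <- vapply(seq_len(arch$R), function(r)
        rate_in_window(osn$time_s[osn$channel == r]), numeric(1))
      pn_rates <- vapply(tr$spikes$pn, rate_in_window, numeric(1))
      tibble(odorant = o, conc_ppm = u,
             osn_distance = if (sum(osn_rates) == 0) 1
                            else angular_distance(osn_rates, aff),
             pn_distance = if (sum(pn_rates) == 0) 1
                           else angular_distance(pn_rates, aff))
    })
  })
}

#' Compare the five Pre-LN architectures on the identity-recovery objective
#'
#' Draws `n_samples` random theta1 vectors (correlation-screened LHS over
#' the global bounds) and evaluates, for every architecture variant, the
#' multi-channel identity-recovery objective against a shared target built
#' from a reference recording scaled across channels by the odorant
#' affinity. Global (panglomerular) inhibition is expected to dominate: its
#' objective distribution should sit below the local and no-inhibition
#' variants.
#'
#' @param reference an [generate_reference()] single-channel recording
#' @param identity multi-channel `odor_identity` defining the affinity
#'   pattern (its reference channel 1 corresponds to the recording)
#' @param n_samples random parameter sets per variant (>= 50)
#' @param variants architecture variants to compare
#' @param seed integer seed (shared sample matrix across variants)
#' @return tibble: `variant`, `sample`, `objective`, `feasible`
#' @export
run_architecture_comparison <- function(reference, identity, n_samples = 200,
                                        variants = PRELN_VARIANTS,
                                        seed = 1L) {
  if (n_samples < 50) abort("need n_samples >= 50")
  R <- nrow(identity)
  psth_mc <- scale_psth_by_affinity(reference$pn_psth, identity, 1L)
  targets <- targets_from_psth(psth_mc, reference$fi, reference$stimulus)
  osn <- osn_frontend(drive_matrix(identity, reference$stimulus),
                      dt = reference$dt)
  X <- lhs_sample(length(THETA1_NAMES), n_samples,
                  reference$theta_star$bounds, K = min(1000, n_samples),
                  iters = 5, seed = seed)
  purrr::map_dfr(variants, function(v) {
    spec <- objective_spec("preln_multichannel", targets$I_OP, osn,
                           variant = v, dt = reference$dt,
                           base_theta = reference$theta_star,
                           stimulus = reference$stimulus)
    purrr::map_dfr(seq_len(nrow(X)), function(i)
      mutate(eval_objective(spec, X[i, ]), variant = v, sample = i)) %>%
      dplyr::select("variant", "sample", "objective", "feasible")
  })
}

#' ON/OFF event-timing robustness to stimulus white noise
#'
#' Simulates the circuit on a staircase with increasing levels of additive
#' white noise and extracts ON events from the Post-eLN current and OFF
#' events from the magnitude of the Post-iLN current (same thresholded-peak
#' rule as the stimulus jump detector); reports each event's timing error
#' against the noise-free run.
#'
#' @param theta a [circuit_params()]
#' @param waveform the clean `conc_waveform` staircase
#' @param identity an `odor_identity` (default one unit-affinity channel)
#' @param noise_sigmas noise standard deviations (ppm); 0 is added as the
#'   reference automatically
#' @param seed integer seed
#' @param dt simulation step (s)
#' @param smooth_s current-smoothing half width (s) before peak detection
#' @return tibble: `sigma`, `event_type` ("on"/"off"), `ref_time_s`,
#'   `time_s`, `timing_error_s`
#' @export
run_noise_robustness <- function(theta = default_circuit_params(), waveform,
                                 identity = odorant_identity("probe", 1, 1),
                                 noise_sigmas = c(5, 10), seed = 1L,
                                 dt = 1e-4, smooth_s = 0.05,
                                 event_window = 0.6) {
  arch <- build_architecture("global_feedforward", nrow(identity))
  half <- round(smooth_s / dt)
  # events are timing markers for stimulus transitions: a detected current
  # peak counts as an event only within `event_window` after a transition
  # of the clean stimulus (onsets for ON, offsets for OFF)
  jumps <- detect_jump_times(waveform)
  near <- function(tbl, tms) {
    keep <- vapply(tbl$time_s, function(t)
      any(t >= tms & t <= tms + event_window), logical(1))
    tbl[keep, ]
  }
  events_for <- function(sigma, k) {
    w <- if (sigma == 0) waveform else add_white_noise(waveform, sigma,
                                                       seed + k)
    osn <- osn_frontend(drive_matrix(identity, w), dt = dt)
    tr <- simulate_multi_channel(theta, arch, osn, dt = dt, seed = seed,
                                 sigma_P = 0)
    tgrid <- seq_len(ncol(tr$I_OP)) * dt - dt
    on <- near(find_signal_peaks(cpp_boxcar(tr$I_eLP[1, ], half), tgrid),
               jumps$time_s[jumps$sign > 0])
    off <- near(find_signal_peaks(cpp_boxcar(abs(tr$I_iLP[1, ]), half),
                                  tgrid),
                jumps$time_s[jumps$sign < 0])
    dplyr::bind_rows(mutate(on, event_type = "on"),
                     mutate(off, event_type = "off")) %>%
      mutate(sigma = sigma) %>% dplyr::select(-"sign")
  }
  ref <- events_for(0, 0)
  purrr::imap_dfr(c(0, noise_sigmas), function(sg, k) {
    ev <- events_for(sg, k)
    ev %>% group_by(.data$event_type) %>%
      mutate(idx = dplyr::row_number()) %>% ungroup() %>%
      dplyr::left_join(
        ref %>% group_by(.data$event_type) %>%
          mutate(idx = dplyr::row_number()) %>% ungroup() %>%
          dplyr::select("event_type", "idx", ref_time_s = "time_s"),
        by = c("event_type", "idx")) %>%
      mutate(timing_error_s = .data$time_s - .data$ref_time_s) %>%
      dplyr::select("sigma", "event_type", "ref_time_s", "time_s",
                    "timing_error_s")
  })
}
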