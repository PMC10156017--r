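#' Odorant stimuli: concentration waveforms, identities and affinity panels
#'
#' Odorant stimuli are represented as the multiplicative coupling of a
#' *concentration waveform* u(t) (syntactic information, in ppm) with an
#' *odorant identity* given by per-receptor binding/dissociation rate vectors
#' (b, d) (semantic information). The element-wise ratio b/d is the odorant
#' affinity vector.
#'
#' @name stimuli
NULL

new_waveform <- function(time_s, ppm) {
  out <- tibble(time_s = time_s, ppm = ppm)
  class(out) <- c("conc_waveform", class(out))
  out
}

wf_dt <- function(w) {
  stopifnot(nrow(w) >= 2)
  w$time_s[2] - w$time_s[1]
}

#' Piecewise-constant concentration staircase
#'
#' @param levels concentration levels (ppm, >= 0) visited in order
#' @param step_duration holding time per level (s); scalar or one per level
#' @param dt sample interval (s)
#' @param t0 start time (s)
#' @return a `conc_waveform` tibble with columns `time_s`, `ppm`
#' @export
#' @examples
#' w <- make_staircase(c(0, 100, 0), step_duration = 1, dt = 1e-3)
make_staircase <- function(levels, step_duration = 1, dt = 1e-4, t0 = 0) {
  if (any(levels < 0)) abort("staircase levels must be >= 0")
  if (any(step_duration < dt) || dt <= 0) abort("need step_duration >= dt > 0")
  n_per <- round(rep_len(step_duration, length(levels)) / dt)
  ppm <- rep(levels, times = n_per)
  new_waveform(t0 + seq_along(ppm) * dt - dt, ppm)
}

#' Add white Gaussian noise to a concentration waveform
#'
#' Samples are clipped at zero to keep concentrations physical.
#'
#' @param w a `conc_waveform`
#' @param sigma noise standard deviation (ppm)
#' @param seed integer seed; the same seed reproduces the same waveform
#' @export
add_white_noise <- function(w, sigma, seed = 1L) {
  if (sigma < 0) abort("sigma must be >= 0")
  if (sigma == 0) return(w)
  noise <- withr_rnorm(nrow(w), sigma, seed)
  new_waveform(w$time_s, pmax(0, w$ppm + noise))
}

# local RNG that does not disturb the global .Random.seed
withr_rnorm <- function(n, sigma, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  rnorm(n, 0, sigma)
}

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Concentration contrast d/dt log(eps + u(t))
#'
#' The bias `eps` avoids division by zero at u = 0. The discrete derivative
#' uses central differences in the interior and one-sided differences at the
#' boundaries, so the rectangle-rule integral of the contrast telescopes to
#' log((eps + u_end)/(eps + u_start)) up to one differencing step's
#' truncation error.
#'
#' @param w a `conc_waveform`
#' @param eps bias term (ppm, > 0); default 1
#' @return tibble with columns `time_s`, `contrast` (1/s)
#' @export
concentration_contrast <- function(w, eps = 1) {
  if (eps <= 0) abort("eps must be > 0")
  lg <- log(eps + w$ppm)
  dt <- wf_dt(w)
  n <- length(lg)
  d <- numeric(n)
  d[1] <- (lg[2] - lg[1]) / dt
  d[n] <- (lg[n] - lg[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (lg[3:n] - lg[1:(n - 2)]) / (2 * dt)
  tibble(time_s = w$time_s, contrast = d)
}

#' Odorant identity: per-receptor binding/dissociation rates
#'
#' @param name odorant label
#' @param b binding-rate vector (>= 0; zero marks a non-responding receptor)
#' @param d dissociation-rate vector (> 0), same length as `b`
#' @param receptors optional receptor labels
#' @return an `odor_identity` tibble with columns `receptor`, `b`, `d`,
#'   `affinity` (= b/d)
#' @export
odorant_identity <- function(name, b, d, receptors = NULL) {
  if (length(b) != length(d)) abort("b and d must have the same length")
  if (any(d <= 0)) abort("d must be strictly positive")
  if (any(b < 0)) abort("b must be >= 0")
  if (is.null(receptors)) receptors <- paste0("Or", seq_along(b))
  out <- tibble(receptor = receptors, b = b, d = d, affinity = b / d)
  attr(out, "odorant") <- name
  class(out) <- c("odor_identity", class(out))
  out
}

#' Per-channel stimulus drive
#'
#' The odorant object stimulus couples identity and concentration
#' multiplicatively; channel r receives the drive (b_r/d_r) * u(t).
#'
#' @param id an `odor_identity`
#' @param w a `conc_waveform`
#' @return a tibble with columns `time_s`, `receptor`, `drive`
#' @export
stimulus_drive <- function(id, w) {
  tidyr::expand_grid(receptor = id$receptor, time_s = w$time_s) %>%
    mutate(drive = rep(id$affinity, each = nrow(w)) * rep(w$ppm, nrow(id)))
}

# internal: drive as an R x T matrix (fast path used by the simulators)
drive_matrix <- function(id, w) {
  outer(id$affinity, w$ppm)
}

#' Synthetic odorant affinity panel
#'
#' Stand-in for a measured odorant-response panel: affinities are drawn
#' log-normally (log10 standard deviation `sigma_log10`, default 1, so each
#' odorant spans several orders of magnitude across receptors) and a fraction
#' of receptor channels per odorant are non-responders (affinity 0).
#'
#' @param R number of receptors (>= 2)
#' @param n_odorants number of odorants (>= 1)
#' @param seed integer seed
#' @param mu_log10,sigma_log10 log10-space mean and sd of the affinities
#' @param nonresponder_frac fraction of channels with zero binding
#' @return an `odor_panel` tibble with columns `odorant`, `receptor`, `b`,
#'   `d`, `affinity`
#' @export
synth_affinity_panel <- function(R = 24, n_odorants = 110, seed = 1L,
                                 mu_log10 = -2.5, sigma_log10 = 1,
                                 nonresponder_frac = 0.2) {
  if (R < 2 || n_odorants < 1) abort("need R >= 2 and n_odorants >= 1")
  local_seed(seed, {
    aff <- 10^(mu_log10 + sigma_log10 * matrix(rnorm(R * n_odorants), n_odorants, R))
    d <- 10^matrix(rnorm(R * n_odorants, 1, 0.3), n_odorants, R)
    nz <- matrix(runif(R * n_odorants) < nonresponder_frac, n_odorants, R)
    # keep at least two responding channels per odorant
    for (i in seq_len(n_odorants)) {
      keep <- order(aff[i, ], decreasing = TRUE)[1:2]
      nz[i, keep] <- FALSE
    }
    aff[nz] <- 0
    out <- tidyr::expand_grid(
      odorant = paste0("odorant_", seq_len(n_odorants)),
      receptor = paste0("Or", seq_len(R))
    ) %>%
      mutate(
        affinity = as.vector(t(aff)),
        d = as.vector(t(d)),
        b = .data$affinity * .data$d
      ) %>%
      dplyr::select("odorant", "receptor", "b", "d", "affinity")
    class(out) <- c("odor_panel", class(out))
    out
  })
}

#' Extract one odorant from a panel as an `odor_identity`
#' @param panel an `odor_panel`
#' @param odorant odorant label or index
#' @export
panel_identity <- function(panel, odorant) {
  if (is.numeric(odorant)) odorant <- unique(panel$odorant)[odorant]
  sub <- panel[panel$odorant == odorant, ]
  if (nrow(sub) == 0) abort(paste("unknown odorant:", odorant))
  odorant_identity(odorant, sub$b, sub$d, sub$receptor)
}

#' Read/write a waveform as two-column CSV (time_s, value)
#' @param w waveform; `path` file path
#' @export
#' @rdname waveform_io
write_waveform_csv <- function(w, path) {
  utils::write.csv(data.frame(time_s = w$time_s, value = w$ppm), path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname waveform_io
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  new_waveform(d$time_s, d$value)
}

#' Read an affinity matrix CSV (rows = odorants, columns = receptors)
#'
#' Adapter for user-supplied odorant-response panels; dissociation rates are
#' set to 1 so the matrix entries are used directly as affinities.
#' @param path CSV path with odorant labels in the first column
#' @export
read_affinity_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  odors <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  out <- tidyr::expand_grid(odorant = odors, receptor = colnames(m)) %>%
    mutate(affinity = as.vector(t(m)), d = 1, b = .data$affinity)
  class(out) <- c("odor_panel", class(out))
  out
}
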