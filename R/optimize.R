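#' Angular-distance objectives and the two-step fitting procedure
#'
#' Each local-neuron pathway is fitted independently by minimizing the
#' angular distance between its model synaptic current into the PN and a
#' target current (estimated from recordings, or from the pseudo-physiology
#' module). The Pre-LN objectives carry the saturation constraint
#' max over time (and channels) of the axon-terminal gating < 0.8, enforced
#' as a feasibility filter. Optimization is a two-step procedure: broad
#' Latin-Hypercube screening of the \[1, 1e6\] parameter box, then
#' Differential Evolution inside the mean +/- sd hypercube of the top
#' screened samples.
#'
#' @name optimize
NULL

pathway_block <- function(pathway) {
  switch(pathway,
         preln = "theta1", preln_multichannel = "theta1",
         post_eln = "theta2", post_iln = "theta3")
}

pathway_names <- function(pathway) {
  switch(pathway,
         preln = THETA1_NAMES, preln_multichannel = THETA1_NAMES,
         post_eln = THETA2_NAMES, post_iln = THETA3_NAMES)
}

#' Objective specification for one pathway fit
#'
#' @param pathway `"preln"`, `"post_eln"`, `"post_iln"` or
#'   `"preln_multichannel"`
#' @param target target synaptic-current series: numeric vector (single
#'   channel) or channels x time matrix, sampled on the simulation grid
#' @param osn_spikes the OSN input spike trains (an `al_spikes` tibble)
#' @param variant Pre-LN architecture variant used for Pre-LN pathway fits
#' @param dt simulation step (s)
#' @param constraint_cap axon-terminal gating cap (default 0.8)
#' @param smooth_s half-width (s) of the boxcar applied to the model current
#'   before the angular distance; the default matches the 200 ms PSTH window
#'   through which targets are estimated, so model and target are compared
#'   at the same temporal resolution. 0 disables
#' @param base_theta full parameter set supplying the non-fitted blocks
#' @param stimulus optional `conc_waveform`, stored for provenance
#' @param mask optional logical validity mask (length T, e.g. the `valid`
#'   mask of [targets_from_psth()]); samples flagged FALSE are excluded from
#'   the angular distance on both the target and the model side
#' @export
objective_spec <- function(pathway, target, osn_spikes,
                           variant = "global_feedforward", dt = 1e-4,
                           constraint_cap = 0.8, smooth_s = 0.1,
                           base_theta = default_circuit_params(),
                           stimulus = NULL, mask = NULL) {
  pathway <- match.arg(pathway, c("preln", "post_eln", "post_iln",
                                  "preln_multichannel"))
  target <- as_signal_matrix(target)
  R <- attr(osn_spikes, "R") %||% max(osn_spikes$channel)
  n <- ncol(target)
  if (pathway %in% c("post_eln", "post_iln") && nrow(target) != 1 && R == 1)
    abort("single-channel pathway target must be one channel")
  deltas <- spikes_to_deltas(osn_spikes, R, n, dt)
  if (!is.null(mask)) {
    if (length(mask) != n) abort("mask length must match the target")
    target[, !mask] <- 0
  }
  structure(list(pathway = pathway, target = target, osn_delta = deltas,
                 mask = mask,
                 variant = if (pathway %in% c("post_eln", "post_iln")) "none"
                           else variant,
                 dt = dt, constraint_cap = constraint_cap,
                 smooth_s = smooth_s, base_theta = base_theta,
                 stimulus = stimulus, R = R),
            class = "al_objective")
}

sub_theta <- function(spec, theta_sub) {
  th <- spec$base_theta
  blk <- pathway_block(spec$pathway)
  th[[blk]] <- setNames(as.numeric(theta_sub), pathway_names(spec$pathway))
  th
}

#' Evaluate a pathway objective at one parameter vector
#'
#' Simulates the pathway (noise-free), extracts the model PN-input current
#' component, and returns the angular distance to the target together with
#' the maximum axon-terminal gating. Simulation failures yield the worst
#' objective 1 with an error flag instead of an exception so population
#' methods can continue.
#'
#' @param spec an [objective_spec()]
#' @param theta_sub parameter vector for the fitted block (length 7 for
#'   Pre-LN, 8 for Post-LN pathways)
#' @return tibble row: `objective`, `max_gating`, `feasible`, `error`
#' @export
eval_objective <- function(spec, theta_sub) {
  res <- tryCatch({
    th <- sub_theta(spec, theta_sub)
    sim <- simulate_pathway(spec$pathway, th, spec$osn_delta, spec$variant,
                            spec$dt)
    I <- sim$I
    if (spec$smooth_s > 0) {
      half <- round(spec$smooth_s / spec$dt)
      I <- t(apply(I, 1, cpp_boxcar, half = half))
    }
    if (!is.null(spec$mask)) I[, !spec$mask] <- 0
    if (any(!is.finite(I))) stop("non-finite current")
    obj <- if (l2_norm(I) == 0) 1 else angular_distance(spec$target, I)
    # the saturation cap applies to the Pre-LN objectives only (the Post-LN
    # pathway simulations run without presynaptic inhibition, so their
    # uninhibited terminal gating is not a fitted quantity)
    constrained <- spec$pathway %in% c("preln", "preln_multichannel")
    tibble(objective = obj, max_gating = sim$max_gating,
           feasible = !constrained || sim$max_gating <= spec$constraint_cap,
           error = FALSE)
  }, error = function(e) {
    tibble(objective = 1, max_gating = NA_real_, feasible = FALSE,
           error = TRUE)
  })
  res
}

#' Latin-Hypercube screening sample
#'
#' The simplified correlation-screened procedure: draw N x D uniform samples
#' per dimension, estimate the average absolute pairwise correlation between
#' K randomly chosen rows, repeat `iters` times and keep the matrix with the
#' lowest correlation.
#'
#' @param D dimensionality
#' @param N number of samples
#' @param bounds length-2 vector or D x 2 matrix of per-dimension bounds;
#'   default \[1, 1e6\]
#' @param K rows used in the correlation estimate (capped at N)
#' @param iters repeats
#' @param seed integer seed
#' @return N x D matrix with attributes `rho` (selected correlation), `seed`,
#'   `method`
#' @export
lhs_sample <- function(D, N, bounds = c(1, 1e6), K = 1000, iters = 10,
                       seed = 1L) {
  if (iters < 1 || N < 2) abort("need N >= 2 and iters >= 1")
  K <- max(2L, min(K, N))
  if (is.null(dim(bounds))) bounds <- matrix(bounds, D, 2, byrow = TRUE)
  local_seed(seed, {
    best <- NULL; best_rho <- Inf
    for (i in seq_len(iters)) {
      X <- vapply(seq_len(D), function(d)
        runif(N, bounds[d, 1], bounds[d, 2]), numeric(N))
      rows <- sample.int(N, K)
      cm <- suppressWarnings(cor(t(X[rows, , drop = FALSE])))
      rho <- mean(abs(cm[upper.tri(cm)]), na.rm = TRUE)
      if (rho < best_rho) { best <- X; best_rho <- rho }
    }
    attr(best, "rho") <- best_rho
    attr(best, "seed") <- seed
    attr(best, "method") <- "correlation-screened uniform LHS"
    best
  })
}

# average absolute pairwise row correlation (used by tests as a re-check)
lhs_rho <- function(X) {
  cm <- suppressWarnings(cor(t(X)))
  mean(abs(cm[upper.tri(cm)]), na.rm = TRUE)
}

#' Differential-Evolution refinement inside the top-sample hypercube
#'
#' Builds the per-dimension \[mean - sd, mean + sd\] hypercube of the top
#' screened samples (clipped to the global bounds, widened if degenerate)
#' and runs elitist best/1/bin Differential Evolution with dithered mutation
#' in \[0.5, 1\] and crossover 0.7. Infeasible candidates are kept in the
#' record but never outrank a feasible one.
#'
#' @param objective function(theta) returning a row like [eval_objective()]
#' @param top_samples matrix of top parameter vectors (>= 2 rows)
#' @param bounds global bounds (length-2 or D x 2)
#' @param generations,popsize DE budget
#' @param seed integer seed
#' @return list: `best_par`, `best` (objective row), `history` tibble
#' @export
de_refine <- function(objective, top_samples, bounds = c(1, 1e6),
                      generations = 20, popsize = 15, seed = 1L) {
  top_samples <- as.matrix(top_samples)
  if (nrow(top_samples) < 2) abort("need at least 2 top samples")
  D <- ncol(top_samples)
  if (is.null(dim(bounds))) bounds <- matrix(bounds, D, 2, byrow = TRUE)
  mu <- colMeans(top_samples)
  sg <- apply(top_samples, 2, sd)
  degen <- sg == 0
  if (any(degen)) {
    warn("degenerate hypercube dimension; widening by epsilon")
    sg[degen] <- 1e-6 * (bounds[degen, 2] - bounds[degen, 1])
  }
  lo <- pmax(mu - sg, bounds[, 1]); hi <- pmin(mu + sg, bounds[, 2])
  key <- function(row) row$objective + 10 * (!isTRUE(row$feasible))
  local_seed(seed, {
    pop <- t(vapply(seq_len(popsize), function(i) runif(D, lo, hi),
                    numeric(D)))
    pop[1, ] <- pmin(pmax(top_samples[1, ], lo), hi)  # seed with the best
    evals <- purrr::map(seq_len(popsize), ~ objective(pop[.x, ]))
    keys <- purrr::map_dbl(evals, key)
    hist_rows <- list()
    for (g in seq_len(generations)) {
      Fg <- runif(1, 0.5, 1)
      b <- which.min(keys)
      for (i in seq_len(popsize)) {
        idx <- sample(setdiff(seq_len(popsize), i), 2)
        mutant <- pop[b, ] + Fg * (pop[idx[1], ] - pop[idx[2], ])
        mutant <- pmin(pmax(mutant, lo), hi)
        cross <- runif(D) < 0.7
        cross[sample.int(D, 1)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        ev <- objective(trial)
        if (key(ev) <= keys[i]) {
          pop[i, ] <- trial; evals[[i]] <- ev; keys[i] <- key(ev)
        }
        hist_rows[[length(hist_rows) + 1]] <-
          mutate(ev, generation = g, member = i)
      }
    }
    b <- which.min(keys)
    list(best_par = pop[b, ], best = evals[[b]],
         history = dplyr::bind_rows(hist_rows))
  })
}

#' Desk-scale budget for the two-step fit
#'
#' The full-scale budget of the original procedure (1e5 Latin-Hypercube
#' samples, top-100, long DE runs) takes hours; the desk profile keeps the
#' procedure identical at a budget that runs in seconds to minutes.
#' @param n_lhs LHS screening samples
#' @param top_k top samples defining the DE hypercube
#' @param de_generations,de_popsize DE budget
#' @param lhs_K,lhs_iters correlation-screen settings
#' @export
fit_budget <- function(n_lhs = 500, top_k = 20, de_generations = 20,
                       de_popsize = 15, lhs_K = 1000, lhs_iters = 5) {
  list(n_lhs = n_lhs, top_k = top_k, de_generations = de_generations,
       de_popsize = de_popsize, lhs_K = lhs_K, lhs_iters = lhs_iters)
}

#' Two-step LHS + Differential-Evolution pathway fit
#'
#' Step 1 screens the parameter box with the correlation-screened LHS and
#' ranks feasible samples by objective (ties broken by sample index); step 2
#' refines inside the top-sample hypercube with DE. If no feasible sample is
#' found the best infeasible result is returned with
#' `constraint_satisfied = FALSE`.
#'
#' @param spec an [objective_spec()]
#' @param budget a [fit_budget()]
#' @param seed integer seed controlling both steps
#' @return an `al_fit` object; see [tidy.al_fit()] and [glance.al_fit()]
#' @export
two_step_fit <- function(spec, budget = fit_budget(), seed = 1L) {
  D <- length(pathway_names(spec$pathway))
  bounds <- spec$base_theta$bounds
  X <- lhs_sample(D, budget$n_lhs, bounds, K = budget$lhs_K,
                  iters = budget$lhs_iters, seed = seed)
  screen <- purrr::map_dfr(seq_len(nrow(X)), function(i)
    mutate(eval_objective(spec, X[i, ]), sample = i))
  # feasibility-first ranking: constraint-satisfying samples outrank any
  # violating one; ties broken by objective then sample index
  pool <- screen[order(!screen$feasible, screen$objective, screen$sample), ]
  top <- head(pool, max(2, budget$top_k))
  de <- de_refine(function(th) eval_objective(spec, th),
                  X[top$sample, , drop = FALSE], bounds,
                  generations = budget$de_generations,
                  popsize = budget$de_popsize, seed = seed + 1L)
  # the DE result is elitist within its run; keep the screening winner if it
  # is still better
  best_screen <- top[1, ]
  use_de <- (de$best$objective + 10 * !de$best$feasible) <=
    (best_screen$objective + 10 * !best_screen$feasible)
  best_par <- if (use_de) de$best_par else X[best_screen$sample, ]
  best <- if (use_de) de$best else
    best_screen[, c("objective", "max_gating", "feasible", "error")]
  structure(list(
    pathway = spec$pathway, spec = spec,
    best_theta = setNames(as.numeric(best_par), pathway_names(spec$pathway)),
    best_objective = best$objective,
    max_gating = best$max_gating,
    constraint_satisfied = isTRUE(best$feasible),
    screen = screen, de_history = de$history,
    budget = budget, seed = seed
  ), class = "al_fit")
}

#' @export
print.al_fit <- function(x, ...) {
  cat("<al_fit> pathway:", x$pathway, "\n")
  cat("  best objective (angular distance):", signif(x$best_objective, 4),
      "\n")
  cat("  max axon-terminal gating:", signif(x$max_gating, 4),
      if (x$constraint_satisfied) "(constraint satisfied)" else
        "(CONSTRAINT VIOLATED)", "\n")
  invisible(x)
}

#' Tidy the fitted parameters of a pathway fit
#' @param x an `al_fit`
#' @param ... unused
#' @export
tidy.al_fit <- function(x, ...) {
  tibble(term = names(x$best_theta), estimate = as.numeric(x$best_theta))
}

#' One-row summary of a pathway fit
#' @param x an `al_fit`
#' @param ... unused
#' @export
glance.al_fit <- function(x, ...) {
  tibble(pathway = x$pathway, objective = x$best_objective,
         max_gating = x$max_gating,
         constraint_satisfied = x$constraint_satisfied,
         n_screen = nrow(x$screen),
         n_de = nrow(x$de_history))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
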