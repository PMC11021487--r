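#' Annealing configuration
#'
#' Controls the simulated-annealing search for the unknown boundary
#' pressures. Defaults that depend on the problem (`NULL` here) are
#' resolved against the network and boundary conditions when a run starts:
#' `initial_temperature` defaults to half the number of observed segments
#' (the error is a mismatch count, so T starts at the scale of a
#' substantial error), `cooling` to the geometric factor giving
#' `T(iterations) = 1e-3 T0`, `proposal_scale` to the width of
#' `pressure_bounds`, and `pressure_bounds` to the interval between the
#' reference pressure `P_v` and the inlet pressure (FOV-edge pressures
#' physically lie between the two).
#'
#' @param iterations_per_run Boundary-pressure updates per run (default
#'   5000).
#' @param restarts Independent runs from fresh random initial guesses
#'   (default 100).
#' @param initial_temperature Starting pseudo temperature, same units as
#'   the error.
#' @param cooling Geometric decay factor per iteration, in (0, 1).
#' @param proposal_scale Pressure-perturbation scale, Pa; each proposal
#'   perturbs every unknown pressure by a heavy-tailed increment of scale
#'   `proposal_scale x E / n_observed`, so steps shrink as the fit
#'   improves (see [propose_boundary_pressures()]).
#' @param weighting Error weighting: `"unweighted"` (mismatch count),
#'   `"flow"` (each mismatch weighted by its |normalized flow|),
#'   `"diameter"` (by diameter in micrometres), or `"flow_and_diameter"`.
#' @param pressure_bounds Length-2 numeric `[low, high]`, Pa; proposals and
#'   initial guesses are confined to this interval.
#' @param seed Master RNG seed for [run_ensemble()].
#' @return An object of class `vasc_anneal_config`.
#' @export
annealing_config <- function(iterations_per_run = 5000, restarts = 100,
                             initial_temperature = NULL, cooling = NULL,
                             proposal_scale = NULL,
                             weighting = c("unweighted", "flow", "diameter",
                                           "flow_and_diameter"),
                             pressure_bounds = NULL, seed = 1L) {
  weighting <- match.arg(weighting)
  if (iterations_per_run < 1) abort("iterations_per_run must be >= 1")
  if (restarts < 1) abort("restarts must be >= 1")
  if (!is.null(cooling) && (cooling <= 0 || cooling >= 1)) {
    abort("cooling must lie strictly between 0 and 1")
  }
  if (!is.null(pressure_bounds)) {
    if (length(pressure_bounds) != 2 ||
        pressure_bounds[1] >= pressure_bounds[2]) {
      abort("pressure_bounds must be c(low, high) with low < high")
    }
  }
  structure(
    list(
      iterations_per_run = as.integer(iterations_per_run),
      restarts = as.integer(restarts),
      initial_temperature = initial_temperature,
      cooling = cooling,
      proposal_scale = proposal_scale,
      weighting = weighting,
      pressure_bounds = pressure_bounds,
      seed = as.integer(seed)
    ),
    class = "vasc_anneal_config"
  )
}

resolve_annealing_config <- function(config, bc, n_observed) {
  if (is.null(config$pressure_bounds)) {
    config$pressure_bounds <- sort(c(bc$venous_pressure, bc$inlet_pressure))
    if (config$pressure_bounds[1] == config$pressure_bounds[2]) {
      abort("cannot derive pressure_bounds: P_v equals inlet pressure")
    }
  }
  if (is.null(config$initial_temperature)) {
    config$initial_temperature <- max(n_observed / 2, .Machine$double.eps)
  }
  if (is.null(config$cooling)) {
    config$cooling <- 1e-3^(1 / config$iterations_per_run)
  }
  if (is.null(config$proposal_scale)) {
    config$proposal_scale <- diff(config$pressure_bounds)
  }
  config
}

#' Flow-direction error of a solved state
#'
#' The error E counts segments whose computed flow direction differs from
#' the experimentally observed one; segments with no observation
#' (`observed_direction = 0`) contribute nothing. Weighted variants
#' multiply each mismatch by the segment's |normalized flow|, its diameter
#' in micrometres, or their product.
#'
#' @param state A `vasc_state` solved on `network`.
#' @param network The `vasc_network` carrying `observed_direction`.
#' @param weighting One of `"unweighted"`, `"flow"`, `"diameter"`,
#'   `"flow_and_diameter"`.
#' @return Non-negative scalar E.
#' @export
direction_error <- function(state, network, weighting = "unweighted") {
  obs <- network$segments$observed_direction
  keep <- obs != 0L
  mism <- state$flows$direction[keep] != obs[keep]
  w <- switch(weighting,
    unweighted = rep(1, sum(keep)),
    flow = abs(state$flows$flow_normalized[keep]),
    diameter = m_to_um(network$segments$diameter[keep]),
    flow_and_diameter = abs(state$flows$flow_normalized[keep]) *
      m_to_um(network$segments$diameter[keep]),
    abort(paste0("unknown weighting: ", weighting))
  )
  sum(w[mism])
}

# fast internal error: precomputed observed subset and weights
fast_error <- function(flows, tol, obs_idx, obs_dir, weights, flow_weighted,
                       qref_idx) {
  d <- flow_direction(flows[obs_idx], tol)
  mism <- d != obs_dir
  if (flow_weighted) {
    qref <- abs(flows[qref_idx])
    if (qref == 0) qref <- .Machine$double.eps
    w <- weights * abs(1000 * flows[obs_idx] / qref)
    sum(w[mism])
  } else {
    sum(weights[mism])
  }
}

#' Propose a new set of unknown boundary pressures
#'
#' Every unknown pressure is perturbed by an independent heavy-tailed
#' (Cauchy) increment whose scale parameter is
#' `proposal_scale x E / n_observed`, then clipped to the pressure bounds:
#' the worse the current fit, the larger the typical step, while the
#' Cauchy tail still yields occasional long jumps that let the chain
#' escape single-segment local minima late in the cooling schedule. At
#' E = 0 the proposal equals the current point. The inlet pressure is
#' never part of the proposal.
#'
#' @param current Named numeric vector of current unknown boundary
#'   pressures, Pa.
#' @param error Current error E.
#' @param n_observed Number of segments with observed directions.
#' @param config A resolved [annealing_config()] (explicit
#'   `proposal_scale` and `pressure_bounds`).
#' @return Named numeric candidate vector, within bounds.
#' @export
propose_boundary_pressures <- function(current, error, n_observed, config) {
  if (is.null(config$proposal_scale) || is.null(config$pressure_bounds)) {
    abort("config must carry explicit proposal_scale and pressure_bounds")
  }
  s <- config$proposal_scale * error / max(n_observed, 1)
  if (s == 0) return(current)
  cand <- current + stats::rcauchy(length(current), scale = s)
  pmin(pmax(cand, config$pressure_bounds[1]), config$pressure_bounds[2])
}

#' One simulated-annealing run
#'
#' Starting from a uniform random guess of the unknown boundary pressures
#' within the bounds, performs `iterations_per_run` updates. Each update
#' proposes perturbed pressures ([propose_boundary_pressures()]), solves
#' the flow field, and evaluates the direction error E. Improvements
#' (including ties) are always accepted; a worsening of `dE` is accepted
#' with probability `exp(-dE / T)`, with T following geometric cooling
#' `T(n) = T0 cooling^n`. The best pressures seen are retained.
#'
#' @param network A `vasc_network` with at least one observed direction.
#' @param bc A `vasc_bc`; its `inlet_pressure` is held fixed.
#' @param config An [annealing_config()].
#' @param seed RNG seed for this run.
#' @param keep_trace Keep the full per-iteration trace (default `TRUE`)?
#' @param context Optional precomputed solver context (internal reuse).
#' @return An object of class `vasc_anneal`: `trace` tibble (`iteration`,
#'   `error`, `temperature`, `accepted`), `best_error`,
#'   `best_boundary_pressures` (named), `n_observed` and the resolved
#'   config.
#' @export
anneal_run <- function(network, bc, config = annealing_config(), seed = 1L,
                       keep_trace = TRUE, context = NULL) {
  ctx <- context %||% build_solver_context(network, bc, fluid_parameters())
  segs <- network$segments
  obs_idx <- which(segs$observed_direction != 0L)
  if (length(obs_idx) == 0) {
    abort("configuration error: no segment has an observed flow direction")
  }
  config <- resolve_annealing_config(config, bc, length(obs_idx))
  obs_dir <- segs$observed_direction[obs_idx]
  qref_idx <- which.max(segs$diameter)
  flow_weighted <- config$weighting %in% c("flow", "flow_and_diameter")
  weights <- switch(config$weighting,
    unweighted = rep(1, length(obs_idx)),
    flow = rep(1, length(obs_idx)),
    diameter = m_to_um(segs$diameter[obs_idx]),
    flow_and_diameter = m_to_um(segs$diameter[obs_idx])
  )
  unknown_bnd <- boundary_nodes(network)
  fixed_nodes <- ctx$sys$fixed_nodes
  free_cols <- match(unknown_bnd, fixed_nodes)
  p_fixed <- ctx$sys$fixed
  p_fixed[fixed_nodes == bc$inlet_node] <- bc$inlet_pressure

  set.seed(seed)
  lo <- config$pressure_bounds[1]; hi <- config$pressure_bounds[2]
  cur <- setNames(runif(length(unknown_bnd), lo, hi), unknown_bnd)
  # stagnation tolerance on the raw-flow scale, tied to the trunk flow of
  # the initial solve (kept fixed within the run so E is well defined)
  p_fixed[free_cols] <- cur
  sol <- context_solve(ctx, p_fixed)
  tol <- 1e-6 * abs(sol$flows[qref_idx])
  e_cur <- fast_error(sol$flows, tol, obs_idx, obs_dir, weights,
                      flow_weighted, qref_idx)
  best_e <- e_cur
  best_p <- cur
  n_it <- config$iterations_per_run
  tr_error <- numeric(n_it); tr_temp <- numeric(n_it)
  tr_acc <- logical(n_it)
  temp <- config$initial_temperature
  for (n in seq_len(n_it)) {
    temp <- config$initial_temperature * config$cooling^n
    if (e_cur == 0) {
      # proposals have zero magnitude at E = 0: the chain is stationary
      tr_error[n] <- 0; tr_temp[n] <- temp; tr_acc[n] <- TRUE
      next
    }
    cand <- propose_boundary_pressures(cur, e_cur, length(obs_idx), config)
    p_fixed[free_cols] <- cand
    sol <- context_solve(ctx, p_fixed)
    e_cand <- fast_error(sol$flows, tol, obs_idx, obs_dir, weights,
                         flow_weighted, qref_idx)
    de <- e_cand - e_cur
    accept <- de <= 0 || runif(1) < exp(-de / temp)
    if (accept) {
      cur <- cand
      e_cur <- e_cand
      if (e_cur < best_e) {
        best_e <- e_cur
        best_p <- cur
      }
    }
    tr_error[n] <- e_cur; tr_temp[n] <- temp; tr_acc[n] <- accept
  }
  structure(
    list(
      trace = if (keep_trace) {
        tibble(iteration = seq_len(n_it), error = tr_error,
               temperature = tr_temp, accepted = tr_acc)
      } else {
        NULL
      },
      best_error = best_e,
      best_boundary_pressures = best_p,
      n_observed = length(obs_idx),
      config = config,
      seed = seed
    ),
    class = "vasc_anneal"
  )
}

#' @export
print.vasc_anneal <- function(x, ...) {
  cat(sprintf(
    "<vasc_anneal: %d iterations, best error %.4g on %d observed segments>\n",
    x$config$iterations_per_run, x$best_error, x$n_observed
  ))
  invisible(x)
}

#' Tidy an annealing trace
#'
#' @param x A `vasc_anneal`.
#' @param ... Unused.
#' @return The per-iteration trace tibble.
#' @method tidy vasc_anneal
#' @export
tidy.vasc_anneal <- function(x, ...) {
  x$trace %||% abort("run was performed with keep_trace = FALSE")
}

#' @method glance vasc_anneal
#' @export
glance.vasc_anneal <- function(x, ...) {
  tibble(best_error = x$best_error, n_observed = x$n_observed,
         iterations = x$config$iterations_per_run, seed = x$seed)
}

#' Restart ensemble of annealing runs
#'
#' Repeats the whole annealing optimization `restarts` times from fresh
#' random initial pressures (independent RNG substreams derived from the
#' master seed). Each restart contributes the normalized flow field of its
#' best boundary pressures; per-segment statistics over the ensemble
#' quantify how strongly the observations constrain each vessel. Because
#' the optimization is stochastic, the spread of a segment's flow across
#' restarts measures its sensitivity to distant pressure changes — high
#' spread flags collateral-capable vessels.
#'
#' @inheritParams anneal_run
#' @return An object of class `vasc_ensemble`: `stats` tibble per segment
#'   (`flow_mean`, `flow_sd`, `uncertainty_index` = SD/|mean| with an `Inf`
#'   sentinel for stagnant means, `direction_consistency`,
#'   `modal_direction`), the restarts-by-segments `samples` matrix of
#'   normalized flows, per-restart `best_errors`, and the resolved config.
#' @export
run_ensemble <- function(network, bc, config = annealing_config(),
                         context = NULL) {
  ctx <- context %||% build_solver_context(network, bc, fluid_parameters())
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$restarts)
  segs <- network$segments
  qref_idx <- which.max(segs$diameter)
  ref_id <- segs$segment_id[qref_idx]
  n_seg <- nrow(segs)
  samples <- matrix(NA_real_, nrow = config$restarts, ncol = n_seg,
                    dimnames = list(NULL, segs$segment_id))
  best_errors <- numeric(config$restarts)
  boundary_sets <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    run <- anneal_run(network, bc, config, seed = seeds[r],
                      keep_trace = FALSE, context = ctx)
    best_errors[r] <- run$best_error
    boundary_sets[[r]] <- run$best_boundary_pressures
    p_fixed <- ctx$sys$fixed
    p_fixed[names(run$best_boundary_pressures)] <-
      run$best_boundary_pressures
    p_fixed[ctx$sys$fixed_nodes == bc$inlet_node] <- bc$inlet_pressure
    sol <- context_solve(ctx, p_fixed)
    qref <- abs(sol$flows[qref_idx])
    samples[r, ] <- if (qref > 0) 1000 * (sol$flows / qref) else sol$flows
  }
  stag_tol <- 1e-3 # normalized units: 1e-6 x the reference value of 1000
  dirs <- apply(samples, 2, flow_direction,
                stagnation_tolerance = stag_tol)
  if (is.null(dim(dirs))) dirs <- matrix(dirs, nrow = config$restarts)
  modal <- integer(n_seg); consist <- numeric(n_seg)
  for (s in seq_len(n_seg)) {
    counts <- table(factor(dirs[, s], levels = c(-1, 0, 1)))
    modal[s] <- as.integer(names(counts)[which.max(counts)])
    consist[s] <- max(counts) / config$restarts
  }
  mu <- colMeans(samples)
  sdev <- apply(samples, 2, function(x) if (length(x) > 1) sd(x) else 0)
  sdev[is.na(sdev)] <- 0
  # sd = 0 means the ensemble pins the flow exactly (index 0); otherwise a
  # stagnant mean with nonzero spread gets the Inf sentinel
  ui <- ifelse(sdev == 0, 0, ifelse(abs(mu) <= stag_tol, Inf, sdev / abs(mu)))
  structure(
    list(
      stats = tibble(
        segment_id = segs$segment_id,
        vessel_class = segs$vessel_class,
        diameter_um = m_to_um(segs$diameter),
        observed_direction = segs$observed_direction,
        flow_mean = unname(mu),
        flow_sd = unname(sdev),
        uncertainty_index = unname(ui),
        direction_consistency = unname(consist),
        modal_direction = modal
      ),
      samples = samples,
      best_errors = best_errors,
      boundary_pressures = boundary_sets,
      reference_segment = ref_id,
      stagnation_tolerance = stag_tol,
      config = config,
      seeds = seeds
    ),
    class = "vasc_ensemble"
  )
}

#' @export
print.vasc_ensemble <- function(x, ...) {
  cat(sprintf(
    "<vasc_ensemble: %d restarts x %d segments, %.0f%% of runs at E = 0>\n",
    nrow(x$samples), ncol(x$samples), 100 * mean(x$best_errors == 0)
  ))
  invisible(x)
}

#' Per-segment relative flow uncertainty
#'
#' The uncertainty index is the standard deviation of a segment's
#' normalized flow across annealing restarts divided by the magnitude of
#' its mean. Segments whose mean flow is below the stagnation tolerance
#' receive an `Inf` sentinel and rank above every finite index: their
#' direction is entirely unconstrained by the observations.
#'
#' @param ensemble A `vasc_ensemble`.
#' @return A tibble `segment_id`, `uncertainty_index`.
#' @export
uncertainty_index <- function(ensemble) {
  ensemble$stats |> select("segment_id", "uncertainty_index")
}

#' Tidy an annealing ensemble
#'
#' @param x A `vasc_ensemble`.
#' @param ... Unused.
#' @return The per-segment statistics tibble.
#' @method tidy vasc_ensemble
#' @export
tidy.vasc_ensemble <- function(x, ...) x$stats

#' One-row ensemble summary
#'
#' @param x A `vasc_ensemble`.
#' @param ... Unused.
#' @return A tibble with restart count, fraction of restarts reaching
#'   E = 0, and the median best error.
#' @method glance vasc_ensemble
#' @export
glance.vasc_ensemble <- function(x, ...) {
  tibble(
    restarts = nrow(x$samples),
    n_segments = ncol(x$samples),
    frac_zero_error = mean(x$best_errors == 0),
    median_best_error = median(x$best_errors),
    reference_segment = x$reference_segment
  )
}
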