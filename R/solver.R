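#' Fluid parameters
#'
#' Blood is treated as a Newtonian fluid in steady laminar flow; the only
#' parameter is the dynamic viscosity, default 3 cP (3e-3 Pa s), a standard
#' effective value for blood in microvessels.
#'
#' @param viscosity Dynamic viscosity in Pa s; must be positive.
#' @return An object of class `vasc_fluid`.
#' @export
fluid_parameters <- function(viscosity = 3e-3) {
  if (!is.numeric(viscosity) || length(viscosity) != 1 || viscosity <= 0) {
    abort("viscosity must be a single positive number (Pa s)")
  }
  structure(list(viscosity = viscosity), class = "vasc_fluid")
}

#' Poiseuille resistance of a cylindrical segment
#'
#' For steady laminar flow of a Newtonian fluid in a cylinder,
#' R = 128 L mu / (pi D^4). All arguments SI.
#'
#' @param length Segment length, m.
#' @param diameter Inner diameter, m.
#' @param viscosity Dynamic viscosity, Pa s (default 3 cP).
#' @return Resistance in Pa s m^-3. Vectorized over arguments.
#' @export
#' @examples
#' segment_resistance(100e-6, 10e-6) # ~1.22e15 Pa s m^-3
segment_resistance <- function(length, diameter, viscosity = 3e-3) {
  if (any(length <= 0) || any(diameter <= 0) || any(viscosity <= 0)) {
    abort("length, diameter and viscosity must all be positive")
  }
  128 * length * viscosity / (pi * diameter^4)
}

#' Boundary conditions for a network solve
#'
#' The pressure problem is closed by: one known pressure at the largest
#' vessel entering the field of view (the inlet); pressures at every other
#' boundary crossing (unknown a priori, estimated by [run_ensemble()] or
#' supplied as guesses); and a lumped terminal pathway of resistance `R_TA`
#' from each node through the capillary bed to a constant reference
#' pressure `P_v`.
#'
#' @param inlet_node Node id of the known-pressure inlet (a boundary node).
#' @param inlet_pressure Pressure at the inlet, Pa. Never altered by the
#'   annealer.
#' @param venous_pressure Reference pressure `P_v`, Pa. For an arterial
#'   network this is the downstream venous compartment; for a venous
#'   network the same term acts as a distributed inflow from the capillary
#'   bed, with `P_v` an upstream capillary pressure above the vein
#'   pressures.
#' @param terminal_resistance `R_TA`, Pa s m^-3; positive, may be `Inf`
#'   (no terminal leak).
#' @param boundary_pressures Named numeric vector, Pa: one entry per
#'   non-inlet boundary node. May be `NULL` when the values are to be
#'   estimated.
#' @param leak Where the terminal pathway attaches: `"all"` (every
#'   non-boundary node; the default, the literal reading of the nodal
#'   balance), `"terminal_only"` (only nodes of kind `terminal`), or
#'   `"none"` (equivalent to `R_TA = Inf`).
#' @return An object of class `vasc_bc`.
#' @export
boundary_conditions <- function(inlet_node, inlet_pressure, venous_pressure,
                                terminal_resistance,
                                boundary_pressures = NULL,
                                leak = c("all", "terminal_only", "none")) {
  leak <- match.arg(leak)
  if (terminal_resistance <= 0) abort("terminal_resistance must be positive")
  if (!is.null(boundary_pressures) &&
      (is.null(names(boundary_pressures)) ||
       any(!nzchar(names(boundary_pressures))))) {
    abort("boundary_pressures must be a fully named numeric vector")
  }
  structure(
    list(
      inlet_node = as.character(inlet_node),
      inlet_pressure = as.numeric(inlet_pressure),
      venous_pressure = as.numeric(venous_pressure),
      terminal_resistance = as.numeric(terminal_resistance),
      boundary_pressures = boundary_pressures,
      leak = leak
    ),
    class = "vasc_bc"
  )
}

#' Default boundary conditions for a network
#'
#' Convenience constructor: inlet at the flagged known-inlet node,
#' `R_TA = 100 x` the median segment resistance (so terminal leak stays
#' small relative to through-flow), `P_v = 0` gauge, and unknown boundary
#' pressures initialized at the midpoint between `P_v` and the inlet
#' pressure. Studies should set these deliberately; the defaults make
#' exploratory use possible.
#'
#' @param network A `vasc_network`.
#' @param inlet_pressure Inlet pressure, Pa.
#' @param venous_pressure Reference pressure, Pa.
#' @param terminal_resistance `R_TA`; default 100 x median segment
#'   resistance.
#' @param viscosity Viscosity used for the median-resistance default.
#' @inheritParams boundary_conditions
#' @return A `vasc_bc`.
#' @export
default_boundary_conditions <- function(network, inlet_pressure = 8000,
                                        venous_pressure = 0,
                                        terminal_resistance = NULL,
                                        viscosity = 3e-3,
                                        leak = "all") {
  inlet <- network$nodes$node_id[network$nodes$is_known_inlet]
  if (length(inlet) != 1) abort("network must flag exactly one known inlet")
  if (is.null(terminal_resistance)) {
    r <- segment_resistance(network$segments$length,
                            network$segments$diameter, viscosity)
    terminal_resistance <- 100 * median(r)
  }
  unknown <- boundary_nodes(network)
  guess <- rep((inlet_pressure + venous_pressure) / 2, length(unknown))
  boundary_conditions(
    inlet_node = inlet, inlet_pressure = inlet_pressure,
    venous_pressure = venous_pressure,
    terminal_resistance = terminal_resistance,
    boundary_pressures = setNames(guess, unknown),
    leak = leak
  )
}

#' Assemble the nodal mass-conservation linear system
#'
#' One equation per non-boundary node i:
#' (P_i - P_v)/R_TA + sum_j (P_i - P_j)/R_ij = 0,
#' with boundary pressures moved to the right-hand side. The matrix is
#' symmetric positive definite (strictly diagonally dominant whenever the
#' leak conductance is nonzero).
#'
#' @param network A valid `vasc_network`.
#' @param bc A `vasc_bc` with a pressure for every non-inlet boundary node.
#' @param fluid A `vasc_fluid`.
#' @return A list with the sparse matrix `A`, right-hand side `b`, the
#'   unknown-node ordering `unknown_nodes`, fixed pressures `fixed`, the
#'   boundary-coupling matrix `B` (so that `b = b_leak + B %*% p_fixed`),
#'   per-segment conductances and index maps.
#' @export
assemble_system <- function(network, bc, fluid = fluid_parameters()) {
  nodes <- network$nodes
  segs <- network$segments
  fixed_ids <- nodes$node_id[nodes$kind == "boundary"]
  unknown_ids <- nodes$node_id[nodes$kind != "boundary"]

  p_fixed <- setNames(rep(NA_real_, length(fixed_ids)), fixed_ids)
  p_fixed[bc$inlet_node] <- bc$inlet_pressure
  if (!is.null(bc$boundary_pressures)) {
    known <- intersect(names(bc$boundary_pressures), fixed_ids)
    p_fixed[known] <- bc$boundary_pressures[known]
  }
  if (anyNA(p_fixed)) {
    abort(paste0("assembly error: no pressure assigned to boundary node(s) ",
                 toString(names(p_fixed)[is.na(p_fixed)])))
  }

  res <- segment_resistance(segs$length, segs$diameter, fluid$viscosity)
  g <- 1 / res
  nu <- length(unknown_ids)
  ui <- match(segs$node_a, unknown_ids) # NA when endpoint is fixed
  uj <- match(segs$node_b, unknown_ids)
  fi <- match(segs$node_a, fixed_ids)
  fj <- match(segs$node_b, fixed_ids)

  # leak conductance per unknown node
  g_leak <- rep(0, nu)
  if (bc$leak != "none" && is.finite(bc$terminal_resistance)) {
    gl <- 1 / bc$terminal_resistance
    if (bc$leak == "all") {
      g_leak[] <- gl
    } else {
      g_leak[nodes$kind[match(unknown_ids, nodes$node_id)] == "terminal"] <- gl
    }
  }

  # diagonal: all incident conductances + leak
  diag_val <- g_leak
  both <- !is.na(ui)
  diag_val <- diag_val +
    vapply(seq_len(nu), function(k) sum(g[which(ui == k | uj == k)]),
           numeric(1))
  # off-diagonal: -g for segments with both endpoints unknown
  off <- which(!is.na(ui) & !is.na(uj))
  A <- Matrix::sparseMatrix(
    i = c(seq_len(nu), ui[off], uj[off]),
    j = c(seq_len(nu), uj[off], ui[off]),
    x = c(diag_val, -g[off], -g[off]),
    dims = c(nu, nu)
  )
  # coupling to fixed nodes: B[i, f] = sum of g over segments joining them
  bi <- which(!is.na(ui) & !is.na(fj))
  bj <- which(!is.na(uj) & !is.na(fi))
  B <- Matrix::sparseMatrix(
    i = c(ui[bi], uj[bj]), j = c(fj[bi], fi[bj]), x = c(g[bi], g[bj]),
    dims = c(nu, length(fixed_ids))
  )
  b_leak <- g_leak * bc$venous_pressure
  list(
    A = A, B = B, b_leak = b_leak,
    b = b_leak + as.numeric(B %*% p_fixed),
    unknown_nodes = unknown_ids, fixed_nodes = fixed_ids, fixed = p_fixed,
    conductance = g, resistance = res, g_leak = g_leak,
    seg_a = match(segs$node_a, nodes$node_id),
    seg_b = match(segs$node_b, nodes$node_id)
  )
}

# Precomputed affine solve map: the matrix A is fixed by geometry, so the
# solution is affine in the fixed boundary pressures,
#   P_unknown = p0 + M p_fixed,
# with M = A^-1 B computed once by sparse Cholesky. The annealer exploits
# this: each of its iterations is a dense (n_unknown x n_boundary)
# matrix-vector product, not a fresh factorization.
build_solver_context <- function(network, bc, fluid = fluid_parameters()) {
  sys <- assemble_system(network, bc, fluid)
  nu <- length(sys$unknown_nodes)
  if (nu > 0) {
    ch <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(sys$A), LDL = FALSE),
      error = function(e) {
        abort(paste0(
          "singular nodal system: with R_TA = Inf every connected component ",
          "needs at least 2 boundary nodes (", conditionMessage(e), ")"
        ))
      }
    )
    M <- as.matrix(Matrix::solve(ch, sys$B, system = "A"))
    p0 <- as.numeric(Matrix::solve(ch, sys$b_leak, system = "A"))
  } else {
    M <- matrix(0, 0, length(sys$fixed_nodes))
    p0 <- numeric(0)
  }
  node_order <- c(sys$unknown_nodes, sys$fixed_nodes)
  list(
    sys = sys, M = M, p0 = p0,
    node_order = node_order,
    nu = nu,
    seg_a = match(network$segments$node_a, node_order),
    seg_b = match(network$segments$node_b, node_order),
    inlet_col = match(bc$inlet_node, sys$fixed_nodes),
    network = network, bc = bc, fluid = fluid
  )
}

# Solve for the full pressure vector and per-segment flows given the fixed
# boundary pressures (ordered as ctx$sys$fixed_nodes). Fast path.
context_solve <- function(ctx, p_fixed) {
  p_unknown <- if (ctx$nu > 0) {
    ctx$p0 + as.numeric(ctx$M %*% p_fixed)
  } else {
    numeric(0)
  }
  p_full <- c(p_unknown, p_fixed)
  flows <- (p_full[ctx$seg_a] - p_full[ctx$seg_b]) * ctx$sys$conductance
  list(pressures = p_full, flows = flows)
}

# Max nodal mass-balance residual (absolute, m^3/s) and relative to total
# absolute boundary + leak throughflow.
context_residual <- function(ctx, p_full, flows) {
  nu <- ctx$nu
  if (nu == 0) return(c(abs = 0, rel = 0))
  resid <- ctx$sys$g_leak * (p_full[seq_len(nu)] - ctx$bc$venous_pressure)
  a_in <- ctx$seg_a[ctx$seg_a <= nu]
  # outflow along each segment from its endpoints
  for (s in seq_along(flows)) {
    ia <- ctx$seg_a[s]; ib <- ctx$seg_b[s]
    if (ia <= nu) resid[ia] <- resid[ia] + flows[s]
    if (ib <= nu) resid[ib] <- resid[ib] - flows[s]
  }
  scale <- sum(abs(flows[ctx$seg_a > nu | ctx$seg_b > nu])) +
    sum(abs(ctx$sys$g_leak * (p_full[seq_len(nu)] - ctx$bc$venous_pressure)))
  mx <- max(abs(resid))
  c(abs = mx, rel = if (scale > 0) mx / scale else 0)
}

#' Solve network pressures and flows
#'
#' Solves the nodal mass-conservation system for the pressures at all
#' non-boundary nodes (sparse Cholesky factorization) and derives signed
#' per-segment flows Q = (P_a - P_b)/R (positive means flow from `node_a`
#' to `node_b`). Flows are also normalized to the convention used for flow
#' maps: the reference segment (by default the largest-diameter vessel)
#' carries a magnitude of 1000.
#'
#' @inheritParams assemble_system
#' @param reference_segment Segment id used for normalization; default the
#'   largest-diameter segment.
#' @param stagnation_tolerance Absolute flow (m^3/s) below which a segment
#'   direction is reported as 0; default `1e-6 x |reference flow|`.
#' @return An object of class `vasc_state` with elements `pressures`
#'   (tibble `node_id`, `pressure_pa`), `flows` (tibble `segment_id`,
#'   `vessel_class`, `flow`, `flow_normalized`, `direction`),
#'   `reference_segment`, `residual_norm` (max nodal residual, m^3/s) and
#'   `residual_rel` (relative to total boundary throughflow).
#' @export
solve_pressures <- function(network, bc, fluid = fluid_parameters(),
                            reference_segment = NULL,
                            stagnation_tolerance = NULL) {
  ctx <- build_solver_context(network, bc, fluid)
  state_from_context(ctx, ctx$sys$fixed, reference_segment,
                     stagnation_tolerance)
}

state_from_context <- function(ctx, p_fixed, reference_segment = NULL,
                               stagnation_tolerance = NULL) {
  sol <- context_solve(ctx, p_fixed)
  resid <- context_residual(ctx, sol$pressures, sol$flows)
  segs <- ctx$network$segments
  if (is.null(reference_segment)) {
    reference_segment <- segs$segment_id[which.max(segs$diameter)]
  }
  state <- structure(
    list(
      pressures = tibble(node_id = ctx$node_order,
                         pressure_pa = unname(sol$pressures)),
      flows = tibble(segment_id = segs$segment_id,
                     vessel_class = segs$vessel_class,
                     flow = unname(sol$flows),
                     flow_normalized = NA_real_,
                     direction = NA_integer_),
      reference_segment = reference_segment,
      residual_norm = unname(resid["abs"]),
      residual_rel = unname(resid["rel"]),
      stagnation_tolerance = stagnation_tolerance
    ),
    class = "vasc_state"
  )
  if (abs(sol$flows[match(reference_segment, segs$segment_id)]) == 0) {
    # equilibrium state (e.g. all pressures equal): nothing to normalize
    state$flows$flow_normalized <- 0
    state$stagnation_tolerance <- stagnation_tolerance %||% 0
    state$flows$direction <-
      flow_direction(state$flows$flow, state$stagnation_tolerance)
    return(state)
  }
  normalize_flows(state, reference_segment)
}

#' Normalize flows to the reference-vessel convention
#'
#' Rescales every signed flow so the reference segment (by convention the
#' largest vessel in the field of view) has magnitude 1000; signs are
#' preserved. Also classifies each segment's direction with the stagnation
#' tolerance.
#'
#' @param state A `vasc_state` from [solve_pressures()].
#' @param reference_segment Segment id; default the state's stored
#'   reference.
#' @return The state with `flow_normalized` and `direction` filled in.
#' @export
normalize_flows <- function(state, reference_segment = NULL) {
  flows <- state$flows
  reference_segment <- reference_segment %||% state$reference_segment
  iref <- match(reference_segment, flows$segment_id)
  if (is.na(iref)) {
    abort(paste0("reference segment not in state: ", reference_segment))
  }
  qref <- abs(flows$flow[iref])
  if (qref == 0) {
    abort(paste0("cannot normalize: reference segment ", reference_segment,
                 " carries zero flow"))
  }
  tol <- state$stagnation_tolerance %||% (1e-6 * qref)
  # ratio first: the reference then lands on exactly +/-1000
  state$flows$flow_normalized <- 1000 * (flows$flow / qref)
  state$flows$direction <- flow_direction(flows$flow, tol)
  state$reference_segment <- reference_segment
  state$stagnation_tolerance <- tol
  state
}

#' Classify a flow as forward, reverse or stagnant
#'
#' @param flow Signed flow(s), any consistent unit.
#' @param stagnation_tolerance Magnitude at or below which the segment is
#'   classified as stagnant (direction 0). Must be >= 0.
#' @return Integer vector in \{-1, 0, +1\}.
#' @export
flow_direction <- function(flow, stagnation_tolerance = 0) {
  if (stagnation_tolerance < 0) abort("stagnation_tolerance must be >= 0")
  out <- sign(flow)
  out[abs(flow) <= stagnation_tolerance] <- 0
  as.integer(out)
}

#' @export
print.vasc_state <- function(x, ...) {
  cat(sprintf(
    "<vasc_state: %d nodes, %d segments, reference %s, max residual %.2e m^3/s>\n",
    nrow(x$pressures), nrow(x$flows), x$reference_segment, x$residual_norm
  ))
  invisible(x)
}

#' Tidy a solved hemodynamic state
#'
#' @param x A `vasc_state`.
#' @param ... Unused.
#' @return The per-segment flow tibble.
#' @method tidy vasc_state
#' @export
tidy.vasc_state <- function(x, ...) x$flows

#' One-row summary of a solved state
#'
#' @param x A `vasc_state`.
#' @param ... Unused.
#' @return A tibble with node/segment counts, residuals and the reference
#'   segment.
#' @method glance vasc_state
#' @export
glance.vasc_state <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$pressures), n_segments = nrow(x$flows),
    reference_segment = x$reference_segment,
    residual_norm = x$residual_norm, residual_rel = x$residual_rel,
    total_abs_flow = sum(abs(x$flows$flow))
  )
}
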