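#' Parameters for the synthetic network generator
#'
#' The generator emulates the structure the analysis assumes from
#' intravital tracings of skin microvasculature: a hybrid topology — a
#' bifurcating tree plus arcade (collateral) cross-connections that create
#' loops — with a diameter hierarchy tapering from a main trunk
#' (~150 um arterial, ~250 um venous) by a Murray-like factor of
#' 2^(-1/3) per generation, multiple unknown-pressure boundary crossings
#' at the field-of-view edge, and a ground-truth boundary pressure field
#' from which flow-direction observations are forward-simulated.
#'
#' @param depth Tree depth (bifurcation generations below the trunk).
#' @param arcades Number of cross-connections between same-depth nodes of
#'   adjacent subtrees.
#' @param trunk_diameter_um Trunk diameter, um; default 150 for arteries,
#'   250 for veins.
#' @param taper Child/parent diameter ratio per generation, in (0, 1);
#'   default `2^(-1/3)`.
#' @param length_range_um Segment length range, um.
#' @param boundary_crossings Number of leaf nodes that cross the FOV edge
#'   and carry unknown pressures (>= 2).
#' @param stagnant_fraction Share of forward observations blanked to
#'   direction 0, mimicking unobservable segments; in [0, 1).
#' @param vessel_class `"artery"` or `"vein"`.
#' @param inlet_pressure Known pressure of the trunk where it enters the
#'   FOV, Pa. Default 8000 Pa (~60 mmHg) for arteries; 1000 Pa for veins,
#'   where the trunk is the draining vessel.
#' @param venous_pressure Reference pressure `P_v`, Pa: 0 gauge for
#'   arterial networks, 2000 Pa (capillary pressure above the veins) for
#'   venous ones.
#' @param pressure_margin Ground-truth boundary pressures are drawn
#'   uniformly within the inner `1 - 2 x margin` band between
#'   `venous_pressure` and `inlet_pressure`, avoiding degenerate zero-flow
#'   boundaries (default 0.1).
#' @return A list of class `vasc_generator_params`.
#' @export
generator_params <- function(depth = 5, arcades = 4,
                             trunk_diameter_um = NULL,
                             taper = 2^(-1 / 3),
                             length_range_um = c(150, 400),
                             boundary_crossings = 8,
                             stagnant_fraction = 0.1,
                             vessel_class = c("artery", "vein"),
                             inlet_pressure = NULL,
                             venous_pressure = NULL,
                             pressure_margin = 0.1) {
  vessel_class <- match.arg(vessel_class)
  trunk_diameter_um <- trunk_diameter_um %||%
    if (vessel_class == "artery") 150 else 250
  inlet_pressure <- inlet_pressure %||%
    if (vessel_class == "artery") 8000 else 1000
  venous_pressure <- venous_pressure %||%
    if (vessel_class == "artery") 0 else 2000
  if (taper <= 0 || taper >= 1) abort("taper must lie in (0, 1)")
  if (boundary_crossings < 2) abort("boundary_crossings must be >= 2")
  if (stagnant_fraction < 0 || stagnant_fraction >= 1) {
    abort("stagnant_fraction must lie in [0, 1)")
  }
  if (boundary_crossings > 2^depth) {
    abort(paste0("boundary_crossings exceeds the ", 2^depth,
                 " leaves of a depth-", depth, " tree"))
  }
  structure(
    list(depth = depth, arcades = arcades,
         trunk_diameter_um = trunk_diameter_um, taper = taper,
         length_range_um = length_range_um,
         boundary_crossings = boundary_crossings,
         stagnant_fraction = stagnant_fraction,
         vessel_class = vessel_class, inlet_pressure = inlet_pressure,
         venous_pressure = venous_pressure,
         pressure_margin = pressure_margin),
    class = "vasc_generator_params"
  )
}

#' Generate a synthetic vascular network with ground truth
#'
#' Builds the hybrid tree-plus-arcade network described by
#' [generator_params()] and draws a ground-truth pressure for every
#' unknown boundary crossing. Deterministic for a given seed. The known
#' inlet is the trunk; a seeded subset of leaves become boundary crossings
#' (kind `boundary`), the remainder feed the capillary bed (kind
#' `terminal`). Arcades connect adjacent same-depth nodes of different
#' parent branches, with diameter `taper x` the smaller adjacent branch
#' (floored at the 11 um resolvable limit).
#'
#' @param params A [generator_params()] object.
#' @param seed RNG seed.
#' @return A list with `network` (a validated `vasc_network`) and `bc`
#'   (a `vasc_bc` holding the ground-truth boundary pressures,
#'   `R_TA = 100 x` median segment resistance).
#' @export
generate_network <- function(params = generator_params(), seed = 1L) {
  set.seed(seed)
  depth <- params$depth
  lev_ids <- function(l) paste0("n", l, "_", seq_len(2^l))
  nodes <- tibble(node_id = "inlet", kind = "boundary",
                  x_um = 0, y_um = 0, is_known_inlet = TRUE)
  segs <- list()
  span <- 2^depth * 120 # vertical spread of the layout, um
  add_seg <- function(id, a, b, d_um, class) {
    tibble(segment_id = id, node_a = a, node_b = b,
           diameter_um = d_um,
           length_um = runif(1, params$length_range_um[1],
                             params$length_range_um[2]),
           vessel_class = class, observed_direction = 0L)
  }
  # trunk into the root of the tree
  nodes <- bind_rows(nodes, tibble(node_id = "n0_1", kind = "interior",
                                   x_um = 500, y_um = 0,
                                   is_known_inlet = FALSE))
  segs[[1]] <- add_seg("trunk", "inlet", "n0_1",
                       params$trunk_diameter_um, params$vessel_class)
  for (l in seq_len(depth)) {
    ids <- lev_ids(l)
    parents <- lev_ids(l - 1)
    if (l == 1) parents <- rep("n0_1", 1)
    d_um <- params$trunk_diameter_um * params$taper^l
    y <- (seq_len(2^l) - (2^l + 1) / 2) * span / 2^l
    is_leaf <- l == depth
    nodes <- bind_rows(nodes, tibble(
      node_id = ids, kind = if (is_leaf) "terminal" else "interior",
      x_um = 500 + l * 500, y_um = y, is_known_inlet = FALSE
    ))
    for (k in seq_len(2^l)) {
      parent <- if (l == 1) "n0_1" else parents[ceiling(k / 2)]
      segs[[length(segs) + 1]] <-
        add_seg(paste0("s", l, "_", k), parent, ids[k], d_um,
                params$vessel_class)
    }
  }
  # arcade cross-links between adjacent same-depth nodes of neighbouring
  # subtrees, deepest internal level first
  pairs <- list()
  internal_levels <- if (depth >= 2) rev(seq_len(depth - 1)) else integer()
  for (l in internal_levels) {
    ids <- lev_ids(l)
    for (k in seq_len(2^l - 1)) {
      pairs[[length(pairs) + 1]] <- c(ids[k], ids[k + 1], l)
    }
  }
  if (params$arcades > length(pairs)) {
    abort(paste0("generation error: ", params$arcades,
                 " arcades requested but only ", length(pairs),
                 " adjacent-branch pairs available"))
  }
  if (params$arcades > 0) {
    for (a in seq_len(params$arcades)) {
      p <- pairs[[a]]
      l <- as.numeric(p[3])
      d_um <- max(params$trunk_diameter_um * params$taper^(l + 1), 11)
      segs[[length(segs) + 1]] <-
        add_seg(paste0("arc", a), p[1], p[2], d_um, params$vessel_class)
    }
  }
  segs <- bind_rows(segs)
  # a seeded subset of leaves become FOV boundary crossings
  leaves <- lev_ids(depth)
  crossing <- sort(sample(leaves, params$boundary_crossings))
  nodes$kind[nodes$node_id %in% crossing] <- "boundary"
  net <- vasc_network(nodes, segs, network_class =
                        if (params$vessel_class == "artery") "arterial"
                        else "venous")
  # ground-truth pressures in the inner band between P_v and the inlet
  rng <- sort(c(params$venous_pressure, params$inlet_pressure))
  m <- params$pressure_margin * diff(rng)
  truth <- setNames(runif(length(crossing), rng[1] + m, rng[2] - m),
                    crossing)
  r <- segment_resistance(net$segments$length, net$segments$diameter)
  bc <- boundary_conditions(
    inlet_node = "inlet", inlet_pressure = params$inlet_pressure,
    venous_pressure = params$venous_pressure,
    terminal_resistance = 100 * median(r),
    boundary_pressures = truth
  )
  list(network = net, bc = bc)
}

#' Forward-simulate flow-direction observations
#'
#' Solves the network under the ground-truth boundary conditions,
#' classifies each segment's direction, and blanks a seeded random subset
#' (`round(stagnant_fraction x n)` segments) to direction 0 to mimic
#' vessels whose flow could not be observed.
#'
#' @param network A `vasc_network`.
#' @param bc Ground-truth `vasc_bc`.
#' @param fluid A `vasc_fluid`.
#' @param stagnant_fraction Fraction of segments blanked (default 0).
#' @param seed Seed for the blanking draw.
#' @return The network with `observed_direction` filled in; the solved
#'   truth state is attached as attribute `"truth_state"`.
#' @export
forward_observe <- function(network, bc, fluid = fluid_parameters(),
                            stagnant_fraction = 0, seed = 1L) {
  state <- solve_pressures(network, bc, fluid)
  dirs <- state$flows$direction
  n_blank <- round(stagnant_fraction * length(dirs))
  if (n_blank > 0) {
    set.seed(seed)
    dirs[sample(length(dirs), n_blank)] <- 0L
  }
  network$segments$observed_direction <- dirs
  attr(network, "truth_state") <- state
  network
}

#' Programmed longitudinal remodeling fixture
#'
#' Generates a synthetic table of per-segment diameter time courses with
#' known injected effects, so the descriptive remodeling statistics can be
#' verified in closed loop. The programmed conditions mirror the reported
#' remodeling pattern of skin microvasculature after laser ablation:
#'
#' * immediately post-ablation (day 1) the mean artery and vein diameter
#'   increases are exactly `artery_immediate_pct` (14%) and
#'   `vein_immediate_pct` (23%);
#' * at day 20 the maximum fold-increase among vessels resolvable at
#'   baseline is exactly `artery_day20_max_fold` (2.5x) for arteries and
#'   `vein_day20_max_fold` (3.3x) for veins;
#' * one initially sub-resolution collateral venule (`vein_collateral`,
#'   baseline 10 um) remodels outward along the programmed profile
#'   +40% (day 6), +221% (13), +229% (14), +306% (16), +343% (20),
#'   peaking at +379% (day 23) and regressing to +282% (day 28).
#'
#' @param n_arteries,n_veins Number of main vessels per class (default 20
#'   each).
#' @param seed RNG seed for baselines and profile noise.
#' @param artery_immediate_pct,vein_immediate_pct Programmed mean
#'   immediate increases, percent.
#' @param artery_day20_max_fold,vein_day20_max_fold Programmed day-20
#'   maximum fold changes.
#' @return A long-format records tibble (`segment_id`, `vessel_class`,
#'   `day`, `diameter_um`, `x_um`, `y_um`).
#' @export
make_remodeling_fixture <- function(n_arteries = 20, n_veins = 20,
                                    seed = 1L,
                                    artery_immediate_pct = 14,
                                    vein_immediate_pct = 23,
                                    artery_day20_max_fold = 2.5,
                                    vein_day20_max_fold = 3.3) {
  set.seed(seed)
  days <- c(0, 1, 6, 13, 14, 16, 20, 23, 28, 30)
  one_class <- function(n, class, d_max, imm_pct, max_fold) {
    ids <- paste0(substr(class, 1, 1), "_", seq_len(n))
    d0 <- runif(n, 15, d_max)
    # immediate percent changes centered to hit the programmed mean exactly
    imm <- rnorm(n, imm_pct, 5)
    imm <- imm - mean(imm) + imm_pct
    # day-20 folds: one designated vessel carries the programmed maximum
    fold20 <- runif(n, 0.8, min(1.8, max_fold - 0.2))
    fold20[1] <- max_fold
    purrr::map_dfr(seq_len(n), function(i) {
      f1 <- 1 + imm[i] / 100
      # smooth multiplicative path between the pinned days
      f <- stats::approx(x = c(1, 20, 30), y = c(f1, fold20[i], f1),
                         xout = days[-1])$y
      f <- f * exp(rnorm(length(f), 0, 0.01))
      f[days[-1] == 1] <- f1
      f[days[-1] == 20] <- fold20[i]
      tibble(segment_id = ids[i], vessel_class = class, day = days,
             diameter_um = d0[i] * c(1, f),
             x_um = runif(1, 0, 9000), y_um = runif(1, 0, 9000))
    })
  }
  arteries <- one_class(n_arteries, "artery", 150, artery_immediate_pct,
                        artery_day20_max_fold)
  veins <- one_class(n_veins, "vein", 250, vein_immediate_pct,
                     vein_day20_max_fold)
  # the collateral venule: below the 11 um resolvable limit at baseline
  collateral_pct <- c(`1` = 0, `6` = 40, `13` = 221, `14` = 229,
                      `16` = 306, `20` = 343, `23` = 379, `28` = 282,
                      `30` = 282)
  collateral <- tibble(
    segment_id = "vein_collateral", vessel_class = "vein",
    day = days,
    diameter_um = unname(10 * (1 + c(0, collateral_pct) / 100)),
    x_um = 4500, y_um = 4500
  )
  bind_rows(arteries, veins, collateral)
}

#' Two-arcade ladder fixture
#'
#' A small deterministic arterial network used throughout the tests and
#' examples: a wide central trunk (inlet -> t0 -> t1 -> t2 -> boundary
#' outlet bt) paralleled by a narrower side branch (t0 -> s0 -> s1 ->
#' boundary outlet bs), with two arcade cross-links s0–t1 and s1–t2.
#'
#' With the asymmetric ground-truth outlet pressures (trunk outlet
#' 4200 Pa, side outlet 3000 Pa, inlet 8000 Pa, P_v = 0) both arcades
#' carry a near-zero trunk-to-side flow whose magnitude and sign are
#' only weakly constrained by the observed directions — they are the
#' high-uncertainty collateral candidates. Ablating the central trunk
#' segment `t0_t1` leaves the whole distal trunk fed through the arcades
#' from the side branch, and both arcades reverse. The terminal
#' resistance is set high (1e4 x median segment resistance) so the leak
#' pathway does not blur the small collateral flows.
#'
#' @return A list with `network`, `bc` and `trunk_segment` (`"t0_t1"`, the
#'   canonical ablation target).
#' @export
fixture_two_arcade <- function() {
  nodes <- tibble(
    node_id = c("inlet", "t0", "t1", "t2", "s0", "s1", "bt", "bs"),
    kind = c("boundary", "interior", "interior", "interior", "interior",
             "interior", "boundary", "boundary"),
    x_um = c(0, 500, 1000, 1500, 500, 1000, 2000, 1500),
    y_um = c(0, 0, 0, 0, 400, 400, 0, 400),
    is_known_inlet = c(TRUE, rep(FALSE, 7))
  )
  segs <- tibble(
    segment_id = c("trunk", "t0_t1", "t1_t2", "t2_bt",
                   "t0_s0", "s0_s1", "s1_bs", "arc1", "arc2"),
    node_a = c("inlet", "t0", "t1", "t2", "t0", "s0", "s1", "s0", "s1"),
    node_b = c("t0", "t1", "t2", "bt", "s0", "s1", "bs", "t1", "t2"),
    diameter_um = c(150, 100, 100, 100, 40, 40, 40, 15, 15),
    length_um = c(500, 500, 500, 500, 600, 500, 600, 400, 400),
    vessel_class = "artery",
    observed_direction = 0L
  )
  net <- vasc_network(nodes, segs)
  r <- segment_resistance(net$segments$length, net$segments$diameter)
  bc <- boundary_conditions(
    inlet_node = "inlet", inlet_pressure = 8000, venous_pressure = 0,
    terminal_resistance = 1e4 * median(r),
    boundary_pressures = c(bt = 4200, bs = 3000)
  )
  list(network = net, bc = bc, trunk_segment = "t0_t1")
}

#' Convergent venous fixture
#'
#' A small venous network with ample downstream convergence: every path
#' drains toward the known outlet vein, the terminal pathway acts as a
#' distributed capillary inflow (`P_v` above the vein pressures, leak at
#' terminal nodes only), and the unknown boundary crossing is an
#' additional low-pressure drain. Ablating the mid-trunk reroutes flow
#' through the remaining drains with magnitude changes but no direction
#' reversals.
#'
#' @return A list with `network`, `bc` and `trunk_segment` (`"t1_t2"`).
#' @export
fixture_venous_convergent <- function() {
  nodes <- tibble(
    node_id = c("outlet", "t0", "t1", "t2", "c1", "bc1",
                "term1", "term2", "term3"),
    kind = c("boundary", "interior", "interior", "interior", "interior",
             "boundary", "terminal", "terminal", "terminal"),
    x_um = c(0, 500, 1000, 1500, 2000, 2500, 2200, 1000, 500),
    y_um = c(0, 0, 0, 0, 0, 0, 400, 400, -400),
    is_known_inlet = c(TRUE, rep(FALSE, 8))
  )
  segs <- tibble(
    segment_id = c("main", "t0_t1", "t1_t2", "t2_c1", "c1_bc1",
                   "c1_term1", "t1_term2", "t0_term3"),
    node_a = c("outlet", "t0", "t1", "t2", "c1", "c1", "t1", "t0"),
    node_b = c("t0", "t1", "t2", "c1", "bc1", "term1", "term2", "term3"),
    diameter_um = c(250, 200, 150, 120, 100, 60, 60, 60),
    length_um = c(500, 500, 500, 500, 500, 400, 400, 400),
    vessel_class = "vein",
    observed_direction = 0L
  )
  net <- vasc_network(nodes, segs)
  r <- segment_resistance(net$segments$length, net$segments$diameter)
  bc <- boundary_conditions(
    inlet_node = "outlet", inlet_pressure = 500, venous_pressure = 2000,
    terminal_resistance = 20 * median(r),
    boundary_pressures = c(bc1 = 520),
    leak = "terminal_only"
  )
  list(network = net, bc = bc, trunk_segment = "t1_t2")
}

#' Three-node toy network
#'
#' @return A minimal valid network: inlet — interior — outlet.
#' @export
fixture_three_node <- function() {
  vasc_network(
    nodes = tibble(node_id = c("in", "mid", "out"),
                   kind = c("boundary", "interior", "boundary"),
                   x_um = c(0, 500, 1000), y_um = 0,
                   is_known_inlet = c(TRUE, FALSE, FALSE)),
    segments = tibble(segment_id = c("s1", "s2"),
                      node_a = c("in", "mid"), node_b = c("mid", "out"),
                      diameter_um = c(50, 40), length_um = c(300, 300),
                      vessel_class = "artery", observed_direction = 1L)
  )
}
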