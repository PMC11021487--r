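test_that("segment resistance follows the Poiseuille formula and scalings", {
  # hand evaluation: 128 * 100e-6 * 3e-3 / (pi * (10e-6)^4)
  expect_equal(segment_resistance(100e-6, 10e-6, 3e-3),
               1.22231e15, tolerance = 1e-5)
  r <- segment_resistance(2e-4, 3e-5)
  expect_equal(segment_resistance(2e-4, 6e-5), r / 16) # D^-4
  expect_equal(segment_resistance(6e-4, 3e-5), 3 * r)  # linear in L
  expect_error(segment_resistance(-1, 3e-5), "positive")
})

test_that("single-junction solves match hand calculations", {
  nodes <- tibble::tibble(
    node_id = c("b1", "i", "b2"),
    kind = c("boundary", "interior", "boundary"),
    is_known_inlet = c(TRUE, FALSE, FALSE)
  )
  segs <- tibble::tibble(
    segment_id = c("s1", "s2"), node_a = c("b1", "i"),
    node_b = c("i", "b2"), diameter_um = 50, length_um = 200,
    vessel_class = "artery", observed_direction = 0L
  )
  net <- vasc_network(nodes, segs)
  rseg <- segment_resistance(200e-6, 50e-6)
  # no leak: interior settles at the mean of the two boundary pressures
  bc <- boundary_conditions("b1", 6000, 0, 1e30, c(b2 = 2000),
                            leak = "none")
  st <- solve_pressures(net, bc)
  expect_equal(st$pressures$pressure_pa[st$pressures$node_id == "i"], 4000)
  # leak with R_TA equal to the segment resistance and P_v = 0:
  # (P-p1)/R + (P-p2)/R + P/R = 0  =>  P = (p1+p2)/3
  bc <- boundary_conditions("b1", 6000, 0, rseg, c(b2 = 2000))
  st <- solve_pressures(net, bc)
  expect_equal(st$pressures$pressure_pa[st$pressures$node_id == "i"],
               8000 / 3)
})

test_that("system diagonal equals incident conductances plus leak", {
  fx <- fixture_two_arcade()
  sys <- assemble_system(fx$network, fx$bc)
  segs <- fx$network$segments
  g <- 1 / segment_resistance(segs$length, segs$diameter)
  for (k in seq_along(sys$unknown_nodes)) {
    id <- sys$unknown_nodes[k]
    inc <- sum(g[segs$node_a == id | segs$node_b == id])
    expect_equal(sys$A[k, k], inc + 1 / fx$bc$terminal_resistance)
  }
  expect_true(Matrix::isSymmetric(sys$A))
  expect_error(
    assemble_system(fx$network,
                    boundary_conditions("inlet", 8000, 0, 1e12,
                                        c(bt = 4200))),
    "bs"
  )
})

test_that("series circuit carries the hand-computed flow", {
  fx <- series_network(r_ohm = 1e15)
  st <- solve_pressures(fx$network, fx$bc)
  expect_equal(st$flows$flow, c(5e-14, 5e-14), tolerance = 1e-12)
})

test_that("equal pressures everywhere give zero flow", {
  fx <- fixture_two_arcade()
  bc <- fx$bc
  bc$inlet_pressure <- 3000
  bc$venous_pressure <- 3000
  bc$boundary_pressures[] <- 3000
  st <- solve_pressures(fx$network, bc, reference_segment = "trunk",
                        stagnation_tolerance = 1e-30)
  expect_lt(max(abs(st$flows$flow)), 1e-20) # numerically zero
})

test_that("sparse solve matches the dense brute-force oracle", {
  for (i in 1:25) {
    rn <- random_network(n_nodes = sample(10:50, 1),
                         extra_edges = sample(0:6, 1),
                         n_boundary = sample(2:5, 1), seed = i)
    st <- solve_pressures(rn$network, rn$bc)
    oracle <- dense_oracle_solve(rn$network, rn$bc)
    p <- setNames(st$pressures$pressure_pa, st$pressures$node_id)
    expect_equal(p[names(oracle$pressures)], oracle$pressures,
                 tolerance = 1e-10)
    q <- setNames(st$flows$flow, st$flows$segment_id)
    expect_equal(q[names(oracle$flows)], oracle$flows, tolerance = 1e-10)
    expect_lte(st$residual_rel, 1e-12)
  }
})

test_that("large terminal resistance converges to the no-leak solution", {
  fx <- fixture_two_arcade()
  bc_inf <- fx$bc
  bc_inf$leak <- "none"
  ref <- solve_pressures(fx$network, bc_inf)
  bc_big <- fx$bc
  r <- segment_resistance(fx$network$segments$length,
                          fx$network$segments$diameter)
  bc_big$terminal_resistance <- 1e20 * max(r)
  near <- solve_pressures(fx$network, bc_big)
  expect_equal(near$flows$flow, ref$flows$flow, tolerance = 1e-6)
})

test_that("flows are gauge invariant and linear in pressure offsets", {
  for (i in 1:10) {
    rn <- random_network(n_nodes = 25, extra_edges = 4, n_boundary = 4,
                         seed = 100 + i)
    base <- solve_pressures(rn$network, rn$bc)
    # gauge: shift every boundary pressure and P_v by a constant
    bc <- rn$bc
    shift <- 1234.5
    bc$inlet_pressure <- bc$inlet_pressure + shift
    bc$venous_pressure <- bc$venous_pressure + shift
    bc$boundary_pressures <- bc$boundary_pressures + shift
    shifted <- solve_pressures(rn$network, bc)
    expect_equal(shifted$flows$flow, base$flows$flow, tolerance = 1e-9)
    # linearity: scale all offsets from P_v by k
    k <- 2.5
    bc <- rn$bc
    pv <- bc$venous_pressure
    bc$inlet_pressure <- pv + k * (bc$inlet_pressure - pv)
    bc$boundary_pressures <- pv + k * (bc$boundary_pressures - pv)
    scaled <- solve_pressures(rn$network, bc)
    expect_equal(scaled$flows$flow, k * base$flows$flow,
                 tolerance = 1e-9)
    expect_equal(scaled$flows$direction, base$flows$direction)
  }
})

test_that("mass is conserved at interior nodes including the leak", {
  rn <- random_network(n_nodes = 40, extra_edges = 5, n_boundary = 4,
                       seed = 7)
  st <- solve_pressures(rn$network, rn$bc)
  p <- setNames(st$pressures$pressure_pa, st$pressures$node_id)
  q <- setNames(st$flows$flow, st$flows$segment_id)
  segs <- rn$network$segments
  interior <- rn$network$nodes$node_id[rn$network$nodes$kind != "boundary"]
  for (id in interior) {
    inflow <- sum(q[segs$segment_id[segs$node_b == id]]) -
      sum(q[segs$segment_id[segs$node_a == id]])
    leak <- (p[id] - rn$bc$venous_pressure) / rn$bc$terminal_resistance
    expect_lt(abs(unname(inflow - leak)), 1e-12 * sum(abs(q)))
  }
})

test_that("normalization pins the reference at 1000 and preserves ratios", {
  # parallel pair whose conductances are in ratio 5:1 under one drop
  d1 <- 50e-6
  d2 <- d1 / 5^(1 / 4)
  nodes <- tibble::tibble(
    node_id = c("in", "out"), kind = "boundary",
    is_known_inlet = c(TRUE, FALSE)
  )
  segs <- tibble::tibble(
    segment_id = c("big", "small"), node_a = "in", node_b = "out",
    diameter = c(d1, d2), length = 300e-6,
    vessel_class = "artery", observed_direction = 0L
  )
  net <- vasc_network(nodes, segs)
  bc <- boundary_conditions("in", 5000, 0, 1e30, c(out = 1000),
                            leak = "none")
  st <- solve_pressures(net, bc)
  expect_equal(st$reference_segment, "big")
  q <- setNames(st$flows$flow_normalized, st$flows$segment_id)
  expect_identical(abs(q[["big"]]), 1000)
  expect_equal(q[["small"]], 200)
  # re-normalizing to the small branch rescales, preserving signs
  st2 <- normalize_flows(st, "small")
  q2 <- setNames(st2$flows$flow_normalized, st2$flows$segment_id)
  expect_equal(abs(q2[["small"]]), 1000)
  expect_equal(q2[["big"]], 5000)
})

test_that("explicit normalization rejects a zero-flow reference", {
  fx <- fixture_two_arcade()
  bc <- fx$bc
  bc$inlet_pressure <- 0
  bc$venous_pressure <- 0
  bc$boundary_pressures[] <- 0
  st <- solve_pressures(fx$network, bc) # equilibrium itself is fine
  expect_equal(st$flows$flow_normalized, rep(0, nrow(st$flows)))
  expect_error(normalize_flows(st, "trunk"), "zero flow")
})

test_that("flow direction classification respects the tolerance", {
  expect_identical(flow_direction(3e-13, 1e-15), 1L)
  expect_identical(flow_direction(-1e-16, 1e-15), 0L)
  expect_identical(flow_direction(0), 0L)
  expect_identical(flow_direction(c(-2, 0.5, 3), 1), c(-1L, 0L, 1L))
  expect_error(flow_direction(1, -1), ">= 0")
})
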