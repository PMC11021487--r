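test_that("occluded segments vanish and orphan nodes are dropped", {
  fx <- fixture_two_arcade()
  post <- apply_ablation(fx$network, "arc1")
  expect_false("arc1" %in% post$segments$segment_id)
  expect_equal(nrow(post$nodes), nrow(fx$network$nodes))
  expect_error(apply_ablation(fx$network, "nope"), "nope")
})

test_that("dominant-series parallel pair: survivor takes the joint flow", {
  # a high-resistance feeder in series with a low-resistance parallel
  # pair: ablating one of the pair leaves the total (feeder-limited)
  # flow through the survivor
  nodes <- tibble::tibble(
    node_id = c("in", "m", "out"),
    kind = c("boundary", "interior", "boundary"),
    is_known_inlet = c(TRUE, FALSE, FALSE)
  )
  segs <- tibble::tibble(
    segment_id = c("feeder", "p1", "p2"),
    node_a = c("in", "m", "m"), node_b = c("m", "out", "out"),
    diameter_um = c(20, 200, 200), length_um = c(400, 100, 100),
    vessel_class = "artery", observed_direction = 0L
  )
  net <- vasc_network(nodes, segs)
  bc <- boundary_conditions("in", 8000, 0, 1e30, c(out = 1000),
                            leak = "none")
  pre <- solve_pressures(net, bc, reference_segment = "feeder")
  joint <- sum(pre$flows$flow[pre$flows$segment_id %in% c("p1", "p2")])
  post <- solve_pressures(apply_ablation(net, "p2"), bc,
                          reference_segment = "feeder")
  expect_equal(post$flows$flow[post$flows$segment_id == "p1"], joint,
               tolerance = 1e-6)
})

test_that("isolating a component from every boundary is rejected", {
  # ablating the only path to a leaf subtree strands it
  gen <- generate_network(generator_params(depth = 3, arcades = 0,
                                           boundary_crossings = 2),
                          seed = 2)
  expect_error(apply_ablation(gen$network, "trunk"),
               "disconnects the inlet")
  # ablating both feeders of an interior junction strands it
  fx <- fixture_venous_convergent()
  expect_error(apply_ablation(fx$network, c("t2_c1", "c1_bc1")),
               "isolates")
})

test_that("finite-resistance occlusion scales resistance by the factor", {
  fx <- fixture_two_arcade()
  post <- apply_ablation(fx$network, "t0_t1", mode = "resistance",
                         occlusion_factor = 1e6)
  i <- which(post$segments$segment_id == "t0_t1")
  r_pre <- segment_resistance(fx$network$segments$length[i],
                              fx$network$segments$diameter[i])
  r_post <- segment_resistance(post$segments$length[i],
                               post$segments$diameter[i])
  expect_equal(r_post / r_pre, 1e6, tolerance = 1e-9)
})

test_that("state comparison flags reversals per the definition", {
  mk <- function(q) {
    structure(list(flows = tibble::tibble(
      segment_id = paste0("s", seq_along(q)),
      vessel_class = "artery",
      flow = q * 1e-12, flow_normalized = q,
      direction = sign(q)
    )), class = "vasc_state")
  }
  pre <- mk(c(100, 50, 0.0005, 30))
  expect_s3_class(compare_states(pre, pre), "vasc_comparison")
  same <- compare_states(pre, pre)
  expect_equal(sum(same$comparison$reversed), 0)
  expect_equal(same$comparison$delta, rep(0, 4))

  post <- mk(c(-100, 50, -20, 0.0002))
  cmp <- compare_states(pre, post)
  flags <- setNames(cmp$comparison$reversed, cmp$comparison$segment_id)
  expect_true(flags[["s1"]])   # clean sign flip
  expect_false(flags[["s2"]])  # unchanged
  expect_false(flags[["s3"]])  # pre below tolerance: activation, not reversal
  expect_false(flags[["s4"]])  # post below tolerance: stagnation
  # antisymmetry
  expect_equal(compare_states(post, pre)$comparison$reversed,
               cmp$comparison$reversed)
})

test_that("ablated segments carry exactly zero flow post-ablation", {
  fx <- fixture_two_arcade()
  exp <- ablation_experiment(fx$network, fx$bc, fx$trunk_segment)
  row <- exp$comparison$comparison
  expect_identical(row$flow_post[row$segment_id == fx$trunk_segment], 0)
  expect_true(row$ablated[row$segment_id == fx$trunk_segment])
  # conservation holds independently in both states
  expect_lte(exp$pre$residual_rel, 1e-12)
  expect_lte(exp$post$residual_rel, 1e-12)
})

test_that("trunk ablation reverses the arcades (dense-oracle checked)", {
  fx <- fixture_two_arcade()
  exp <- ablation_experiment(fx$network, fx$bc, fx$trunk_segment)
  cmp <- exp$comparison$comparison
  expect_setequal(cmp$segment_id[cmp$reversed], c("arc1", "arc2"))
  # cross-check both solves against the independent dense oracle
  for (st in list(exp$pre, exp$post)) {
    net <- if (nrow(st$flows) == 9) fx$network else {
      apply_ablation(fx$network, fx$trunk_segment)
    }
    oracle <- dense_oracle_solve(net, fx$bc)
    q <- setNames(st$flows$flow, st$flows$segment_id)
    expect_equal(q[names(oracle$flows)], oracle$flows, tolerance = 1e-10)
  }
})

test_that("candidate ranking puts sentinels first, ties by mean flow", {
  fake <- structure(list(stats = tibble::tibble(
    segment_id = c("a", "b", "c", "d"),
    vessel_class = "artery", diameter_um = 50, observed_direction = 1L,
    flow_mean = c(500, 2, -80, 10),
    flow_sd = c(10, 5, 40, 0),
    uncertainty_index = c(0.02, Inf, 0.5, 0),
    direction_consistency = 1, modal_direction = 1L
  )), class = "vasc_ensemble")
  ranked <- rank_collateral_candidates(fake)
  expect_equal(ranked$segment_id, c("b", "c", "a", "d"))
  # all-equal indices fall back to ascending |mean|
  fake$stats$uncertainty_index <- 0
  ranked <- rank_collateral_candidates(fake)
  expect_equal(ranked$segment_id, c("b", "d", "c", "a"))
  expect_equal(rank_collateral_candidates(fake, top_k = 2)$segment_id,
               c("b", "d"))
})

test_that("prediction evaluation reports precision, recall and p-value", {
  fake_cmp <- structure(list(comparison = tibble::tibble(
    segment_id = paste0("s", 1:10), vessel_class = "artery",
    flow_pre = 100, flow_post = c(-100, -100, rep(100, 8)),
    ablated = FALSE, delta = 0,
    reversed = c(TRUE, TRUE, rep(FALSE, 8))
  )), class = "vasc_comparison")
  cand <- tibble::tibble(segment_id = paste0("s", c(1, 2, 5, 6, 7)))
  enr <- evaluate_prediction(cand, fake_cmp, k = 2, seed = 1)
  expect_equal(enr$precision, 1)
  expect_equal(enr$recall, 1)
  expect_lt(enr$p_value, 0.05)
  # empty reversed set: not applicable
  fake_cmp$comparison$reversed <- FALSE
  enr <- evaluate_prediction(cand, fake_cmp, k = 2, seed = 1)
  expect_equal(enr$precision, 0)
  expect_true(is.na(enr$recall))
})

test_that("venous convergent fixture reroutes without reversals", {
  vx <- fixture_venous_convergent()
  exp <- ablation_experiment(vx$network, vx$bc, vx$trunk_segment)
  cmp <- exp$comparison
  expect_equal(sum(cmp$comparison$reversed), 0)
  # magnitudes do change: rerouting is happening
  unablated <- cmp$comparison[!cmp$comparison$ablated, ]
  expect_gt(max(abs(unablated$delta)), 50)
})
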