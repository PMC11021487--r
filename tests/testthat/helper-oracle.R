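# Independent dense brute-force solver used as the oracle for the sparse
# solver: assembles the full nodal conductance system with plain base-R
# matrices and solves it with solve(), sharing no code with the package's
# assembly path.
dense_oracle_solve <- function(network, bc, viscosity = 3e-3) {
  nodes <- network$nodes
  segs <- network$segments
  ids <- nodes$node_id
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  for (s in seq_len(nrow(segs))) {
    a <- segs$node_a[s]; b <- segs$node_b[s]
    g <- pi * segs$diameter[s]^4 / (128 * segs$length[s] * viscosity)
    G[a, b] <- G[a, b] + g
    G[b, a] <- G[b, a] + g
  }
  fixed <- nodes$node_id[nodes$kind == "boundary"]
  p_fixed <- setNames(rep(NA_real_, length(fixed)), fixed)
  p_fixed[bc$inlet_node] <- bc$inlet_pressure
  other <- setdiff(fixed, bc$inlet_node)
  p_fixed[other] <- bc$boundary_pressures[other]
  free <- setdiff(ids, fixed)
  gl <- setNames(rep(0, n), ids)
  if (bc$leak != "none" && is.finite(bc$terminal_resistance)) {
    hit <- if (bc$leak == "all") free else {
      nodes$node_id[nodes$kind == "terminal"]
    }
    gl[hit] <- 1 / bc$terminal_resistance
  }
  A <- matrix(0, length(free), length(free),
              dimnames = list(free, free))
  b <- setNames(rep(0, length(free)), free)
  for (i in free) {
    A[i, i] <- sum(G[i, ]) + gl[i]
    b[i] <- gl[i] * bc$venous_pressure
    for (j in ids[G[i, ] > 0]) {
      if (j %in% free) A[i, j] <- A[i, j] - G[i, j] else {
        b[i] <- b[i] + G[i, j] * p_fixed[j]
      }
    }
  }
  p <- setNames(rep(NA_real_, n), ids)
  p[fixed] <- p_fixed
  if (length(free) > 0) p[free] <- solve(A, b)
  flows <- setNames(
    (p[segs$node_a] - p[segs$node_b]) *
      pi * segs$diameter^4 / (128 * segs$length * viscosity),
    segs$segment_id
  )
  list(pressures = p, flows = flows)
}

# Random connected test network: a spanning tree over n nodes plus extra
# edges, random geometry, >= 2 boundary nodes with random pressures.
random_network <- function(n_nodes, extra_edges = 3, n_boundary = 3,
                           seed = 1) {
  set.seed(seed)
  ids <- paste0("v", seq_len(n_nodes))
  a <- character(); b <- character()
  for (k in 2:n_nodes) { # random spanning tree
    a <- c(a, ids[sample(k - 1, 1)])
    b <- c(b, ids[k])
  }
  tries <- 0
  while (extra_edges > 0 && tries < 200) {
    ij <- sample(n_nodes, 2)
    cand <- sort(ids[ij])
    dup <- any(pmin(a, b) == cand[1] & pmax(a, b) == cand[2])
    tries <- tries + 1
    if (!dup) {
      a <- c(a, cand[1]); b <- c(b, cand[2])
      extra_edges <- extra_edges - 1
    }
  }
  m <- length(a)
  bnd <- sample(ids, n_boundary)
  nodes <- tibble::tibble(
    node_id = ids,
    kind = ifelse(ids %in% bnd, "boundary", "interior"),
    is_known_inlet = ids == bnd[1]
  )
  segs <- tibble::tibble(
    segment_id = paste0("e", seq_len(m)),
    node_a = a, node_b = b,
    diameter_um = runif(m, 15, 150),
    length_um = runif(m, 100, 500),
    vessel_class = "artery",
    observed_direction = 0L
  )
  net <- vasc_network(nodes, segs)
  r <- segment_resistance(net$segments$length, net$segments$diameter)
  bc <- boundary_conditions(
    inlet_node = bnd[1], inlet_pressure = 8000, venous_pressure = 0,
    terminal_resistance = 10^runif(1, 1, 3) * median(r),
    boundary_pressures = setNames(runif(n_boundary - 1, 500, 7500),
                                  bnd[-1])
  )
  list(network = net, bc = bc)
}

# Two-resistor series network with each segment resistance exactly r_ohm,
# solved end-to-end under a 100 Pa drop with no terminal leak.
series_network <- function(r_ohm = 1e15, mu = 3e-3, len = 100e-6) {
  d <- (128 * len * mu / (pi * r_ohm))^(1 / 4)
  net <- vasc_network(
    nodes = tibble::tibble(
      node_id = c("a", "m", "b"),
      kind = c("boundary", "interior", "boundary"),
      is_known_inlet = c(TRUE, FALSE, FALSE)
    ),
    segments = tibble::tibble(
      segment_id = c("s1", "s2"), node_a = c("a", "m"),
      node_b = c("m", "b"), diameter = d, length = len,
      vessel_class = "artery", observed_direction = 0L
    )
  )
  bc <- boundary_conditions("a", 100, 0, 1e30, c(b = 0), leak = "none")
  list(network = net, bc = bc)
}
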