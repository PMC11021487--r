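#' Apply an in-silico ablation
#'
#' Models laser cauterization of vessels. By default occluded segments are
#' removed from the flow graph (infinite resistance); degree-0 nodes left
#' behind are dropped. A partial-occlusion mode multiplies the segment
#' resistance by a large finite factor instead (implemented by shrinking
#' the diameter, since R scales as D^-4).
#'
#' After removal every connected component must still contain at least one
#' boundary node, otherwise its pressures would be set by the terminal
#' leak alone and the acute-redistribution comparison is meaningless;
#' such ablations are rejected naming the isolated component.
#'
#' @param network A `vasc_network`.
#' @param segment_ids Character vector of segments to occlude.
#' @param mode `"remove"` (default) or `"resistance"` for a finite
#'   occlusion.
#' @param occlusion_factor Resistance multiplier for `mode = "resistance"`
#'   (default 1e6).
#' @return The post-ablation `vasc_network`.
#' @export
apply_ablation <- function(network, segment_ids,
                           mode = c("remove", "resistance"),
                           occlusion_factor = 1e6) {
  mode <- match.arg(mode)
  segs <- network$segments
  unknown <- setdiff(segment_ids, segs$segment_id)
  if (length(unknown) > 0) {
    abort(paste0("ablation names unknown segment(s): ", toString(unknown)))
  }
  if (mode == "resistance") {
    hit <- segs$segment_id %in% segment_ids
    segs$diameter[hit] <- segs$diameter[hit] / occlusion_factor^(1 / 4)
    out <- network
    out$segments <- segs
    return(out)
  }
  keep <- !(segs$segment_id %in% segment_ids)
  segs <- segs[keep, ]
  if (nrow(segs) == 0) abort("ablation would remove every segment")
  used <- unique(c(segs$node_a, segs$node_b))
  inlet <- network$nodes$node_id[network$nodes$is_known_inlet]
  if (!inlet %in% used) {
    abort(paste0("ablation disconnects the inlet ", inlet,
                 " from the remaining network"))
  }
  nodes <- network$nodes[network$nodes$node_id %in% used, ]
  g <- igraph::graph_from_data_frame(segs[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = nodes["node_id"])
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  bnd <- nodes$node_id[nodes$kind == "boundary"]
  isolated <- groups[!vapply(groups, function(g) any(g %in% bnd), logical(1))]
  if (length(isolated) > 0) {
    abort(paste0(
      "ablation isolates component(s) from every boundary node: ",
      paste(vapply(isolated, function(g) paste0("{", toString(g), "}"),
                   character(1)), collapse = " ")
    ))
  }
  out <- network
  out$segments <- segs
  out$nodes <- nodes
  out
}

#' Compare pre- and post-ablation flow states
#'
#' Joins the two normalized flow fields by segment id. Segments absent from
#' the post state (the ablated ones) are assigned a post flow of exactly 0.
#' A segment is flagged `reversed` only when both its pre and post flows
#' exceed the stagnation tolerance in magnitude and their signs differ —
#' a segment that merely stagnates has not reversed.
#'
#' @param pre,post `vasc_state` objects solved on networks sharing segment
#'   ids (the post network lacking the ablated segments).
#' @param tol Stagnation tolerance on the normalized-flow scale; default
#'   the pre state's tolerance mapped to normalized units.
#' @return An object of class `vasc_comparison`: a per-segment tibble
#'   (`flow_pre`, `flow_post`, `delta`, `reversed`, `ablated`) plus a
#'   reversal-count summary by vessel class.
#' @export
compare_states <- function(pre, post, tol = NULL) {
  tol <- tol %||% 1e-3 # normalized units; reference flow is 1000
  pre_tbl <- pre$flows |>
    select("segment_id", "vessel_class", flow_pre = "flow_normalized")
  post_tbl <- post$flows |>
    select("segment_id", flow_post = "flow_normalized")
  cmp <- left_join(pre_tbl, post_tbl, by = "segment_id") |>
    mutate(
      ablated = is.na(.data$flow_post),
      flow_post = ifelse(.data$ablated, 0, .data$flow_post),
      delta = .data$flow_post - .data$flow_pre,
      reversed = abs(.data$flow_pre) > tol & abs(.data$flow_post) > tol &
        sign(.data$flow_pre) != sign(.data$flow_post)
    )
  summary <- cmp |>
    group_by(.data$vessel_class) |>
    summarise(n_segments = n(), n_reversed = sum(.data$reversed),
              .groups = "drop")
  structure(list(comparison = cmp, summary = summary, tol = tol),
            class = "vasc_comparison")
}

#' @export
print.vasc_comparison <- function(x, ...) {
  cat(sprintf("<vasc_comparison: %d segments, %d reversed, %d ablated>\n",
              nrow(x$comparison), sum(x$comparison$reversed),
              sum(x$comparison$ablated)))
  invisible(x)
}

#' Tidy an ablation comparison
#'
#' @param x A `vasc_comparison`.
#' @param ... Unused.
#' @return The per-segment comparison tibble.
#' @method tidy vasc_comparison
#' @export
tidy.vasc_comparison <- function(x, ...) x$comparison

#' @method glance vasc_comparison
#' @export
glance.vasc_comparison <- function(x, ...) {
  tibble(n_segments = nrow(x$comparison),
         n_reversed = sum(x$comparison$reversed),
         n_ablated = sum(x$comparison$ablated),
         max_abs_delta = max(abs(x$comparison$delta)))
}

#' Rank segments as collateral candidates
#'
#' Orders segments by uncertainty index descending — the `Inf` sentinel
#' (stagnant-mean segments, fully unconstrained) first — with ties broken
#' by lower |mean flow|: among equally uncertain vessels, the low-flow ones
#' are the likelier dormant collaterals.
#'
#' @param ensemble A `vasc_ensemble` computed on the pre-ablation network.
#' @param top_k Optionally truncate to the first `top_k` rows.
#' @return A tibble of ensemble statistics ordered by rank, with a `rank`
#'   column.
#' @export
rank_collateral_candidates <- function(ensemble, top_k = NULL) {
  ranked <- ensemble$stats |>
    arrange(desc(.data$uncertainty_index), abs(.data$flow_mean)) |>
    mutate(rank = row_number())
  if (!is.null(top_k)) ranked <- head(ranked, top_k)
  ranked
}

#' Test whether top-ranked candidates are the segments that reverse
#'
#' Quantifies the claim that high-uncertainty segments are the ones that
#' reverse after ablation: precision and recall of the top-k candidate set
#' against the observed reversed set, with a seeded permutation p-value for
#' the overlap (random size-k segment sets drawn from all compared
#' segments).
#'
#' @param candidates Ranked tibble from [rank_collateral_candidates()].
#' @param comparison A `vasc_comparison`.
#' @param k Size of the candidate set to evaluate; defaults to the number
#'   of reversed segments.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed for the permutation draw.
#' @return An object of class `vasc_enrichment` (list with `k`, `overlap`,
#'   `precision`, `recall`, `p_value`, `n_reversed`, `n_universe`).
#'   With an empty reversed set precision is 0 and recall/p-value are `NA`
#'   (not applicable).
#' @export
evaluate_prediction <- function(candidates, comparison, k = NULL,
                                n_perm = 10000, seed = 1L) {
  cmp <- comparison$comparison
  reversed <- cmp$segment_id[cmp$reversed]
  universe <- cmp$segment_id
  if (is.null(k)) k <- max(length(reversed), 1L)
  if (k > length(universe)) abort("k exceeds the number of compared segments")
  top <- head(candidates$segment_id[candidates$segment_id %in% universe], k)
  overlap <- length(intersect(top, reversed))
  if (length(reversed) == 0) {
    res <- list(k = k, overlap = 0L, precision = 0, recall = NA_real_,
                p_value = NA_real_, n_reversed = 0L,
                n_universe = length(universe))
    return(structure(res, class = "vasc_enrichment"))
  }
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    length(intersect(sample(universe, k), reversed))
  }, numeric(1))
  p <- (1 + sum(perm >= overlap)) / (n_perm + 1)
  structure(
    list(k = k, overlap = overlap, precision = overlap / k,
         recall = overlap / length(reversed), p_value = p,
         n_reversed = length(reversed), n_universe = length(universe)),
    class = "vasc_enrichment"
  )
}

#' @export
print.vasc_enrichment <- function(x, ...) {
  cat(sprintf(
    "<vasc_enrichment: top-%d overlap %d/%d, precision %.2f, p = %s>\n",
    x$k, x$overlap, x$n_reversed, x$precision,
    ifelse(is.na(x$p_value), "NA", format.pval(x$p_value))
  ))
  invisible(x)
}

#' @method glance vasc_enrichment
#' @export
glance.vasc_enrichment <- function(x, ...) {
  tibble(k = x$k, overlap = x$overlap, precision = x$precision,
         recall = x$recall, p_value = x$p_value,
         n_reversed = x$n_reversed, n_universe = x$n_universe)
}

#' Run a full ablation experiment
#'
#' Convenience wrapper for the acute-redistribution protocol: solve the
#' intact network, occlude the specified segments, re-solve with the same
#' boundary pressures (the acute state, before any distal adaptation), and
#' compare. The post solve reuses the pre-ablation reference segment for
#' normalization so the two maps share a scale; set `reanneal = TRUE` to
#' re-estimate boundary pressures on the post network instead (requires
#' post-ablation observed directions).
#'
#' @param network Pre-ablation `vasc_network`.
#' @param bc A `vasc_bc` with every boundary pressure filled in (for
#'   example the best pressures of an annealing restart).
#' @param segment_ids Segments to ablate.
#' @param fluid A `vasc_fluid`.
#' @param reanneal Re-run the annealing ensemble on the post network and
#'   use its mean boundary pressures (default `FALSE`).
#' @param config Annealing configuration, used only when `reanneal = TRUE`.
#' @return A list with `pre`, `post` (both `vasc_state`) and `comparison`
#'   (`vasc_comparison`).
#' @export
ablation_experiment <- function(network, bc, segment_ids,
                                fluid = fluid_parameters(),
                                reanneal = FALSE,
                                config = annealing_config()) {
  pre <- solve_pressures(network, bc, fluid)
  post_net <- apply_ablation(network, segment_ids)
  bc_post <- bc
  bc_post$boundary_pressures <-
    bc$boundary_pressures[names(bc$boundary_pressures) %in%
                            boundary_nodes(post_net)]
  if (reanneal) {
    ens <- run_ensemble(post_net, bc_post, config)
    best <- which.min(ens$best_errors)
    bc_post$boundary_pressures <- ens$boundary_pressures[[best]]
  }
  ref <- pre$reference_segment
  if (!ref %in% post_net$segments$segment_id) {
    ref <- NULL # reference itself ablated: fall back to largest survivor
  }
  post <- solve_pressures(post_net, bc_post, fluid, reference_segment = ref)
  list(pre = pre, post = post, comparison = compare_states(pre, post))
}
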