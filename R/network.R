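#' Construct a vascular network
#'
#' A vascular network is a graph of cylindrical vessel segments joining
#' nodes. Nodes are `interior` (bifurcations inside the field of view, FOV),
#' `boundary` (vessels crossing the FOV edge, where pressures are boundary
#' conditions) or `terminal` (dead ends feeding the capillary bed through a
#' lumped terminal resistance). Exactly one boundary node carries the known
#' inlet pressure; the arterial and venous trees are represented as separate
#' networks.
#'
#' Geometry columns are supplied in micrometres and stored internally in SI
#' metres; all downstream computation is SI.
#'
#' @param nodes A data frame with columns `node_id`, `kind` (one of
#'   `"interior"`, `"boundary"`, `"terminal"`), `is_known_inlet` (logical),
#'   and optional plotting coordinates `x_um`, `y_um`.
#' @param segments A data frame with columns `segment_id`, `node_a`,
#'   `node_b`, `diameter_um`, `length_um`, `vessel_class` (`"artery"` or
#'   `"vein"`) and `observed_direction` (+1 flow a to b, -1 flow b to a,
#'   0 unknown or stagnant).
#' @param network_class `"arterial"` or `"venous"`; inferred from the modal
#'   `vessel_class` when `NULL`.
#' @param validate If `TRUE` (default), reject networks violating the
#'   structural invariants (see [validate_network()]).
#' @return An object of class `vasc_network`: a list with tibbles `nodes`
#'   and `segments` (geometry in metres) and the `network_class` string.
#' @export
#' @examples
#' net <- vasc_network(
#'   nodes = data.frame(
#'     node_id = c("in", "mid", "out"),
#'     kind = c("boundary", "interior", "boundary"),
#'     is_known_inlet = c(TRUE, FALSE, FALSE)
#'   ),
#'   segments = data.frame(
#'     segment_id = c("s1", "s2"), node_a = c("in", "mid"),
#'     node_b = c("mid", "out"), diameter_um = c(50, 40),
#'     length_um = c(300, 300), vessel_class = "artery",
#'     observed_direction = c(1L, 1L)
#'   )
#' )
#' net
vasc_network <- function(nodes, segments, network_class = NULL,
                         validate = TRUE) {
  nodes <- as_tibble(nodes)
  segments <- as_tibble(segments)
  if (!"x_um" %in% names(nodes)) nodes$x_um <- NA_real_
  if (!"y_um" %in% names(nodes)) nodes$y_um <- NA_real_
  if (!"is_known_inlet" %in% names(nodes)) nodes$is_known_inlet <- FALSE
  nodes <- tibble(
    node_id = as.character(nodes$node_id),
    kind = as.character(nodes$kind),
    x_um = as.numeric(nodes$x_um),
    y_um = as.numeric(nodes$y_um),
    is_known_inlet = as.logical(nodes$is_known_inlet) %in% TRUE
  )
  # accept either internal SI columns or file-facing micrometre columns
  if (!"diameter" %in% names(segments) && "diameter_um" %in% names(segments)) {
    segments$diameter <- um_to_m(as.numeric(segments$diameter_um))
  }
  if (!"length" %in% names(segments) && "length_um" %in% names(segments)) {
    segments$length <- um_to_m(as.numeric(segments$length_um))
  }
  if (!"observed_direction" %in% names(segments)) {
    segments$observed_direction <- 0L
  }
  segments <- tibble(
    segment_id = as.character(segments$segment_id),
    node_a = as.character(segments$node_a),
    node_b = as.character(segments$node_b),
    diameter = as.numeric(segments$diameter),
    length = as.numeric(segments$length),
    vessel_class = as.character(segments$vessel_class),
    observed_direction = as.integer(segments$observed_direction)
  )
  if (is.null(network_class)) {
    network_class <- if (mean(segments$vessel_class == "vein") > 0.5) {
      "venous"
    } else {
      "arterial"
    }
  }
  network_class <- match.arg(network_class, c("arterial", "venous"))
  net <- structure(
    list(nodes = nodes, segments = segments, network_class = network_class),
    class = "vasc_network"
  )
  if (validate) {
    report <- validate_network(net)
    if (nrow(report) > 0) {
      abort(c("invalid vascular network",
              stats::setNames(report$message, rep("x", nrow(report)))))
    }
  }
  net
}

#' Validate a vascular network
#'
#' Checks every structural invariant of the network data model and reports
#' all violations; it never throws on structurally parseable input. An empty
#' report means the network is valid.
#'
#' @param network A `vasc_network` (possibly built with `validate = FALSE`).
#' @return A tibble with columns `rule`, `message` and `ids` (a list column
#'   of the offending node or segment identifiers); zero rows iff valid.
#' @export
validate_network <- function(network) {
  nodes <- network$nodes
  segs <- network$segments
  out <- list()
  bad <- function(rule, message, ids = character()) {
    tibble(rule = rule, message = message, ids = list(ids))
  }

  dup <- unique(nodes$node_id[duplicated(nodes$node_id)])
  if (length(dup) > 0) {
    out <- c(out, list(bad("unique_node_id",
      paste0("duplicated node ids: ", toString(dup)), dup)))
  }
  dup <- unique(segs$segment_id[duplicated(segs$segment_id)])
  if (length(dup) > 0) {
    out <- c(out, list(bad("unique_segment_id",
      paste0("duplicated segment ids: ", toString(dup)), dup)))
  }
  bad_kind <- nodes$node_id[!nodes$kind %in% c("interior", "boundary", "terminal")]
  if (length(bad_kind) > 0) {
    out <- c(out, list(bad("node_kind",
      paste0("unknown node kind for: ", toString(bad_kind)), bad_kind)))
  }
  bad_class <- segs$segment_id[!segs$vessel_class %in% c("artery", "vein")]
  if (length(bad_class) > 0) {
    out <- c(out, list(bad("vessel_class",
      paste0("vessel_class must be artery or vein for: ", toString(bad_class)),
      bad_class)))
  }
  bad_dir <- segs$segment_id[!segs$observed_direction %in% c(-1L, 0L, 1L)]
  if (length(bad_dir) > 0) {
    out <- c(out, list(bad("observed_direction",
      paste0("observed_direction must be -1, 0 or +1 for: ", toString(bad_dir)),
      bad_dir)))
  }
  if (nrow(segs) == 0) {
    out <- c(out, list(bad("has_segments", "network has no segments")))
  }
  np <- segs$segment_id[!is.na(segs$diameter) & segs$diameter <= 0 |
                          is.na(segs$diameter)]
  if (length(np) > 0) {
    out <- c(out, list(bad("diameter_positive",
      paste0("non-positive diameter in segments: ", toString(np)), np)))
  }
  np <- segs$segment_id[!is.na(segs$length) & segs$length <= 0 |
                          is.na(segs$length)]
  if (length(np) > 0) {
    out <- c(out, list(bad("length_positive",
      paste0("non-positive length in segments: ", toString(np)), np)))
  }
  loops <- segs$segment_id[segs$node_a == segs$node_b]
  if (length(loops) > 0) {
    out <- c(out, list(bad("no_self_loops",
      paste0("self-loop segments: ", toString(loops)), loops)))
  }
  dangling <- segs$segment_id[!(segs$node_a %in% nodes$node_id) |
                                !(segs$node_b %in% nodes$node_id)]
  if (length(dangling) > 0) {
    missing_nodes <- setdiff(c(segs$node_a, segs$node_b), nodes$node_id)
    out <- c(out, list(bad("endpoints_exist",
      paste0("segments ", toString(dangling),
             " reference nonexistent node(s): ", toString(missing_nodes)),
      dangling)))
  }
  n_bound <- sum(nodes$kind == "boundary")
  if (n_bound < 1) {
    out <- c(out, list(bad("has_boundary", "no boundary node present")))
  }
  n_inlet <- sum(nodes$is_known_inlet)
  if (n_inlet != 1) {
    out <- c(out, list(bad("one_known_inlet",
      paste0("expected exactly one known-pressure inlet, found ", n_inlet),
      nodes$node_id[nodes$is_known_inlet])))
  } else if (nodes$kind[nodes$is_known_inlet] != "boundary") {
    out <- c(out, list(bad("inlet_is_boundary",
      paste0("known inlet ", nodes$node_id[nodes$is_known_inlet],
             " is not a boundary node"),
      nodes$node_id[nodes$is_known_inlet])))
  }
  # connectivity (only meaningful when endpoints resolve)
  if (length(dangling) == 0 && nrow(segs) > 0 && nrow(nodes) > 0) {
    g <- igraph::graph_from_data_frame(
      segs[, c("node_a", "node_b")], directed = FALSE,
      vertices = nodes["node_id"]
    )
    comp <- igraph::components(g)
    if (comp$no > 1) {
      groups <- split(names(comp$membership), comp$membership)
      msg <- paste0(
        "network is disconnected (", comp$no, " components): ",
        paste(vapply(groups, function(g) paste0("{", toString(g), "}"),
                     character(1)), collapse = " ")
      )
      out <- c(out, list(bad("connected", msg, unlist(groups))))
    }
  }
  if (length(out) == 0) {
    tibble(rule = character(), message = character(), ids = list())
  } else {
    bind_rows(out)
  }
}

#' @export
print.vasc_network <- function(x, ...) {
  cat(sprintf(
    "<vasc_network: %s, %d nodes (%d boundary), %d segments>\n",
    x$network_class, nrow(x$nodes), sum(x$nodes$kind == "boundary"),
    nrow(x$segments)
  ))
  cat(sprintf(
    "  diameters %.0f-%.0f um, known inlet: %s\n",
    m_to_um(min(x$segments$diameter)), m_to_um(max(x$segments$diameter)),
    x$nodes$node_id[x$nodes$is_known_inlet][1]
  ))
  invisible(x)
}

#' Boundary node ids of a network
#'
#' @param network A `vasc_network`.
#' @param known_inlet Include the known-pressure inlet? Default `FALSE`,
#'   returning only the unknown-pressure boundary crossings (the free
#'   parameters of the inverse problem).
#' @return Character vector of node ids.
#' @export
boundary_nodes <- function(network, known_inlet = FALSE) {
  nd <- network$nodes
  ids <- nd$node_id[nd$kind == "boundary"]
  if (!known_inlet) ids <- setdiff(ids, nd$node_id[nd$is_known_inlet])
  ids
}

#' Tidy a vascular network into its segment table
#'
#' @param x A `vasc_network`.
#' @param ... Unused.
#' @return A tibble of segments with geometry in micrometres.
#' @method tidy vasc_network
#' @export
tidy.vasc_network <- function(x, ...) {
  x$segments |>
    mutate(diameter_um = m_to_um(.data$diameter),
           length_um = m_to_um(.data$length)) |>
    select("segment_id", "node_a", "node_b", "diameter_um", "length_um",
           "vessel_class", "observed_direction")
}
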