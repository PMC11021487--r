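#' Read a vascular network from disk
#'
#' Two formats are supported. `edge_list_csv` is a pair of UTF-8 CSV files:
#' a segment file with header
#' `segment_id,node_a,node_b,diameter_um,length_um,vessel_class,observed_direction`
#' and a companion node file (same path with `_nodes` appended to the stem)
#' with header `node_id,kind,x_um,y_um,is_known_inlet` (`x_um`/`y_um`
#' optional). `graphml` is a single GraphML file carrying the same attribute
#' names. With `format = "auto"` the format is chosen from the extension
#' (`.graphml`/`.xml` for GraphML, anything else CSV).
#'
#' Geometry is converted from micrometres to SI metres on load and the
#' network is validated; invalid networks are rejected with the full
#' violation list.
#'
#' @param path Path to the segment CSV or the GraphML file.
#' @param format `"auto"`, `"edge_list_csv"` or `"graphml"`.
#' @return A validated [vasc_network()].
#' @seealso [write_network()]
#' @export
read_network <- function(path, format = c("auto", "edge_list_csv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(graphml|xml)$", path, ignore.case = TRUE)) {
      "graphml"
    } else {
      "edge_list_csv"
    }
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "edge_list_csv") {
    read_network_csv(path)
  } else {
    read_network_graphml(path)
  }
}

node_file_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "", path) |>
    paste0("_nodes.csv")
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("format error in ", what, ": missing required column(s) ",
                 toString(missing)))
  }
}

read_network_csv <- function(path) {
  seg_cols <- c("segment_id", "node_a", "node_b", "diameter_um", "length_um",
                "vessel_class", "observed_direction")
  node_cols <- c("node_id", "kind", "is_known_inlet")
  segs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(segs, seg_cols, paste0("segment file ", basename(path)))
  npath <- node_file_path(path)
  if (!file.exists(npath)) {
    abort(paste0("companion node file not found: ", npath))
  }
  nodes <- readr::read_csv(npath, show_col_types = FALSE, progress = FALSE)
  check_columns(nodes, node_cols, paste0("node file ", basename(npath)))
  vasc_network(nodes = nodes, segments = segs)
}

read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- tibble(
    node_id = va$name,
    kind = va$kind,
    x_um = va$x_um %||% NA_real_,
    y_um = va$y_um %||% NA_real_,
    is_known_inlet = as.logical(va$is_known_inlet)
  )
  el <- igraph::as_edgelist(g, names = TRUE)
  ea <- igraph::edge_attr(g)
  check_columns(as_tibble(ea),
                c("segment_id", "diameter_um", "length_um", "vessel_class",
                  "observed_direction"),
                paste0("graphml edges of ", basename(path)))
  segs <- tibble(
    segment_id = ea$segment_id,
    node_a = el[, 1],
    node_b = el[, 2],
    diameter_um = ea$diameter_um,
    length_um = ea$length_um,
    vessel_class = ea$vessel_class,
    observed_direction = ea$observed_direction
  )
  cls <- igraph::graph_attr(g, "network_class")
  vasc_network(nodes, segs, network_class = if (is.null(cls)) NULL else cls)
}

#' Write a vascular network to disk
#'
#' Inverse of [read_network()]; `read_network(write_network(n, path))`
#' reproduces every field. The network is validated before writing, so
#' invalid networks (for example with no segments) are rejected.
#'
#' @param network A valid `vasc_network`.
#' @param path Output path: the segment CSV (a `_nodes.csv` companion is
#'   written next to it) or the `.graphml` file.
#' @param format `"auto"`, `"edge_list_csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("auto", "edge_list_csv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(graphml|xml)$", path, ignore.case = TRUE)) {
      "graphml"
    } else {
      "edge_list_csv"
    }
  }
  report <- validate_network(network)
  if (nrow(report) > 0) {
    abort(c("refusing to write invalid network",
            stats::setNames(report$message, rep("x", nrow(report)))))
  }
  if (format == "edge_list_csv") {
    readr::write_csv(tidy(network), path, progress = FALSE)
    readr::write_csv(network$nodes, node_file_path(path), progress = FALSE)
  } else {
    segs <- tidy(network)
    g <- igraph::graph_from_data_frame(
      segs[, c("node_a", "node_b", "segment_id", "diameter_um", "length_um",
               "vessel_class", "observed_direction")],
      directed = FALSE, vertices = network$nodes
    )
    g <- igraph::set_graph_attr(g, "network_class", network$network_class)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
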