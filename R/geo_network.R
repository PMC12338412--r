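#' Free-flow travel time across a road edge
#'
#' Converts an edge's length and posted speed limit into minutes of
#' free-flow driving time: `(length_m / 1000) / speed_kmh * 60`. This is
#' the edge weight used for all service-zone computations; congestion is
#' never part of the theoretical zone analysis.
#'
#' @param length_m Edge length in meters (vector allowed, each `>= 0`).
#' @param speed_kmh Posted speed limit in km/h (each `> 0`).
#' @return Travel time in minutes, same length as the inputs.
#' @examples
#' edge_travel_time(1000, 60)  # 1 minute
#' edge_travel_time(2500, 50)  # 3 minutes
#' @export
edge_travel_time <- function(length_m, speed_kmh) {
  if (any(is.na(length_m)) || any(length_m < 0)) {
    stop("`length_m` must be non-negative and non-missing", call. = FALSE)
  }
  if (any(is.na(speed_kmh)) || any(speed_kmh <= 0)) {
    stop("`speed_kmh` must be strictly positive", call. = FALSE)
  }
  (length_m / 1000) / speed_kmh * 60
}

#' Construct a road network
#'
#' Builds a weighted directed graph from a node table and an edge table.
#' Each edge contributes a forward arc and, unless flagged one-way, a
#' reverse arc; arc weights are free-flow minutes from
#' [edge_travel_time()]. The graph may be disconnected.
#'
#' @param nodes Data frame with columns `id`, `lon`, `lat`.
#' @param edges Data frame with columns `node_a`, `node_b`, `length_m`,
#'   `speed_kmh` and optionally logical `oneway` (default `FALSE`,
#'   i.e. bidirectional).
#' @return An object of class `road_network`: a list with the validated
#'   `nodes` and `edges` tibbles and the underlying `igraph` graph.
#' @export
road_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("id", "lon", "lat") %in% names(nodes)),
            all(c("node_a", "node_b", "length_m", "speed_kmh") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (nrow(edges) > 0 && any(edges$length_m <= 0)) {
    stop("edge lengths must be positive", call. = FALSE)
  }
  if (nrow(edges) > 0 && any(edges$speed_kmh <= 0)) {
    stop("edge speed limits must be positive", call. = FALSE)
  }
  if (!"oneway" %in% names(edges)) edges$oneway <- FALSE
  edges$oneway[is.na(edges$oneway)] <- FALSE
  ids <- as.character(nodes$id)
  bad <- setdiff(c(as.character(edges$node_a), as.character(edges$node_b)), ids)
  if (length(bad) > 0) {
    stop("edge endpoints not in node table: ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  minutes <- if (nrow(edges) > 0) edge_travel_time(edges$length_m, edges$speed_kmh) else numeric(0)
  fwd <- data.frame(from = as.character(edges$node_a),
                    to = as.character(edges$node_b),
                    weight = minutes)
  rev <- fwd[!edges$oneway, c("to", "from", "weight")]
  names(rev) <- c("from", "to", "weight")
  arcs <- rbind(fwd, rev)
  g <- igraph::graph_from_data_frame(
    arcs,
    directed = TRUE,
    vertices = data.frame(name = ids, lon = nodes$lon, lat = nodes$lat)
  )
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat("<road_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

assert_nodes_exist <- function(network, ids, what) {
  missing <- setdiff(as.character(ids), as.character(network$nodes$id))
  if (length(missing) > 0) {
    stop("unknown ", what, " node id(s): ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
}

#' Shortest free-flow travel time to the nearest target
#'
#' Dijkstra least-cost travel time (minutes) from each origin node to the
#' closest of a set of target nodes. Unreachable origins (no target in
#' their connected component) return `Inf`.
#'
#' @param network A [road_network()].
#' @param origin Origin node id(s).
#' @param targets Non-empty vector of target node ids.
#' @return Numeric vector of minutes, one per origin; `Inf` when no
#'   target is reachable.
#' @export
shortest_travel_time <- function(network, origin, targets) {
  stopifnot(inherits(network, "road_network"))
  if (length(targets) == 0) stop("`targets` must be non-empty", call. = FALSE)
  assert_nodes_exist(network, origin, "origin")
  assert_nodes_exist(network, targets, "target")
  d <- igraph::distances(network$graph,
                         v = as.character(origin),
                         to = as.character(unique(targets)),
                         mode = "out")
  apply(d, 1, min)
}

#' Assign a travel-time service band
#'
#' Maps minutes to the smallest band threshold that is greater than or
#' equal to the value (upper-edge inclusive: 30.0 minutes is in `B30`).
#' Times beyond the last threshold, and unreachable (`Inf`) times, map to
#' `BEYOND`.
#'
#' @param minutes Non-negative minutes (may be `Inf`).
#' @param thresholds Strictly increasing positive band edges
#'   (default 15/30/45/60).
#' @return Factor with levels `B15, B30, B45, B60, BEYOND` (for the
#'   default thresholds).
#' @export
service_band <- function(minutes, thresholds = DEFAULT_BAND_THRESHOLDS) {
  check_thresholds(thresholds)
  if (any(is.na(minutes)) || any(minutes < 0)) {
    stop("`minutes` must be non-negative and non-missing", call. = FALSE)
  }
  labs <- band_labels(thresholds)
  idx <- vapply(minutes, function(m) sum(m > thresholds) + 1L, integer(1))
  factor(labs[idx], levels = labs)
}

check_thresholds <- function(thresholds) {
  if (length(thresholds) < 1 || any(thresholds <= 0) ||
      any(diff(thresholds) <= 0)) {
    stop("band thresholds must be positive and strictly increasing", call. = FALSE)
  }
  invisible(thresholds)
}

#' Service-band map for dispatch centers
#'
#' For every dispatch center, the minimal free-flow travel time to any
#' level 1/2 trauma center and the service band it falls in. This is the
#' network service-zone analysis that groups dispatch centers by their
#' theoretical access to definitive trauma care.
#'
#' @param network A [road_network()].
#' @param dispatch_centers Tibble with `id` and `node_id` (see
#'   [attach_points()]).
#' @param facilities Tibble with `id`, `level` and `node_id`; at least one
#'   facility must be `LEVEL1` or `LEVEL2`.
#' @param thresholds Band edges in minutes.
#' @return Tibble `dispatch_id`, `minutes`, `band` with one row per
#'   dispatch center.
#' @export
assign_dispatch_bands <- function(network, dispatch_centers, facilities,
                                  thresholds = DEFAULT_BAND_THRESHOLDS) {
  tc_nodes <- facilities$node_id[facilities$level %in% c("LEVEL1", "LEVEL2")]
  if (length(tc_nodes) == 0) {
    stop("no LEVEL1/LEVEL2 facility attached to the network", call. = FALSE)
  }
  minutes <- shortest_travel_time(network, dispatch_centers$node_id, tc_nodes)
  tibble(dispatch_id = dispatch_centers$id,
         minutes = unname(minutes),
         band = service_band(minutes, thresholds))
}

#' Nodes reachable within a travel-time threshold
#'
#' All network nodes whose shortest free-flow travel time from the nearest
#' source node is at most `threshold` minutes. Sources are always
#' included. Supports exporting service-zone layers.
#'
#' @param network A [road_network()].
#' @param sources Non-empty vector of source node ids.
#' @param threshold Positive minutes.
#' @return Character vector of node ids.
#' @export
reachable_set <- function(network, sources, threshold) {
  stopifnot(inherits(network, "road_network"))
  if (length(sources) == 0) stop("`sources` must be non-empty", call. = FALSE)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  assert_nodes_exist(network, sources, "source")
  d <- igraph::distances(network$graph,
                         v = as.character(unique(sources)),
                         to = igraph::V(network$graph),
                         mode = "out")
  best <- apply(d, 2, min)
  names(best)[best <= threshold]
}

#' Snap points to their nearest network node
#'
#' Attaches each point (facility or dispatch center) to the closest
#' network node by great-circle (haversine) distance. Haversine distance
#' is used only for snapping, never for travel time.
#'
#' @param points Tibble with `lon` and `lat` columns.
#' @param network A [road_network()].
#' @return `points` with a `node_id` column added (or overwritten).
#' @export
attach_points <- function(points, network) {
  stopifnot(inherits(network, "road_network"),
            all(c("lon", "lat") %in% names(points)))
  nd <- cbind(network$nodes$lon, network$nodes$lat)
  idx <- vapply(seq_len(nrow(points)), function(i) {
    which.min(geosphere::distHaversine(c(points$lon[i], points$lat[i]), nd))
  }, integer(1))
  points$node_id <- as.character(network$nodes$id[idx])
  points
}
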