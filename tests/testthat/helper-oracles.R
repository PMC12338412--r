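# Independent oracles for property-style tests. These deliberately avoid
# igraph and dplyr: shortest times come from exhaustive DFS enumeration
# of simple paths, tallies from base table()/sum().

# Exhaustive simple-path shortest travel time over raw node/edge tables.
oracle_shortest <- function(nodes, edges, origin, targets) {
  minutes <- (edges$length_m / 1000) / edges$speed_kmh * 60
  oneway <- if ("oneway" %in% names(edges)) edges$oneway else rep(FALSE, nrow(edges))
  from <- c(as.character(edges$node_a), as.character(edges$node_b[!oneway]))
  to <- c(as.character(edges$node_b), as.character(edges$node_a[!oneway]))
  w <- c(minutes, minutes[!oneway])
  targets <- as.character(targets)
  best <- Inf
  visit <- function(node, cost, seen) {
    if (cost >= best) return(invisible(NULL))
    if (node %in% targets) best <<- cost
    idx <- which(from == node & !(to %in% seen))
    for (i in idx) visit(to[i], cost + w[i], c(seen, to[i]))
    invisible(NULL)
  }
  visit(as.character(origin), 0, as.character(origin))
  best
}

# Random small road network for property tests; may be disconnected.
random_road_network <- function(n_nodes = sample(3:8, 1), p_edge = 0.4) {
  nodes <- data.frame(id = paste0("v", seq_len(n_nodes)),
                      lon = runif(n_nodes, 46, 47),
                      lat = runif(n_nodes, 24, 25))
  pairs <- t(combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  edges <- data.frame(node_a = paste0("v", pairs[keep, 1]),
                      node_b = paste0("v", pairs[keep, 2]),
                      length_m = runif(sum(keep), 500, 8000),
                      speed_kmh = sample(c(30, 50, 80, 120), sum(keep),
                                         replace = TRUE),
                      oneway = FALSE)
  list(nodes = nodes, edges = edges,
       network = road_network(nodes, edges))
}

# The red-criteria rule written out directly as the stated disjunction,
# scalar, for boundary-grid comparison against the vectorized classifier.
oracle_red <- function(age, sbp, hr, penetrating) {
  if (penetrating) return(TRUE)
  if (is.na(age)) age <- 40  # adult thresholds when age unknown
  if (age >= 14 && age <= 64 && (!is.na(sbp) && sbp < 90 ||
                                 (!is.na(sbp) && !is.na(hr) && hr > sbp))) {
    return(TRUE)
  }
  if (age >= 65 && (!is.na(sbp) && sbp < 110 ||
                    (!is.na(sbp) && !is.na(hr) && hr > sbp))) {
    return(TRUE)
  }
  FALSE
}
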