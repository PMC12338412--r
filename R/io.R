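# GeoJSON point/linestring layers are read and written directly with
# jsonlite: the layers used here are flat FeatureCollections, so a thin
# translation to/from tibbles keeps the on-disk format standard without
# pulling in a full spatial stack.

#' Write a tibble of points as a GeoJSON FeatureCollection
#'
#' @param df Tibble with `lon` and `lat` columns; all other columns
#'   become feature properties.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(df, path) {
  stopifnot(all(c("lon", "lat") %in% names(df)))
  props <- setdiff(names(df), c("lon", "lat"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    p <- as.list(df[i, props, drop = FALSE])
    p <- lapply(p, function(v) if (is.factor(v)) as.character(v) else v)
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])),
         properties = p)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a GeoJSON Point FeatureCollection into a tibble
#'
#' @param path GeoJSON file path.
#' @return Tibble with `lon`, `lat` and one column per property.
#' @export
read_geojson_points <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  rows <- lapply(feats, function(f) {
    p <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    c(list(lon = f$geometry$coordinates[[1]],
           lat = f$geometry$coordinates[[2]]), p)
  })
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

coord_key <- function(lon, lat) paste0(round(lon, 7), "_", round(lat, 7))

#' Write a road network as a GeoJSON LineString layer
#'
#' Each edge becomes a two-point LineString with properties `length_m`,
#' `speed_kmh` and `oneway`.
#'
#' @param network A [road_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_road_network_geojson <- function(network, path) {
  nodes <- network$nodes
  edges <- network$edges
  xy <- function(id) {
    i <- match(as.character(id), as.character(nodes$id))
    c(nodes$lon[i], nodes$lat[i])
  }
  features <- lapply(seq_len(nrow(edges)), function(i) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(xy(edges$node_a[i]),
                                            xy(edges$node_b[i]))),
         properties = list(length_m = edges$length_m[i],
                           speed_kmh = edges$speed_kmh[i],
                           oneway = isTRUE(edges$oneway[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a road network from a GeoJSON LineString layer
#'
#' Node ids are synthesized from rounded coordinates, so shared endpoints
#' join into a single node.
#'
#' @param path GeoJSON file path with LineString features carrying
#'   `length_m` and `speed_kmh` (and optionally `oneway`) properties.
#' @return A [road_network()].
#' @export
read_road_network_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  ea <- character(length(feats)); eb <- character(length(feats))
  lons <- c(); lats <- c(); keys <- c()
  len <- numeric(length(feats)); spd <- numeric(length(feats))
  onew <- logical(length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    cc <- f$geometry$coordinates
    a <- unlist(cc[[1]]); b <- unlist(cc[[length(cc)]])
    ka <- coord_key(a[1], a[2]); kb <- coord_key(b[1], b[2])
    for (k in list(c(ka, a), c(kb, b))) {
      if (!(k[1] %in% keys)) {
        keys <- c(keys, k[1])
        lons <- c(lons, as.numeric(k[2])); lats <- c(lats, as.numeric(k[3]))
      }
    }
    ea[i] <- ka; eb[i] <- kb
    len[i] <- f$properties$length_m
    spd[i] <- f$properties$speed_kmh
    onew[i] <- isTRUE(f$properties$oneway)
  }
  road_network(tibble(id = keys, lon = lons, lat = lats),
               tibble(node_a = ea, node_b = eb, length_m = len,
                      speed_kmh = spd, oneway = onew))
}

#' Read a road network from node and edge CSV files
#'
#' @param nodes_path CSV with columns `id`, `lon`, `lat`.
#' @param edges_path CSV with columns `node_a`, `node_b`, `length_m`,
#'   `speed_kmh` and optionally `oneway`.
#' @return A [road_network()].
#' @export
read_road_network_csv <- function(nodes_path, edges_path) {
  nodes <- read.csv(nodes_path, stringsAsFactors = FALSE)
  edges <- read.csv(edges_path, stringsAsFactors = FALSE)
  if ("oneway" %in% names(edges)) edges$oneway <- as.logical(edges$oneway)
  road_network(nodes, edges)
}

#' Write a road network to node and edge CSV files
#'
#' @param network A [road_network()].
#' @param nodes_path,edges_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_road_network_csv <- function(network, nodes_path, edges_path) {
  write.csv(network$nodes, nodes_path, row.names = FALSE)
  write.csv(network$edges, edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

REGISTRY_COLUMNS <- c("id", "timestamp", "dispatch_center_id", "region",
                      "age", "sex", "sbp", "hr", "mechanism_code",
                      "trauma_flag", "outcome_recorded",
                      "destination_facility_id", "observed_travel_time")

#' Validate an incident registry table against the expected schema
#'
#' @param df Data frame to validate.
#' @return List with `ok` (logical) and `problems` (character vector of
#'   human-readable findings; empty when `ok`).
#' @export
validate_registry <- function(df) {
  problems <- character(0)
  missing <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing) > 0) {
    problems <- c(problems,
                  paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in intersect(c("age", "sbp", "hr", "observed_travel_time"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- sum(!is.na(df[[col]]) & is.na(v))
    if (bad > 0) {
      problems <- c(problems, paste0(bad, " non-numeric value(s) in ", col))
    }
  }
  list(ok = length(problems) == 0, problems = problems)
}

#' Read an incident registry CSV
#'
#' Parses the registry schema (see [validate_registry()]) and emits a
#' validation warning listing any schema problems.
#'
#' @param path CSV file path with a header row.
#' @return Tibble of incident records.
#' @export
read_registry <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  v <- validate_registry(df)
  if (!v$ok) {
    warning("registry schema problems: ", paste(v$problems, collapse = "; "),
            call. = FALSE)
  }
  for (col in intersect(c("age", "sbp", "hr", "observed_travel_time",
                          "network_travel_time"), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  for (col in intersect(c("trauma_flag", "outcome_recorded"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  for (col in intersect(c("id", "timestamp", "dispatch_center_id", "region",
                          "sex", "mechanism_code", "destination_facility_id"),
                        names(df))) {
    df[[col]] <- as.character(df[[col]])
  }
  as_tibble(df)
}

#' Write an incident registry CSV
#' @param records Registry tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write / read a service-band map as CSV
#'
#' @param band_map Tibble from [assign_dispatch_bands()].
#' @param path CSV file path.
#' @param thresholds Band thresholds used to restore the factor levels on
#'   read.
#' @return The band map (read) or `path` invisibly (write).
#' @export
write_band_map <- function(band_map, path) {
  out <- band_map
  out$band <- as.character(out$band)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_map
#' @export
read_band_map <- function(path, thresholds = DEFAULT_BAND_THRESHOLDS) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$band <- factor(df$band, levels = band_labels(thresholds))
  as_tibble(df)
}

#' Write an exclusion-flow report as JSON
#'
#' Emits both the sequential (first-match) and the overlap-tolerant
#' counts so the cohort-selection flow is auditable.
#'
#' @param tally An `exclusion_tally` from [apply_inclusion_filters()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_flow_report <- function(tally, path) {
  jsonlite::write_json(
    list(total = tally$total,
         included = tally$included,
         sequential = list(malformed = tally$malformed,
                           missing_outcome = tally$missing_outcome,
                           outside_region = tally$outside_region,
                           pediatric = tally$pediatric,
                           nontrauma = tally$nontrauma),
         overlap = as.list(tally$overlap)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
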