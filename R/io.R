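# Input loading and cross-reference validation: the GeoJSON/CSV file set
# (as written by write_town() or prepared externally) into a `town`.

#' Load and validate the standard input file set
#'
#' Reads buildings, roads, sites, optional barriers (GeoJSON, planar metre
#' coordinates) and the roster CSV, validates every cross-reference
#' (roster building ids resolve; road endpoints snap to shared nodes) and
#' assembles a `town`. Diagnostics name the offending ids.
#'
#' @param buildings path to buildings GeoJSON (Polygon or Point features
#'   with `id` and optionally `group_id`, `structure`, `floors`,
#'   `year_built`)
#' @param roads path to roads GeoJSON (LineString features with `width`)
#' @param sites path to evacuation-site GeoJSON (Point features)
#' @param roster path to roster CSV (`resident_id`, `building_id`,
#'   `group_id`, `age`, `gender`, `needs_assistance`, optionally
#'   `household_id`, `commuter`)
#' @param barriers optional path to barriers GeoJSON
#' @return a `town`
#' @export
load_inputs <- function(buildings, roads, sites, roster, barriers = NULL) {
  bj <- read_geojson(buildings)
  rj <- read_geojson(roads)
  sj <- read_geojson(sites)
  ros <- utils::read.csv(roster, stringsAsFactors = FALSE)

  cent <- geojson_centroids(bj)
  b <- data.frame(
    id = as.integer(geojson_property(bj, "id", NA_integer_)),
    group_id = as.integer(geojson_property(bj, "group_id", 1L)),
    x = cent[, "x"], y = cent[, "y"],
    structure = as.character(geojson_property(bj, "structure", "wood")),
    floors = as.integer(geojson_property(bj, "floors", 1L)),
    year_built = as.integer(geojson_property(bj, "year_built", 1990L))
  )
  if (any(is.na(b$id)) || anyDuplicated(b$id)) {
    stop("buildings must carry unique integer 'id' properties")
  }
  # footprint bounding boxes (point features get a nominal 9 m footprint)
  bbox <- t(vapply(bj$features, function(f) {
    g <- f$geometry
    if (identical(g$type, "Point")) {
      p <- as.numeric(g$coordinates[1:2])
      c(p[1] - 4.5, p[2] - 4.5, p[1] + 4.5, p[2] + 4.5)
    } else {
      m <- flatten_coords(g$coordinates)
      c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2]))
    }
  }, numeric(4)))
  b$xmin <- bbox[, 1]; b$ymin <- bbox[, 2]
  b$xmax <- bbox[, 3]; b$ymax <- bbox[, 4]

  # snap road endpoints to shared nodes
  ends <- lapply(rj$features, function(f) flatten_coords(f$geometry$coordinates))
  all_pts <- unique(do.call(rbind, lapply(ends, function(m) {
    round(m[c(1, nrow(m)), , drop = FALSE], 6)
  })))
  nodes <- data.frame(id = seq_len(nrow(all_pts)),
                      x = all_pts[, 1], y = all_pts[, 2])
  find_node <- function(x, y) {
    i <- which(abs(nodes$x - x) < 1e-6 & abs(nodes$y - y) < 1e-6)
    if (!length(i)) stop("road endpoint (", x, ", ", y,
                         ") does not snap to a node")
    i[1]
  }
  links <- do.call(rbind, lapply(seq_along(ends), function(i) {
    m <- ends[[i]]
    from <- find_node(m[1, 1], m[1, 2])
    to <- find_node(m[nrow(m), 1], m[nrow(m), 2])
    data.frame(from = from, to = to,
               width = as.numeric(rj$features[[i]]$properties$width %||% 4))
  }))
  links$id <- seq_len(nrow(links))
  links$length <- sqrt((nodes$x[links$to] - nodes$x[links$from])^2 +
                         (nodes$y[links$to] - nodes$y[links$from])^2)
  if (any(links$width <= 0)) stop("road widths must be positive")
  links <- links[, c("id", "from", "to", "width", "length")]

  sc <- geojson_centroids(sj)
  site_node <- vapply(seq_len(nrow(sc)), function(i) {
    which.min((nodes$x - sc[i, "x"])^2 + (nodes$y - sc[i, "y"])^2)
  }, integer(1))
  s <- data.frame(id = seq_len(nrow(sc)), node = site_node,
                  x = sc[, "x"], y = sc[, "y"])

  bar <- if (!is.null(barriers) && file.exists(barriers)) {
    barrier_segments(read_geojson(barriers))
  } else {
    barrier_segments(NULL)
  }

  need <- c("resident_id", "building_id", "group_id", "age", "gender")
  missing_cols <- setdiff(need, names(ros))
  if (length(missing_cols)) {
    stop("roster is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dangling <- setdiff(unique(ros$building_id), b$id)
  if (length(dangling)) {
    stop("roster references missing building id(s): ",
         paste(dangling, collapse = ", "))
  }
  if (!all(ros$gender %in% c("male", "female"))) {
    stop("roster 'gender' must be \"male\" or \"female\"")
  }
  if (!is.null(ros$needs_assistance)) {
    ros$needs_assistance <- as.logical(ros$needs_assistance) |
      (ros$needs_assistance %in% c(1, "1"))
  }
  if (!is.null(ros$commuter)) {
    ros$commuter <- as.logical(ros$commuter) | (ros$commuter %in% c(1, "1"))
  }
  if (is.null(ros$household_id)) ros$household_id <- ros$resident_id

  b$node <- vapply(seq_len(nrow(b)), function(i) {
    which.min((nodes$x - b$x[i])^2 + (nodes$y - b$y[i])^2)
  }, integer(1))

  pad <- 6
  extent <- c(xmin = min(b$xmin, nodes$x) - pad,
              ymin = min(b$ymin, nodes$y) - pad,
              xmax = max(b$xmax, nodes$x) + pad,
              ymax = max(b$ymax, nodes$y) + pad)
  structure(list(nodes = nodes, links = links, buildings = b, sites = s,
                 barriers = bar, roster = ros, extent = extent,
                 spec = NULL),
            class = "town")
}

#' Load a YAML run configuration
#'
#' A structured configuration file can carry any of the CLI's options in
#' named blocks (`inputs:`, `capability:`, `hazard:`, `scenario:`,
#' `seed:`, `out:`). Used by the CLI's `--config` option; explicit
#' command-line flags override file values.
#'
#' @param path YAML file path
#' @return named list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping: ", path)
  cfg
}
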