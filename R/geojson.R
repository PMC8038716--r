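# Minimal GeoJSON (RFC 7946) reading/writing over jsonlite. Geometries are
# kept as nested coordinate lists exactly as parsed; helpers extract the
# pieces the package needs (points, line endpoints, polygon rings).
# Coordinates are assumed already projected in metres (CRS declared in the
# run configuration, not in the files).

#' Read a GeoJSON FeatureCollection
#'
#' @param path file path
#' @return list with class `geojson`: `features` (list of features, each
#'   with `geometry` and `properties`)
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  structure(list(features = obj$features), class = "geojson")
}

#' Write a GeoJSON FeatureCollection
#'
#' @param x a `geojson` object (or bare feature list)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_geojson <- function(x, path) {
  feats <- if (inherits(x, "geojson")) x$features else x
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Build a GeoJSON feature
#'
#' @param geometry_type e.g. `"Point"`, `"LineString"`, `"Polygon"`
#' @param coordinates coordinates in GeoJSON nesting
#' @param properties named list of properties
#' @return a feature list
#' @export
geojson_feature <- function(geometry_type, coordinates, properties = list()) {
  list(type = "Feature",
       geometry = list(type = geometry_type, coordinates = coordinates),
       properties = properties)
}

#' @export
print.geojson <- function(x, ...) {
  types <- vapply(x$features, function(f) f$geometry$type %||% "?", "")
  cat("<geojson> ", length(x$features), " features (",
      paste(names(table(types)), table(types), sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# ---- extraction helpers ----------------------------------------------------

geojson_property <- function(gj, name, default = NA) {
  vapply(gj$features, function(f) {
    v <- f$properties[[name]]
    if (is.null(v)) default else v
  }, FUN.VALUE = default)
}

# representative point of any feature: point coords, or bounding-box centre
# (closed polygon rings repeat their first vertex, so a vertex mean is biased)
geojson_centroids <- function(gj) {
  out <- t(vapply(gj$features, function(f) {
    g <- f$geometry
    if (identical(g$type, "Point")) {
      as.numeric(g$coordinates[1:2])
    } else {
      m <- flatten_coords(g$coordinates)
      c((min(m[, 1]) + max(m[, 1])) / 2, (min(m[, 2]) + max(m[, 2])) / 2)
    }
  }, numeric(2)))
  colnames(out) <- c("x", "y")
  out
}

flatten_coords <- function(coords) {
  if (is.numeric(coords[[1]])) {
    do.call(rbind, lapply(list(coords), function(p) as.numeric(p[1:2])))
  } else if (is.numeric(coords[[1]][[1]])) {
    do.call(rbind, lapply(coords, function(p) as.numeric(p[1:2])))
  } else {
    do.call(rbind, lapply(coords, flatten_coords))
  }
}

# rectangle polygon ring (closed) for building footprints
rect_ring <- function(xmin, ymin, xmax, ymax) {
  list(list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
            c(xmin, ymax), c(xmin, ymin)))
}
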