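# Planar geometry predicates. All coordinates are projected metres; no
# geodesic computation anywhere in the package.

#' Do two line segments intersect?
#'
#' Standard orientation-test segment intersection, including collinear
#' overlap and shared endpoints. Used for the barrier rule: a neighbour
#' building (or a victim, for perception) is excluded when the straight
#' segment between the two points crosses any barrier feature.
#'
#' @param p1,p2 numeric length-2, endpoints of the first segment
#' @param q1,q2 numeric length-2, endpoints of the second segment
#' @return logical scalar
#' @export
segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  o1 <- orient(p1, p2, q1)
  o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1)
  o4 <- orient(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, q1)) ||
    (o2 == 0 && on_seg(p1, p2, q2)) ||
    (o3 == 0 && on_seg(q1, q2, p1)) ||
    (o4 == 0 && on_seg(q1, q2, p2))
}

#' Decompose barrier features into a segment matrix
#'
#' Accepts a "barrier set": either a geometry list as returned by
#' [read_geojson()] (LineString / Polygon features) or a plain numeric
#' matrix of segments. Polygon rings contribute their boundary segments.
#'
#' @param barriers barrier features, or `NULL` for none
#' @return numeric matrix with columns x1, y1, x2, y2 (0 rows if none)
#' @export
barrier_segments <- function(barriers) {
  empty <- matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  if (is.null(barriers)) return(empty)
  if (is.matrix(barriers)) {
    stopifnot(ncol(barriers) == 4)
    colnames(barriers) <- c("x1", "y1", "x2", "y2")
    return(barriers)
  }
  feats <- if (!is.null(barriers$features)) barriers$features else barriers
  segs <- list()
  add_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) as.numeric(p[1:2])))
    if (nrow(m) >= 2) {
      segs[[length(segs) + 1]] <<- cbind(
        m[-nrow(m), 1], m[-nrow(m), 2], m[-1, 1], m[-1, 2]
      )
    }
  }
  for (f in feats) {
    g <- f$geometry %||% f
    type <- g$type %||% ""
    if (identical(type, "LineString")) {
      add_ring(g$coordinates)
    } else if (identical(type, "Polygon")) {
      for (ring in g$coordinates) add_ring(ring)
    } else if (identical(type, "MultiLineString")) {
      for (line in g$coordinates) add_ring(line)
    }
  }
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  colnames(out) <- c("x1", "y1", "x2", "y2")
  out
}

#' Does a sight line cross any barrier segment?
#'
#' @param x1,y1,x2,y2 endpoints of the sight line (metres)
#' @param segs segment matrix from [barrier_segments()]
#' @return logical scalar
#' @export
crosses_barrier <- function(x1, y1, x2, y2, segs) {
  if (is.null(segs) || nrow(segs) == 0) return(FALSE)
  # cheap bounding-box rejection first
  lo_x <- pmin(segs[, 1], segs[, 3]); hi_x <- pmax(segs[, 1], segs[, 3])
  lo_y <- pmin(segs[, 2], segs[, 4]); hi_y <- pmax(segs[, 2], segs[, 4])
  keep <- hi_x >= min(x1, x2) & lo_x <= max(x1, x2) &
    hi_y >= min(y1, y2) & lo_y <= max(y1, y2)
  for (i in which(keep)) {
    if (segments_intersect(c(x1, y1), c(x2, y2),
                           segs[i, 1:2], segs[i, 3:4])) {
      return(TRUE)
    }
  }
  FALSE
}

# perpendicular distance from points (px, py) to segment (ax,ay)-(bx,by),
# vectorised over points
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}
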