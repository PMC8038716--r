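# 3 m x 3 m grid-cell field for the hazard models. The evacuation itself
# runs on the road network (network model); the grid carries only the
# damage state (building cells, fire), so the two hybrid representations
# match the simulator structure: grid for hazards, network for routes.

#' Rasterize a town onto the 3 m hazard grid
#'
#' Classifies every cell as building, road or open. Cell size is fixed at
#' 3 m (the field's evaluation unit). A cell belongs to a building when its
#' centre falls inside the footprint; every building claims at least its
#' centroid cell. Road cells are cells whose centre lies within half the
#' road width of the link centreline; where a building and a road would
#' claim the same cell, the building wins (documented precedence).
#'
#' @param town a `town` from [generate_town()] (or any list with `nodes`,
#'   `links`, `buildings`, `extent`)
#' @param cell_size cell edge in metres; fixed at 3
#' @return list of class `grid_field`: `origin`, `cell_size`, `n_rows`,
#'   `n_cols`, `building` (matrix of building ids, 0 = none), `link`
#'   (matrix of link ids, 0 = none), `building_cells` (list of cell indices
#'   per building id)
#' @export
rasterize_town <- function(town, cell_size = 3) {
  stopifnot(cell_size == 3)  # the model's evaluation unit
  ext <- town$extent
  b <- town$buildings
  if (nrow(b) > 0 &&
      (any(b$xmin < ext["xmin"]) || any(b$xmax > ext["xmax"]) ||
       any(b$ymin < ext["ymin"]) || any(b$ymax > ext["ymax"]))) {
    stop("building footprint outside the town extent")
  }
  n_cols <- max(1L, as.integer(ceiling((ext["xmax"] - ext["xmin"]) / cell_size)))
  n_rows <- max(1L, as.integer(ceiling((ext["ymax"] - ext["ymin"]) / cell_size)))
  cx <- ext[["xmin"]] + (seq_len(n_cols) - 0.5) * cell_size
  cy <- ext[["ymin"]] + (seq_len(n_rows) - 0.5) * cell_size

  building <- matrix(0L, n_rows, n_cols)
  building_cells <- vector("list", nrow(b))
  for (i in seq_len(nrow(b))) {
    cols <- which(cx >= b$xmin[i] & cx < b$xmax[i])
    rows <- which(cy >= b$ymin[i] & cy < b$ymax[i])
    if (!length(cols) || !length(rows)) {
      cols <- which.min(abs(cx - b$x[i]))
      rows <- which.min(abs(cy - b$y[i]))
    }
    idx <- as.vector(outer(rows, (cols - 1) * n_rows, "+"))
    building[idx] <- b$id[i]
    building_cells[[i]] <- idx
  }
  names(building_cells) <- as.character(b$id)

  link <- matrix(0L, n_rows, n_cols)
  l <- town$links
  for (i in seq_len(nrow(l))) {
    ax <- town$nodes$x[l$from[i]]; ay <- town$nodes$y[l$from[i]]
    bx <- town$nodes$x[l$to[i]];  by <- town$nodes$y[l$to[i]]
    half <- l$width[i] / 2
    cols <- which(cx >= min(ax, bx) - half - cell_size &
                    cx <= max(ax, bx) + half + cell_size)
    rows <- which(cy >= min(ay, by) - half - cell_size &
                    cy <= max(ay, by) + half + cell_size)
    if (!length(cols) || !length(rows)) next
    px <- rep(cx[cols], each = length(rows))
    py <- rep(cy[rows], times = length(cols))
    d <- point_segment_distance(px, py, ax, ay, bx, by)
    idx <- as.vector(outer(rows, (cols - 1) * n_rows, "+"))[d <= half]
    idx <- idx[building[idx] == 0L & link[idx] == 0L]
    link[idx] <- l$id[i]
  }

  structure(list(origin = c(x = ext[["xmin"]], y = ext[["ymin"]]),
                 cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
                 building = building, link = link,
                 building_cells = building_cells),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat("<grid_field> ", x$n_rows, " x ", x$n_cols, " cells of ",
      x$cell_size, " m (", sum(x$building > 0), " building, ",
      sum(x$link > 0), " road)\n", sep = "")
  invisible(x)
}

#' Cell classification of a grid field
#'
#' @param field a `grid_field`
#' @return character matrix with entries `"building"`, `"road"`, `"open"`
#' @export
cell_classes <- function(field) {
  cls <- matrix("open", field$n_rows, field$n_cols)
  cls[field$link > 0] <- "road"
  cls[field$building > 0] <- "building"
  cls
}

# links adjacent to each building (for rubble intrusion and fire blocking):
# links whose centreline passes within `max_dist` of the building centroid
building_adjacent_links <- function(town, max_dist = 18) {
  l <- town$links
  n <- town$nodes
  lapply(seq_len(nrow(town$buildings)), function(i) {
    d <- vapply(seq_len(nrow(l)), function(j) {
      point_segment_distance(town$buildings$x[i], town$buildings$y[i],
                             n$x[l$from[j]], n$y[l$from[j]],
                             n$x[l$to[j]], n$y[l$to[j]])
    }, numeric(1))
    l$id[d <= max_dist]
  })
}
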