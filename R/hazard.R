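# Precomputed earthquake damage: building collapse, rubble road blockage and
# wind-biased fire spread. All of it is resolved before the evacuation runs
# and is consumed read-only by the simulator, so a damage situation can be
# held fixed across what-if evacuation scenarios.

#' Default building-collapse probability configuration
#'
#' Collapse probability is looked up by structure and construction-year band
#' and scaled by floor count. The paper trail behind such tables is
#' region-specific engineering work; these defaults encode only the
#' qualitative ordering practitioners expect (old wooden buildings worst,
#' recent reinforced concrete best, probability increasing with storeys) and
#' real studies should supply their own table.
#'
#' @return data.frame with columns `structure`, `year_min`, `year_max`, `p`
#' @export
default_collapse_config <- function() {
  data.frame(
    structure = rep(c("wood", "rc", "steel"), each = 3),
    year_min = rep(c(0, 1981, 2001), 3),
    year_max = rep(c(1980, 2000, 9999), 3),
    p = c(0.30, 0.15, 0.08,   # wood: pre-1981 code, 1981-2000, post-2000
          0.10, 0.05, 0.02,   # reinforced concrete
          0.12, 0.06, 0.03)   # steel
  )
}

#' Per-building collapse probabilities
#'
#' @param buildings data.frame with `structure`, `year_built`, `floors`
#' @param config table from [default_collapse_config()] (or user-supplied)
#' @param floor_factor relative increase in collapse probability per storey
#'   above the first
#' @return numeric vector of probabilities in \[0, 1\]
#' @export
collapse_probability <- function(buildings, config = default_collapse_config(),
                                 floor_factor = 0.15) {
  p <- vapply(seq_len(nrow(buildings)), function(i) {
    hit <- config$structure == buildings$structure[i] &
      config$year_min <= buildings$year_built[i] &
      config$year_max >= buildings$year_built[i]
    if (!any(hit)) {
      stop("no collapse-probability row for building id ", buildings$id[i],
           " (structure=", buildings$structure[i],
           ", year=", buildings$year_built[i], ")")
    }
    config$p[which(hit)[1]]
  }, numeric(1))
  pmin(1, p * (1 + floor_factor * (buildings$floors - 1)))
}

#' Sample collapsed buildings
#'
#' Independent Bernoulli draw per building; reproducible under `seed`.
#'
#' @param buildings buildings data.frame
#' @param config collapse configuration
#' @param seed integer seed
#' @param floor_factor see [collapse_probability()]
#' @return integer vector of collapsed building ids
#' @export
sample_collapses <- function(buildings, config = default_collapse_config(),
                             seed = 1, floor_factor = 0.15) {
  p <- collapse_probability(buildings, config, floor_factor)
  with_seed(seed, buildings$id[stats::runif(nrow(buildings)) < p])
}

#' Rubble intrusion and residual road width
#'
#' A collapsed building spills rubble onto its adjacent road links. The
#' intrusion depth is `min(road width, k * floors * 3)` metres (a building-
#' height proxy; `k` configurable), applied uniformly along each adjacent
#' link; the residual width is the road width minus the largest intrusion,
#' and the link is blocked when the residual width is strictly under 0.6 m
#' (a residual of exactly 0.6 m stays passable).
#'
#' @param town a `town`
#' @param collapsed integer vector of collapsed building ids
#' @param k intrusion scale per storey-height (default 0.5)
#' @param adjacency optional precomputed [building_adjacent_links()] result
#' @return data.frame per link: `link_id`, `width`, `intrusion`, `residual`,
#'   `blocked`
#' @export
generate_rubble <- function(town, collapsed, k = 0.5, adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- building_adjacent_links(town)
  l <- town$links
  intr <- numeric(nrow(l))
  for (i in seq_len(nrow(town$buildings))) {
    bid <- town$buildings$id[i]
    if (!(bid %in% collapsed)) next
    depth <- k * town$buildings$floors[i] * 3
    for (lid in adjacency[[i]]) {
      j <- match(lid, l$id)
      intr[j] <- max(intr[j], min(l$width[j], depth))
    }
  }
  data.frame(link_id = l$id, width = l$width, intrusion = intr,
             residual = l$width - intr,
             blocked = (l$width - intr) < 0.6)
}

#' Fire-spread parameters
#'
#' Wind-biased 8-neighbour cellular-automaton spread on the 3 m grid. Each
#' burning cell ignites each unburned neighbouring building cell per second
#' with probability `p_base * wind_factor`, where the wind factor is
#' `max(0, 1 + wind_bias * wind_speed * cos(theta))` and `theta` is the
#' angle between the spread direction and the downwind direction; the
#' product is clipped to \[0, 1\]. Burning cells burn out after
#' `burn_duration` seconds. `p_base` defaults to 0.005/s per neighbour,
#' which under no wind gives a front speed of a few tens of metres per
#' hour, the order observed in dense wooden urban fires.
#'
#' @param wind_speed metres per second (default 5)
#' @param wind_direction 8-point compass direction the wind blows FROM
#'   (default `"NW"`)
#' @param p_base base per-neighbour per-second ignition probability
#' @param wind_bias bias factor per (m/s) of wind
#' @param burn_duration seconds a cell burns before burning out
#' @param n_origins number of random fire origins
#' @return list of class `fire_params`
#' @export
fire_params <- function(wind_speed = 5, wind_direction = "NW",
                        p_base = 0.005, wind_bias = 0.15,
                        burn_duration = 120, n_origins = 1) {
  dirs <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  stopifnot(wind_direction %in% dirs, p_base >= 0, p_base <= 1,
            wind_speed >= 0, burn_duration >= 1, n_origins >= 0)
  structure(list(wind_speed = wind_speed, wind_direction = wind_direction,
                 p_base = p_base, wind_bias = wind_bias,
                 burn_duration = burn_duration, n_origins = n_origins),
            class = "fire_params")
}

# unit vector of the DOWNWIND direction (wind blows from wind_direction)
downwind_vector <- function(wind_direction) {
  from <- switch(wind_direction,
                 N = c(0, 1), NE = c(1, 1), E = c(1, 0), SE = c(1, -1),
                 S = c(0, -1), SW = c(-1, -1), W = c(-1, 0), NW = c(-1, 1))
  v <- -from
  v / sqrt(sum(v^2))
}

# per-offset ignition probabilities for the 8 neighbour directions
neighbour_offsets <- function(params) {
  off <- expand.grid(dc = -1:1, dr = -1:1)
  off <- off[!(off$dc == 0 & off$dr == 0), ]
  dw <- downwind_vector(params$wind_direction)
  p <- vapply(seq_len(nrow(off)), function(i) {
    v <- c(off$dc[i], off$dr[i])
    v <- v / sqrt(sum(v^2))
    fac <- max(0, 1 + params$wind_bias * params$wind_speed * sum(v * dw))
    min(1, max(0, params$p_base * fac))
  }, numeric(1))
  cbind(dc = off$dc, dr = off$dr, p = p)
}

#' Draw random fire origins
#'
#' Uniform draw without replacement among building cells; reproducible
#' under `seed`.
#'
#' @param field a `grid_field`
#' @param n_origins number of origins (0 = no fire ever)
#' @param seed integer seed
#' @return integer vector of cell indices
#' @export
ignite <- function(field, n_origins, seed = 1) {
  if (n_origins < 0) stop("'n_origins' must be >= 0")
  cells <- which(field$building > 0)
  if (n_origins > length(cells)) {
    stop("more fire origins than building cells")
  }
  if (n_origins == 0) return(integer(0))
  with_seed(seed, cells[sample.int(length(cells), n_origins)])
}

#' Advance the fire state by one second
#'
#' Fire is confined to building cells: open and road cells never ignite.
#'
#' @param state list with integer vectors `burning` (cell indices),
#'   `burn_age` (seconds burning, parallel to `burning`), `burned`
#' @param field a `grid_field`
#' @param params a [fire_params()]
#' @return updated state, with `new` holding this step's ignitions
#' @export
step_fire <- function(state, field, params) {
  offsets <- state$offsets %||% neighbour_offsets(params)
  nr <- field$n_rows
  ncell <- nr * field$n_cols
  new_ign <- integer(0)
  if (length(state$burning)) {
    occupied <- logical(ncell)
    occupied[state$burning] <- TRUE
    occupied[state$burned] <- TRUE
    row <- (state$burning - 1L) %% nr + 1L
    col <- (state$burning - 1L) %/% nr + 1L
    for (k in seq_len(nrow(offsets))) {
      r2 <- row + offsets[k, "dr"]
      c2 <- col + offsets[k, "dc"]
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= field$n_cols
      idx <- (c2[ok] - 1L) * nr + r2[ok]
      idx <- idx[field$building[idx] > 0L & !occupied[idx]]
      if (!length(idx)) next
      hit <- idx[stats::runif(length(idx)) < offsets[k, "p"]]
      if (length(hit)) {
        occupied[hit] <- TRUE
        new_ign <- c(new_ign, hit)
      }
    }
  }
  age <- state$burn_age + 1L
  done <- age >= params$burn_duration
  state$burned <- c(state$burned, state$burning[done])
  state$burning <- c(state$burning[!done], new_ign)
  state$burn_age <- c(age[!done], integer(length(new_ign)))
  state$new <- new_ign
  state$offsets <- offsets
  state
}

#' Precompute the full hazard timeline
#'
#' Runs collapse sampling, rubble generation and the fire-spread automaton
#' over `horizon` seconds and freezes the result. Three independent RNG
#' streams (collapse, origins, spread) are derived from the master seed so
#' that toggling one hazard never shifts another's draws. The evacuation
#' simulator consumes the timeline read-only.
#'
#' @param town a `town`
#' @param collapse_config collapse table (see [default_collapse_config()])
#' @param fire a [fire_params()]
#' @param horizon timeline length in seconds (1 step = 1 s)
#' @param seed master seed
#' @param rubble_k intrusion scale, see [generate_rubble()]
#' @param field optional precomputed [rasterize_town()] result
#' @param adjacency optional precomputed [building_adjacent_links()] result
#' @return list of class `hazard_timeline`: `horizon`, `seed`, `collapsed`,
#'   `rubble` (per-link table), `origins`, `cell_ignition` /
#'   `cell_burnout` (per-cell step indices, NA = never), per-building
#'   `building_ignition`, per-link `link_fire_step`
#' @export
build_timeline <- function(town, collapse_config = default_collapse_config(),
                           fire = fire_params(), horizon = 900, seed = 1,
                           rubble_k = 0.5, field = NULL, adjacency = NULL) {
  stopifnot(horizon >= 1)
  if (is.null(field)) field <- rasterize_town(town)
  if (is.null(adjacency)) adjacency <- building_adjacent_links(town)

  collapsed <- sample_collapses(town$buildings, collapse_config,
                                seed = derive_seed(seed, 1))
  rubble <- generate_rubble(town, collapsed, k = rubble_k,
                            adjacency = adjacency)

  ncell <- field$n_rows * field$n_cols
  cell_ignition <- rep(NA_integer_, ncell)
  cell_burnout <- rep(NA_integer_, ncell)
  origins <- ignite(field, fire$n_origins, seed = derive_seed(seed, 2))
  if (length(origins)) {
    cell_ignition[origins] <- 0L
    state <- list(burning = origins,
                  burn_age = integer(length(origins)),
                  burned = integer(0))
    with_seed(derive_seed(seed, 3), {
      for (t in seq_len(horizon)) {
        state <- step_fire(state, field, fire)
        if (length(state$new)) cell_ignition[state$new] <- t
        if (!length(state$burning)) break
      }
    })
    cell_burnout[!is.na(cell_ignition)] <-
      pmin(cell_ignition[!is.na(cell_ignition)] + fire$burn_duration,
           horizon + 1L)
  }

  b <- town$buildings
  building_ignition <- vapply(seq_len(nrow(b)), function(i) {
    ign <- cell_ignition[field$building_cells[[as.character(b$id[i])]]]
    if (all(is.na(ign))) NA_integer_ else as.integer(min(ign, na.rm = TRUE))
  }, integer(1))  # in town$buildings row order

  link_fire_step <- rep(NA_integer_, nrow(town$links))
  for (i in seq_len(nrow(b))) {
    if (is.na(building_ignition[i])) next
    for (lid in adjacency[[i]]) {
      j <- match(lid, town$links$id)
      link_fire_step[j] <- min(link_fire_step[j], building_ignition[i],
                               na.rm = TRUE)
    }
  }

  structure(list(horizon = as.integer(horizon), seed = seed,
                 collapsed = sort(collapsed), rubble = rubble,
                 origins = origins,
                 cell_ignition = cell_ignition, cell_burnout = cell_burnout,
                 building_ignition = building_ignition,
                 link_fire_step = link_fire_step,
                 n_rows = field$n_rows, n_cols = field$n_cols),
            class = "hazard_timeline")
}

#' @export
print.hazard_timeline <- function(x, ...) {
  cat("<hazard_timeline> horizon ", x$horizon, " s, ",
      length(x$collapsed), " collapsed buildings, ",
      sum(x$rubble$blocked), " rubble-blocked links, ",
      sum(!is.na(x$cell_ignition)), " cells ever burning\n", sep = "")
  invisible(x)
}

#' Cells burning / burned at a step
#'
#' @param timeline a `hazard_timeline`
#' @param t step (seconds since the earthquake)
#' @return integer cell indices
#' @export
burning_cells <- function(timeline, t) {
  which(!is.na(timeline$cell_ignition) & timeline$cell_ignition <= t &
          timeline$cell_burnout > t)
}

#' @rdname burning_cells
#' @export
burned_cells <- function(timeline, t) {
  which(!is.na(timeline$cell_burnout) & timeline$cell_burnout <= t)
}

#' Which links are impassable at a step
#'
#' Rubble blocks a link (from step 0, permanently) only when the rubble
#' road-obstruction setting is `"impassable"` and the residual width is
#' under 0.6 m; fire blocks a link from the step an adjacent building
#' ignites (fire obstruction is always impassable).
#'
#' @param timeline a `hazard_timeline`
#' @param t step
#' @param rubble_blocking `"passable"` (default base setting) or
#'   `"impassable"`
#' @return logical vector over links (in `town$links` order)
#' @export
blocked_links <- function(timeline, t, rubble_blocking = "passable") {
  fire <- !is.na(timeline$link_fire_step) & timeline$link_fire_step <= t
  if (identical(rubble_blocking, "impassable")) {
    fire | timeline$rubble$blocked
  } else {
    fire
  }
}

#' Serialize / restore a hazard timeline
#'
#' Compact JSON representation; `read_timeline(write_timeline(x))` restores
#' an identical timeline, and a fixed seed yields a byte-identical file.
#'
#' @param timeline a `hazard_timeline`
#' @param path output path
#' @return `path` invisibly; for `read_timeline`, the timeline
#' @export
write_timeline <- function(timeline, path) {
  obj <- unclass(timeline)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$horizon <- as.integer(obj$horizon)
  obj$seed <- as.integer(obj$seed)
  obj$collapsed <- as.integer(obj$collapsed)
  obj$origins <- as.integer(obj$origins)
  obj$cell_ignition <- as.integer(obj$cell_ignition)
  obj$cell_burnout <- as.integer(obj$cell_burnout)
  obj$building_ignition <- as.integer(obj$building_ignition)
  obj$link_fire_step <- as.integer(obj$link_fire_step)
  obj$rubble <- as.data.frame(obj$rubble)
  structure(obj, class = "hazard_timeline")
}
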