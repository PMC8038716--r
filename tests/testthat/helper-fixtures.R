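# Fixtures built in code and independent oracles used across the suite.

# printed reference values for the seven age bands x two genders
printed_expected_values <- function() {
  data.frame(
    age_band = c(10, 20, 30, 40, 50, 60, 70),
    male = c(0.1733, 0.1733, 0.1583, 0.1995, 0.1293, 0.1187, 0.0755),
    female = c(0.0465, 0.0416, 0.0487, 0.0609, 0.0607, 0.0348, 0.0210)
  )
}

# a compact generated town for engine tests (fast: ~90 residents)
small_town <- function(seed = 42, ...) {
  generate_town(town_spec(block_rows = 2, block_cols = 3,
                          buildings_per_block = 6,
                          target_population = 140, n_sites = 2,
                          seed = seed, ...))
}

# hand-built straight-street micro town:
#   nodes 1..4 on a line at x = 0, 50, 100, 150; site at node 4;
#   buildings A/B/C at nodes 1/2/3, 6 m north of the street
line_town <- function(widths = c(6, 6, 6), floors = c(1, 1, 1),
                      roster = NULL) {
  nodes <- data.frame(id = 1:4, x = c(0, 50, 100, 150), y = 0)
  links <- data.frame(id = 1:3, from = 1:3, to = 2:4, width = widths,
                      length = 50)
  buildings <- data.frame(
    id = 1:3, group_id = 1L,
    xmin = c(-4.5, 45.5, 95.5), ymin = 6,
    xmax = c(4.5, 54.5, 104.5), ymax = 15,
    x = c(0, 50, 100), y = 10.5,
    structure = "wood", floors = floors, year_built = 1990L,
    node = 1:3
  )
  sites <- data.frame(id = 1L, node = 4L, x = 150, y = 0)
  if (is.null(roster)) {
    roster <- data.frame(
      resident_id = 1:3, household_id = 1:3, building_id = 1:3,
      group_id = 1L, age = 40, gender = "male",
      needs_assistance = FALSE, commuter = FALSE
    )
  }
  structure(list(nodes = nodes, links = links, buildings = buildings,
                 sites = sites, barriers = barrier_segments(NULL),
                 roster = roster,
                 extent = c(xmin = -9, ymin = -9, xmax = 159, ymax = 21),
                 spec = NULL),
            class = "town")
}

# collapse configuration with a single flat probability for every building
flat_collapse_config <- function(p) {
  data.frame(structure = c("wood", "rc", "steel"),
             year_min = 0, year_max = 9999, p = p)
}

# a timeline with no hazards at all
zero_hazard_timeline <- function(town, horizon = 600) {
  build_timeline(town, collapse_config = flat_collapse_config(0),
                 fire = fire_params(n_origins = 0),
                 horizon = horizon, seed = 1)
}

# --- independent oracles ----------------------------------------------------

# scalar double-loop capability oracle: per-resident expected values summed
# per building, distance weight evaluated inline, every (i, j) pair visited
# explicitly
oracle_capability <- function(buildings, roster, barriers = NULL,
                              X = 100, divisor = 5, include_self = TRUE) {
  segs <- barrier_segments(barriers)
  tab <- rescue_rate_table()
  person_ev <- function(age, gender) {
    if (age < 16) return(0)
    band <- min(70, floor(age / 10) * 10)
    r <- which(tab$age_band == band)
    raw <- if (gender == "male") {
      tab$strength_male[r] * tab$executing_rate[r] * tab$activity_rate_male[r]
    } else {
      tab$strength_female[r] * tab$executing_rate[r] *
        tab$activity_rate_female[r]
    }
    # the published 4-decimal cell is the canonical per-person value
    floor(raw * 1e4 + 0.5 + 1e-9) / 1e4
  }
  rr <- numeric(nrow(buildings))
  for (i in seq_len(nrow(buildings))) {
    rows <- roster[roster$building_id == buildings$id[i], , drop = FALSE]
    s <- 0
    for (k in seq_len(nrow(rows))) {
      if (!isTRUE(as.logical(rows$needs_assistance[k]))) {
        s <- s + person_ev(rows$age[k], rows$gender[k])
      }
    }
    rr[i] <- s
  }
  cap <- numeric(nrow(buildings))
  for (i in seq_len(nrow(buildings))) {
    acc <- 0
    for (j in seq_len(nrow(buildings))) {
      if (!include_self && i == j) next
      d <- sqrt((buildings$x[i] - buildings$x[j])^2 +
                  (buildings$y[i] - buildings$y[j])^2)
      if (d > X) next
      if (nrow(segs) > 0 && i != j &&
          crosses_barrier(buildings$x[i], buildings$y[i],
                          buildings$x[j], buildings$y[j], segs)) next
      w <- log10(1 + X) / (2 * (log10(1 + d) + 1))
      acc <- acc + rr[j] * w
    }
    cap[i] <- acc / divisor
  }
  cap
}

# exhaustive shortest-path oracle by simple-path enumeration
oracle_shortest <- function(town, from, to, blocked = integer(0)) {
  if (from == to) return(0)
  g <- build_graph(town)
  if (length(blocked)) {
    g <- igraph::delete_edges(g, which(igraph::E(g)$link_id %in% blocked))
  }
  paths <- igraph::all_simple_paths(g, from = as.character(from),
                                    to = as.character(to))
  if (!length(paths)) return(Inf)
  key <- paste(pmin(town$links$from, town$links$to),
               pmax(town$links$from, town$links$to), sep = "|")
  len_of <- stats::setNames(town$links$length, key)
  min(vapply(paths, function(p) {
    v <- as.integer(names(p))
    sum(len_of[paste(pmin(v[-length(v)], v[-1]),
                     pmax(v[-length(v)], v[-1]), sep = "|")])
  }, numeric(1)))
}
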