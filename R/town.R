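#' Specification of a synthetic town
#'
#' Parameters for [generate_town()]. The defaults emulate the kind of
#' dense, small Japanese district the tool targets: a rectangular street
#' grid of 3 x 5 blocks (each block one neighbourhood small group, 15 in
#' all), ~8 wooden/low-rise buildings per block, a total residential
#' population of 398 of whom roughly a quarter commute away in the daytime
#' sense (evening population ~300), two designated evacuation sites at
#' opposite corners, and assistance-need ratios of 0.1 for ages 60-69, 0.2
#' for 70+, 0.05 otherwise.
#'
#' @param block_rows,block_cols street-grid blocks (default 3 x 5)
#' @param block_width,block_height block dimensions in metres
#' @param buildings_per_block buildings per block (2 rows of footprints)
#' @param road_width_major,road_width_minor widths (m) of horizontal /
#'   vertical streets
#' @param target_population total residents (morning population)
#' @param commuter_fraction probability that a resident aged 20-64 is a
#'   commuter (absent in the evening variant)
#' @param assistance_ratios named vector of needing-assistance probabilities
#'   by age class
#' @param n_sites number of evacuation sites (placed at spread corners)
#' @param barrier `NULL`, or `"vertical_mid"` for a river-like barrier line
#'   down the middle of the town
#' @param seed integer seed; generation is fully reproducible under it
#' @return list of class `town_spec`
#' @export
town_spec <- function(block_rows = 3, block_cols = 5,
                      block_width = 60, block_height = 45,
                      buildings_per_block = 8,
                      road_width_major = 6, road_width_minor = 4,
                      target_population = 398,
                      commuter_fraction = 0.43,
                      assistance_ratios = c(`60-69` = 0.1, `70+` = 0.2,
                                            other = 0.05),
                      n_sites = 2, barrier = NULL, seed = 1) {
  spec <- as.list(environment())
  stopifnot(block_rows >= 1, block_cols >= 1, buildings_per_block >= 1,
            target_population >= 1, n_sites >= 1,
            commuter_fraction >= 0, commuter_fraction <= 1,
            all(assistance_ratios >= 0), all(assistance_ratios <= 1))
  structure(spec, class = "town_spec")
}

# one synthetic household: ages, genders
sample_household <- function() {
  type <- sample(c("family", "couple", "single", "elderly_couple",
                   "elderly_single"), 1,
                 prob = c(0.35, 0.25, 0.15, 0.15, 0.10))
  switch(type,
    family = {
      n_kids <- sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
      list(age = c(sample(30:55, 2, replace = TRUE),
                   sample(0:17, n_kids, replace = TRUE)),
           gender = c("male", "female",
                      sample(c("male", "female"), n_kids, replace = TRUE)))
    },
    couple = list(age = sample(25:60, 2, replace = TRUE),
                  gender = c("male", "female")),
    single = list(age = sample(20:60, 1),
                  gender = sample(c("male", "female"), 1)),
    elderly_couple = list(age = sample(65:85, 2, replace = TRUE),
                          gender = c("male", "female")),
    elderly_single = list(age = sample(65:90, 1),
                          gender = sample(c("male", "female"), 1))
  )
}

#' Draw needing-assistance flags from age-class ratios
#'
#' Ages 60-69 draw at the `60-69` ratio, 70 and over at the `70+` ratio, all
#' others at `other`; children under 10 are never flagged here (they are
#' coupled to a parent in the simulator, and the group accounting counts
#' them separately).
#'
#' @param age numeric vector of ages
#' @param ratios named ratio vector as in [town_spec()]
#' @return logical vector
#' @export
draw_assistance_flags <- function(age,
                                  ratios = c(`60-69` = 0.1, `70+` = 0.2,
                                             other = 0.05)) {
  p <- ifelse(age >= 70, ratios[["70+"]],
              ifelse(age >= 60, ratios[["60-69"]], ratios[["other"]]))
  p[age < 10] <- 0
  stats::runif(length(age)) < p
}

#' Generate a synthetic town
#'
#' Builds a fully self-contained district: street-grid road network
#' (connected by construction), building footprints with structure/floors/
#' year attributes, evacuation sites, optional mid-town barrier, and a
#' resident roster grouped by block. Deterministic under `spec$seed`.
#'
#' @param spec a [town_spec()]
#' @return list of class `town` with elements `nodes`, `links`, `buildings`,
#'   `sites`, `barriers` (segment matrix), `roster`, `extent`, `spec`
#' @export
generate_town <- function(spec = town_spec()) {
  stopifnot(inherits(spec, "town_spec"))
  with_seed(spec$seed, {
    bw <- spec$block_width; bh <- spec$block_height
    nc <- spec$block_cols; nr <- spec$block_rows

    # nodes at street intersections, row-major from the lower-left
    grid_xy <- expand.grid(cx = 0:nc, cy = 0:nr)
    nodes <- data.frame(id = seq_len(nrow(grid_xy)),
                        x = grid_xy$cx * bw, y = grid_xy$cy * bh)
    node_at <- function(cx, cy) cx + 1 + cy * (nc + 1)

    links <- list()
    for (cy in 0:nr) for (cx in 0:(nc - 1)) {
      links[[length(links) + 1]] <- c(node_at(cx, cy), node_at(cx + 1, cy),
                                      spec$road_width_major)
    }
    for (cy in 0:(nr - 1)) for (cx in 0:nc) {
      links[[length(links) + 1]] <- c(node_at(cx, cy), node_at(cx, cy + 1),
                                      spec$road_width_minor)
    }
    links <- as.data.frame(do.call(rbind, links))
    names(links) <- c("from", "to", "width")
    links$id <- seq_len(nrow(links))
    links$length <- sqrt((nodes$x[links$to] - nodes$x[links$from])^2 +
                           (nodes$y[links$to] - nodes$y[links$from])^2)
    links <- links[, c("id", "from", "to", "width", "length")]

    if (spec$n_sites > nrow(nodes)) {
      stop("infeasible spec: more evacuation sites than network nodes")
    }

    # buildings: two rows of square footprints inside each block
    per_row <- ceiling(spec$buildings_per_block / 2)
    fs <- 9  # footprint side, metres (3 grid cells)
    buildings <- list()
    bid <- 0
    for (by in 0:(nr - 1)) for (bx in 0:(nc - 1)) {
      group <- bx + 1 + by * nc
      x0 <- bx * bw; y0 <- by * bh
      for (k in seq_len(spec$buildings_per_block)) {
        row <- (k - 1) %/% per_row
        col <- (k - 1) %% per_row
        gap_x <- (bw - per_row * fs) / (per_row + 1)
        xmin <- x0 + gap_x * (col + 1) + fs * col
        ymin <- y0 + if (row == 0) 8 else bh - 8 - fs
        bid <- bid + 1
        buildings[[bid]] <- data.frame(
          id = bid, group_id = group,
          xmin = xmin, ymin = ymin, xmax = xmin + fs, ymax = ymin + fs,
          x = xmin + fs / 2, y = ymin + fs / 2,
          structure = sample(c("wood", "rc", "steel"), 1,
                             prob = c(0.7, 0.2, 0.1)),
          floors = sample(1:3, 1, prob = c(0.5, 0.4, 0.1)),
          year_built = sample(1950:2015, 1)
        )
      }
    }
    buildings <- do.call(rbind, buildings)
    # access node: nearest street intersection
    buildings$node <- vapply(seq_len(nrow(buildings)), function(i) {
      which.min((nodes$x - buildings$x[i])^2 + (nodes$y - buildings$y[i])^2)
    }, integer(1))

    # evacuation sites at spread-out corner nodes
    corner_ids <- c(node_at(0, 0), node_at(nc, nr), node_at(nc, 0),
                    node_at(0, nr))
    site_nodes <- corner_ids[seq_len(min(spec$n_sites, 4))]
    if (spec$n_sites > 4) {
      extra <- setdiff(nodes$id, site_nodes)
      site_nodes <- c(site_nodes, sample(extra, spec$n_sites - 4))
    }
    sites <- data.frame(id = seq_along(site_nodes), node = site_nodes,
                        x = nodes$x[site_nodes], y = nodes$y[site_nodes])

    barriers <- if (identical(spec$barrier, "vertical_mid")) {
      midx <- nc * bw / 2
      matrix(c(midx, -10, midx, nr * bh + 10), ncol = 4,
             dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
    } else {
      barrier_segments(NULL)
    }

    # roster: households filled round-robin over buildings until the target
    roster <- list()
    total <- 0
    hh <- 0
    b_cycle <- rep(seq_len(nrow(buildings)), length.out = 10000)
    while (total < spec$target_population) {
      hh <- hh + 1
      h <- sample_household()
      take <- min(length(h$age), spec$target_population - total)
      idx <- seq_len(take)
      b <- b_cycle[hh]
      roster[[hh]] <- data.frame(
        household_id = hh,
        building_id = buildings$id[b],
        group_id = buildings$group_id[b],
        age = h$age[idx], gender = h$gender[idx]
      )
      total <- total + take
    }
    roster <- do.call(rbind, roster)
    roster$resident_id <- seq_len(nrow(roster))
    roster$needs_assistance <- draw_assistance_flags(
      roster$age, spec$assistance_ratios
    )
    roster$commuter <- roster$age >= 20 & roster$age < 65 &
      stats::runif(nrow(roster)) < spec$commuter_fraction
    roster <- roster[, c("resident_id", "household_id", "building_id",
                         "group_id", "age", "gender", "needs_assistance",
                         "commuter")]

    structure(list(
      nodes = nodes, links = links, buildings = buildings, sites = sites,
      barriers = barriers, roster = roster,
      extent = c(xmin = -6, ymin = -6, xmax = nc * bw + 6,
                 ymax = nr * bh + 6),
      spec = spec
    ), class = "town")
  })
}

#' @export
print.town <- function(x, ...) {
  cat("<town> ", nrow(x$buildings), " buildings, ", nrow(x$roster),
      " residents in ", length(unique(x$roster$group_id)), " groups, ",
      nrow(x$links), " road links, ", nrow(x$sites), " evacuation site(s)\n",
      sep = "")
  invisible(x)
}

#' Write a town to GeoJSON/CSV input files
#'
#' Produces the standard input file set consumed by [load_inputs()] and the
#' CLI: `buildings.geojson`, `roads.geojson`, `sites.geojson`,
#' `barriers.geojson` and `roster.csv`.
#'
#' @param town a `town` from [generate_town()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_town <- function(town, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- town$buildings
  bf <- lapply(seq_len(nrow(b)), function(i) {
    geojson_feature("Polygon",
                    rect_ring(b$xmin[i], b$ymin[i], b$xmax[i], b$ymax[i]),
                    list(id = b$id[i], group_id = b$group_id[i],
                         structure = b$structure[i], floors = b$floors[i],
                         year_built = b$year_built[i]))
  })
  write_geojson(bf, file.path(dir, "buildings.geojson"))

  l <- town$links
  lf <- lapply(seq_len(nrow(l)), function(i) {
    geojson_feature("LineString",
                    list(c(town$nodes$x[l$from[i]], town$nodes$y[l$from[i]]),
                         c(town$nodes$x[l$to[i]], town$nodes$y[l$to[i]])),
                    list(id = l$id[i], width = l$width[i]))
  })
  write_geojson(lf, file.path(dir, "roads.geojson"))

  s <- town$sites
  sf <- lapply(seq_len(nrow(s)), function(i) {
    geojson_feature("Point", c(s$x[i], s$y[i]), list(id = s$id[i]))
  })
  write_geojson(sf, file.path(dir, "sites.geojson"))

  seg <- town$barriers
  xf <- lapply(seq_len(nrow(seg)), function(i) {
    geojson_feature("LineString",
                    list(c(seg[i, 1], seg[i, 2]), c(seg[i, 3], seg[i, 4])),
                    list(id = i))
  })
  write_geojson(xf, file.path(dir, "barriers.geojson"))

  utils::write.csv(town$roster, file.path(dir, "roster.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Reference 15-group roster fixture
#'
#' A synthetic roster of 15 neighbourhood small groups whose per-group
#' counts of assistance-needing persons (6,2,6,1,1,3,2,0,3,5,6,5,2,3,2;
#' total 47) and of children under 10 (0,0,2,0,0,1,2,0,0,1,3,2,0,1,2; total
#' 14) match the published accounting example this package's group-unit
#' evaluation mirrors. Per-group ability cannot be reconstructed from the
#' published counts (member ages are not public), so use
#' [group_fixture_abilities()] as the `ability` override in
#' [group_accounts()] when reproducing that example.
#'
#' @return roster data.frame (synthetic)
#' @export
group_fixture <- function() {
  n_assist <- c(6, 2, 6, 1, 1, 3, 2, 0, 3, 5, 6, 5, 2, 3, 2)
  n_under10 <- c(0, 0, 2, 0, 0, 1, 2, 0, 0, 1, 3, 2, 0, 1, 2)
  rows <- list()
  for (g in 1:15) {
    kids <- n_under10[g]
    elders <- n_assist[g] - kids
    age <- c(rep(5, kids), rep(80, elders), 40, 42, 38, 45)
    gender <- c(rep(c("male", "female"), length.out = kids + elders),
                "male", "female", "female", "male")
    needs <- c(rep(TRUE, kids + elders), rep(FALSE, 4))
    rows[[g]] <- data.frame(group_id = g, building_id = g, age = age,
                            gender = gender, needs_assistance = needs)
  }
  out <- do.call(rbind, rows)
  out$resident_id <- seq_len(nrow(out))
  out$household_id <- out$resident_id  # singleton households; accounting only
  out[, c("resident_id", "household_id", "building_id", "group_id",
          "age", "gender", "needs_assistance")]
}

#' Surveyed per-group ability values for the reference fixture
#'
#' The 15 per-group mutual-assistance ability values (sums of member
#' expected rescue values) that accompany the reference accounting example;
#' supplied as the `ability` override to [group_accounts()] because member
#' ages behind them are not public.
#'
#' @return numeric vector of length 15
#' @export
group_fixture_abilities <- function() {
  c(1.3327, 0.9839, 3.0331, 1.6542, 2.8272, 1.3194, 0.4674, 1.3514,
    2.5286, 2.2181, 2.4041, 3.451, 1.2214, 2.3447, 3.0414)
}
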