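test_that("rasterization classifies cells with building-first precedence", {
  # a 9 m x 9 m footprint aligned to the grid claims exactly 3 x 3 cells
  town <- line_town()
  field <- rasterize_town(town)
  expect_equal(field$cell_size, 3)
  expect_equal(length(field$building_cells[["2"]]), 9)
  expect_true(all(field$building[field$building_cells[["2"]]] == 2))

  # road cells run along the street; building beats road where both claim
  overlap <- line_town()
  overlap$buildings$ymin[1] <- -4.5
  overlap$buildings$ymax[1] <- 4.5
  overlap$buildings$y[1] <- 0  # footprint sits on the street
  f2 <- rasterize_town(overlap)
  cells1 <- f2$building_cells[["1"]]
  expect_true(all(f2$link[cells1] == 0))
  expect_gt(sum(f2$link > 0), 0)

  # empty extent -> all open
  empty <- line_town()
  empty$buildings <- empty$buildings[0, ]
  empty$links <- empty$links[0, ]
  f3 <- rasterize_town(empty)
  expect_true(all(cell_classes(f3) == "open"))

  # building outside the extent is an error
  out <- line_town()
  out$buildings$xmax[1] <- 1000
  expect_error(rasterize_town(out), "extent")
})

test_that("collapse sampling is Bernoulli with the configured probability", {
  many <- data.frame(id = 1:10000, structure = "wood", year_built = 1970,
                     floors = 1)
  expect_length(sample_collapses(many, flat_collapse_config(0), seed = 1), 0)
  expect_length(sample_collapses(many, flat_collapse_config(1), seed = 1),
                10000)
  frac <- length(sample_collapses(many, flat_collapse_config(0.3),
                                  seed = 7)) / 10000
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  # identical under the seed
  expect_identical(sample_collapses(many, flat_collapse_config(0.3), seed = 7),
                   sample_collapses(many, flat_collapse_config(0.3), seed = 7))
  # unmatched building is a configuration error
  odd <- data.frame(id = 1, structure = "brick", year_built = 1970,
                    floors = 1)
  expect_error(collapse_probability(odd), "brick")
  # defaults are ordered: old wood worst, new RC best
  cfg <- default_collapse_config()
  expect_true(cfg$p[cfg$structure == "wood" & cfg$year_max == 1980] ==
                max(cfg$p))
  expect_true(cfg$p[cfg$structure == "rc" & cfg$year_max == 9999] ==
                min(cfg$p))
})

test_that("rubble blocks a link only when residual width is under 0.6 m", {
  # 3-storey building: intrusion 0.5 * 3 * 3 = 4.5 m, capped at road width
  town <- line_town(widths = c(4, 2.1, 6), floors = c(3, 1, 1))
  rub <- generate_rubble(town, collapsed = 1L)
  expect_equal(rub$intrusion[1], 4)        # capped at the 4 m width
  expect_equal(rub$residual[1], 0)
  expect_true(rub$blocked[1])
  # no collapse -> full residual, passable
  rub0 <- generate_rubble(town, collapsed = integer(0))
  expect_true(all(rub0$residual == rub0$width))
  expect_false(any(rub0$blocked))
  # residual of exactly 0.6 m stays passable (strict "under")
  t2 <- line_town(widths = c(6, 2.1, 6), floors = c(1, 1, 1))
  rub2 <- generate_rubble(t2, collapsed = 2L)  # intrusion 0.5 * 1 * 3 = 1.5
  expect_equal(rub2$residual[2], 2.1 - 1.5)
  expect_false(any(rub2$blocked))
})

test_that("fire origins draw uniformly among building cells under the seed", {
  town <- line_town()
  field <- rasterize_town(town)
  expect_length(ignite(field, 0, seed = 1), 0)
  o1 <- ignite(field, 2, seed = 5)
  expect_identical(o1, ignite(field, 2, seed = 5))
  expect_true(all(field$building[o1] > 0))
  expect_error(ignite(field, -1), ">= 0")
  expect_error(ignite(field, 1e6, seed = 1), "more fire origins")
  # single-building town: the origin lands on that building
  solo <- line_town()
  solo$buildings <- solo$buildings[2, ]
  fs <- rasterize_town(solo)
  expect_true(all(fs$building[ignite(fs, 1, seed = 3)] == 2))
})

test_that("fire stays on building cells, spreads downwind, and burns out", {
  # one large 45 m x 45 m footprint: a 15 x 15 cell burnable field
  big <- line_town()
  big$buildings <- data.frame(
    id = 1L, group_id = 1L, xmin = 30, ymin = 30, xmax = 75, ymax = 75,
    x = 52.5, y = 52.5, structure = "wood", floors = 1, year_built = 1950,
    node = 2L
  )
  big$extent <- c(xmin = 0, ymin = 0, xmax = 105, ymax = 105)
  field <- rasterize_town(big)
  centre <- field$building_cells[["1"]][ceiling(225 / 2)]

  run_spread <- function(params, steps, reps, seed0) {
    disp <- matrix(0, reps, 2)
    for (r in seq_len(reps)) {
      set.seed(seed0 + r)
      st <- list(burning = centre, burn_age = 0L, burned = integer(0))
      for (s in seq_len(steps)) st <- step_fire(st, field, params)
      cells <- c(st$burning, st$burned)
      rows <- (cells - 1) %% field$n_rows + 1
      cols <- (cells - 1) %/% field$n_rows + 1
      r0 <- (centre - 1) %% field$n_rows + 1
      c0 <- (centre - 1) %/% field$n_rows + 1
      disp[r, ] <- c(mean(cols - c0), mean(rows - r0))
      expect_true(all(field$building[cells] > 0))  # confinement
    }
    colMeans(disp)
  }
  # p_base = 0: nothing ignites, the origin burns out after its duration
  p0 <- fire_params(p_base = 0, burn_duration = 5, wind_speed = 0)
  set.seed(1)
  st <- list(burning = centre, burn_age = 0L, burned = integer(0))
  for (s in 1:6) st <- step_fire(st, field, p0)
  expect_length(st$burning, 0)
  expect_identical(st$burned, centre)

  # no wind: mean displacement ~ 0
  calm <- run_spread(fire_params(p_base = 0.08, wind_speed = 0,
                                 burn_duration = 300), 40, 25, 100)
  expect_lt(abs(calm[1]), 1)
  expect_lt(abs(calm[2]), 1)

  # wind from the northwest pushes the front southeast (+x, -y)
  windy <- run_spread(fire_params(p_base = 0.08, wind_speed = 5,
                                  wind_direction = "NW", wind_bias = 0.15,
                                  burn_duration = 300), 40, 25, 200)
  expect_gt(windy[1], calm[1] + 0.5)
  expect_lt(windy[2], calm[2] - 0.5)
})

test_that("timelines are deterministic, monotone, and serialize losslessly", {
  town <- small_town(seed = 21)
  tl1 <- build_timeline(town, horizon = 400, seed = 77,
                        fire = fire_params(p_base = 0.02))
  tl2 <- build_timeline(town, horizon = 400, seed = 77,
                        fire = fire_params(p_base = 0.02))
  expect_identical(tl1, tl2)

  # burned/burning sets are non-decreasing unions over time
  prev <- integer(0)
  for (t in seq(0, 400, by = 50)) {
    cur <- sort(union(burning_cells(tl1, t), burned_cells(tl1, t)))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # rubble is fixed from step 0 and fire never leaves building cells
  field <- rasterize_town(town)
  expect_true(all(field$building[which(!is.na(tl1$cell_ignition))] > 0))

  # zero-hazard configuration yields a clean timeline
  tl0 <- zero_hazard_timeline(town, horizon = 300)
  expect_length(tl0$collapsed, 0)
  expect_false(any(tl0$rubble$blocked))
  expect_length(which(!is.na(tl0$cell_ignition)), 0)
  expect_false(any(blocked_links(tl0, 300)))

  # serialization: identical bytes under a fixed seed, lossless round-trip
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_timeline(tl1, p1)
  write_timeline(tl2, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_timeline(p1)
  expect_equal(back$cell_ignition, tl1$cell_ignition)
  expect_equal(back$rubble$blocked, tl1$rubble$blocked)
  expect_equal(back$collapsed, tl1$collapsed)

  # rubble blocking honours the passable/impassable toggle
  if (any(tl1$rubble$blocked)) {
    expect_false(any(blocked_links(tl1, 0, "passable") &
                       tl1$rubble$blocked &
                       is.na(tl1$link_fire_step)))
    expect_true(all(blocked_links(tl1, 0, "impassable")[tl1$rubble$blocked]))
  }
})
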