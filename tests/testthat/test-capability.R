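test_that("distance weight has the documented shape", {
  # closed-form value at D = 0, X = 100
  expect_equal(distance_weight(0), log10(101) / 2, tolerance = 1e-12)
  expect_equal(distance_weight(0), 1.0022, tolerance = 1e-4)
  # zero beyond the range limit
  expect_identical(distance_weight(150), 0)
  expect_identical(distance_weight(100.0001), 0)
  # strictly decreasing and continuous on [0, X] (steepest near 0, where
  # the derivative is ~ -0.44/m; a 1 cm grid keeps increments tiny)
  d <- seq(0, 100, by = 0.01)
  w <- distance_weight(d)
  expect_true(all(diff(w) < 0))
  expect_lt(max(abs(diff(w))), 0.005)  # no jumps inside the range
  expect_error(distance_weight(-1), "non-negative")
})

test_that("building expected value is the sum over residents", {
  roster <- data.frame(
    building_id = c(1, 1, 2, 3),
    age = c(40, 40, 80, 7),
    gender = c("male", "female", "female", "male"),
    needs_assistance = c(FALSE, FALSE, TRUE, FALSE)
  )
  # one 40-y man + one 40-y woman
  expect_equal(round_half_up(building_expected_value(1, roster), 4), 0.2604)
  # only a needs-assistance elder
  expect_identical(building_expected_value(2, roster), 0)
  # empty building
  expect_identical(building_expected_value(99, roster), 0)
})

test_that("capability matches the scalar double-loop oracle", {
  town <- small_town(seed = 5)  # 36 buildings
  for (bar in list(NULL, matrix(c(90, -20, 90, 120), ncol = 4))) {
    cap <- building_capability(town$buildings, town$roster, barriers = bar)
    ora <- oracle_capability(town$buildings, town$roster, barriers = bar)
    expect_equal(cap$capability, ora, tolerance = 1e-10)
  }
})

test_that("capability respects barriers, range and self-inclusion", {
  buildings <- data.frame(id = 1:3, x = c(0, 50, 300), y = 0)
  roster <- data.frame(
    resident_id = 1:3, building_id = 1:3, group_id = 1,
    age = 40, gender = "male", needs_assistance = FALSE
  )
  rr <- expected_value(40, "male")
  cap <- building_capability(buildings, roster)
  # building 3 is beyond 100 m of everyone: self-contribution only
  expect_equal(cap$capability[3], rr * distance_weight(0) / 5,
               tolerance = 1e-12)
  # building 1 sees itself and building 2
  expect_equal(cap$capability[1],
               (rr * distance_weight(0) + rr * distance_weight(50)) / 5,
               tolerance = 1e-12)
  # a barrier between 1 and 2 removes the neighbour term on both sides
  bar <- matrix(c(25, -10, 25, 10), ncol = 4)
  cap_b <- building_capability(buildings, roster, barriers = bar)
  expect_equal(cap_b$capability[1], rr * distance_weight(0) / 5,
               tolerance = 1e-12)
  expect_equal(cap_b$capability[2], rr * distance_weight(0) / 5,
               tolerance = 1e-12)
  # excluding the target's own residents
  cap_ns <- building_capability(buildings, roster, include_self = FALSE)
  expect_equal(cap_ns$capability[3], 0)
  # single neighbour at D = 0 with the worked Rr
  one <- building_capability(data.frame(id = 1, x = 0, y = 0),
                             data.frame(resident_id = 1, building_id = 1,
                                        age = 40, gender = "male",
                                        needs_assistance = FALSE))
  expect_equal(one$capability, 0.1995 * distance_weight(0) / 5,
               tolerance = 1e-9)
  expect_equal(round_half_up(one$capability, 4), 0.04)
  expect_error(
    building_capability(data.frame(id = 1, x = NA, y = 0), roster),
    "coordinates"
  )
})

test_that("adding a rescuer never decreases any in-range capability", {
  town <- small_town(seed = 8)
  base <- building_capability(town$buildings, town$roster)
  extra <- town$roster[1, ]
  extra$resident_id <- max(town$roster$resident_id) + 1
  extra$age <- 40; extra$gender <- "male"; extra$needs_assistance <- FALSE
  for (b in town$buildings$id[c(3, 17, 30)]) {
    extra$building_id <- b
    grown <- building_capability(town$buildings, rbind(town$roster, extra))
    expect_true(all(grown$capability >= base$capability - 1e-12))
  }
})
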