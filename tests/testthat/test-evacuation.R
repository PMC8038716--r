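# helper: roster rows for the hand-built street town
lt_resident <- function(id, hh, b, age = 40, gender = "male",
                        needs = FALSE) {
  data.frame(resident_id = id, household_id = hh, building_id = b,
             group_id = 1L, age = age, gender = gender,
             needs_assistance = needs, commuter = FALSE)
}

test_that("population instantiation follows time of day, ratios and seed", {
  town <- generate_town(town_spec(seed = 4))
  scen <- scenario()
  morning <- init_population(town$roster, scen, seed = 10)
  expect_equal(nrow(morning), 398)
  evening <- init_population(town$roster, scen, time_of_day = "evening",
                             seed = 10)
  expect_lt(nrow(evening), 398)
  expect_false(any(evening$commuter))
  expect_identical(init_population(town$roster, scen, seed = 10), morning)
  # start times fall in the window, one per household
  expect_true(all(morning$start_time >= 0 & morning$start_time <= 120))
  expect_equal(length(unique(paste(morning$household_id,
                                   morning$start_time))),
               length(unique(morning$household_id)))
  # flags are drawn only where missing
  ros <- town$roster
  ros$needs_assistance <- NULL
  drawn <- init_population(ros, scen, seed = 10)
  expect_type(drawn$needs_assistance, "logical")
  expect_error(init_population(ros[0, ], scen), "empty")
})

test_that("destination choice matches the exhaustive path oracle", {
  town <- small_town(seed = 12)  # 12 intersections
  g <- build_graph(town)
  for (node in town$nodes$id) {
    r <- choose_destination(node, town)
    best <- min(vapply(town$sites$node, function(s) {
      oracle_shortest(town, node, s)
    }, numeric(1)))
    expect_equal(r$length, best, tolerance = 1e-9)
  }
  # with blocked links the route still matches enumeration
  blocked <- town$links$id[c(2, 5, 9)]
  for (node in town$nodes$id[c(1, 4, 7, 12)]) {
    r <- choose_destination(node, town, blocked = blocked)
    best <- min(vapply(town$sites$node, function(s) {
      oracle_shortest(town, node, s, blocked = blocked)
    }, numeric(1)))
    if (is.finite(best)) {
      expect_equal(r$length, best, tolerance = 1e-9)
    } else {
      expect_null(r)
    }
  }
  # every link blocked: nowhere to go
  expect_null(choose_destination(5, town, blocked = town$links$id))
})

test_that("hazard-free evacuation reaches the site at walking speed", {
  town <- line_town(roster = lt_resident(1, 1, 1))
  tl <- zero_hazard_timeline(town)
  for (sp in c(1.5, 3)) {
    res <- run_simulation(town, tl,
                          scenario(speed = sp, start_window = c(0, 0),
                                   perception_range = 0, horizon = 600),
                          seed = 1)
    expect_equal(res$agents$outcome, "evacuated")
    t_out <- res$agents$t_out
    # 150 m of street at sp m/s, moving from the first step
    expect_gte((t_out + 1) * sp, 150)
    expect_lt(t_out * sp, 150)
  }
})

test_that("everyone evacuates and families stay together without hazards", {
  town <- small_town(seed = 14)
  town$roster$needs_assistance <- FALSE
  tl <- zero_hazard_timeline(town)
  res <- run_simulation(town, tl, scenario(horizon = 600), seed = 2)
  expect_true(all(res$agents$outcome == "evacuated"))
  expect_equal(res$counts$n_requiring, 0)
  # one terminal site per household
  per_hh <- tapply(res$agents$site, res$agents$household_id,
                   function(s) length(unique(s)))
  expect_true(all(per_hh == 1))
  # conservation
  with(res$counts,
       expect_equal(n_evacuated + n_awaiting + n_casualty, n_present))
})

test_that("rescue succeeds when gathered expected values exceed the threshold", {
  # victim (needs assistance) in the middle building; two one-man rescuer
  # households (0.1995 each) start from the west end
  roster <- rbind(lt_resident(1, 1, 1), lt_resident(2, 2, 1),
                  lt_resident(3, 3, 2, age = 80, gender = "female",
                              needs = TRUE))
  town <- line_town(roster = roster)
  tl <- zero_hazard_timeline(town)
  scen <- scenario(start_window = c(0, 0), rescue_threshold = 0.3,
                   horizon = 600)
  res <- run_simulation(town, tl, scen, seed = 3)
  expect_equal(res$counts$n_requiring, 1)
  expect_equal(res$counts$n_receiving, 1)
  v <- res$agents[res$agents$resident_id == 3, ]
  expect_equal(v$outcome, "evacuated")   # rescued victim joins the rescuers
  expect_true(v$received_assistance)
  expect_true("supported" %in% res$events$type)

  # threshold exactly equal to the gathered pool of 2 x 0.1995 fails:
  # the rule requires the sum to strictly exceed the threshold
  scen_eq <- scenario(start_window = c(0, 0),
                      rescue_threshold = 2 * 0.1995, horizon = 600)
  res_eq <- run_simulation(town, tl, scen_eq, seed = 3)
  expect_equal(res_eq$counts$n_receiving, 0)
})

test_that("rescuers give up at the deadline and resume evacuation", {
  roster <- rbind(lt_resident(1, 1, 1),
                  lt_resident(2, 2, 2, age = 80, gender = "female",
                              needs = TRUE))
  town <- line_town(roster = roster)
  tl <- zero_hazard_timeline(town, horizon = 800)
  res <- run_simulation(town, tl,
                        scenario(start_window = c(0, 0), horizon = 800),
                        seed = 5)
  # 0.1995 alone never exceeds 1: victim abandoned 5 min after the quake
  ab <- res$events[res$events$type == "victim_abandoned", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$t, 300)
  v <- res$agents[res$agents$resident_id == 2, ]
  expect_equal(v$outcome, "awaiting_public")
  expect_false(v$received_assistance)
  r <- res$agents[res$agents$resident_id == 1, ]
  expect_equal(r$outcome, "evacuated")
  expect_gt(r$t_out, 300)  # resumed after giving up

  # per-attempt clock variant: abandonment happens later than engagement+300
  res2 <- run_simulation(town, tl,
                         scenario(start_window = c(0, 0), horizon = 800,
                                  give_up_from = "rescue_start"),
                         seed = 5)
  ab2 <- res2$events[res2$events$type == "victim_abandoned", ]
  eng <- res2$events[res2$events$type == "engage", ]
  expect_equal(ab2$t, eng$t[1] + 300)
})

test_that("parents escorting small children do not divert to rescues", {
  roster <- rbind(lt_resident(1, 1, 1),
                  lt_resident(2, 1, 1, age = 5),
                  lt_resident(3, 3, 2, age = 80, gender = "female",
                              needs = TRUE))
  town <- line_town(roster = roster)
  tl <- zero_hazard_timeline(town)
  res <- run_simulation(town, tl,
                        scenario(start_window = c(0, 0),
                                 rescue_threshold = 0.1, horizon = 600),
                        seed = 6)
  expect_equal(res$counts$n_receiving, 0)
  expect_false("divert" %in% res$events$type)
  expect_true(all(res$agents$outcome[res$agents$resident_id %in% c(1, 2)] ==
                    "evacuated"))
})

test_that("victims in burning buildings get no help; roadless agents await", {
  roster <- rbind(lt_resident(1, 1, 1),
                  lt_resident(2, 2, 2, age = 80, gender = "female",
                              needs = TRUE))
  town <- line_town(roster = roster)
  tl <- zero_hazard_timeline(town)
  tl$building_ignition[2] <- 0L  # the victim's building burns at once
  res <- run_simulation(town, tl,
                        scenario(start_window = c(0, 0),
                                 rescue_threshold = 0.1, horizon = 600),
                        seed = 7)
  v <- res$agents[res$agents$resident_id == 2, ]
  expect_equal(v$outcome, "casualty")
  expect_equal(res$counts$n_receiving, 0)

  # every link rubble-blocked and impassable: no route, all await
  tl2 <- zero_hazard_timeline(town)
  tl2$rubble$blocked[] <- TRUE
  res2 <- run_simulation(town, tl2,
                         scenario(start_window = c(0, 0),
                                  rubble_blocking = "impassable",
                                  perception_range = 0, horizon = 600),
                         seed = 8)
  expect_true(all(res2$agents$outcome %in% c("awaiting_public")))
  # the same blockage under the "passable" setting is ignored
  res3 <- run_simulation(town, tl2,
                         scenario(start_window = c(0, 0),
                                  rubble_blocking = "passable",
                                  perception_range = 0, horizon = 600),
                         seed = 8)
  expect_equal(res3$agents$outcome[1], "evacuated")
})

test_that("batches conserve agents, vary across seeds, reproduce under seed", {
  town <- small_town(seed = 23)
  scen <- scenario(horizon = 480)
  b1 <- run_batch(town, scen, n_runs = 6, master_seed = 17)
  for (r in b1) {
    with(r$counts,
         expect_equal(n_evacuated + n_awaiting + n_casualty, n_present))
    tab <- table(r$agents$outcome)
    expect_equal(sum(tab), r$counts$n_present)
  }
  evac <- vapply(b1, function(r) r$counts$n_evacuated, numeric(1))
  expect_gt(stats::var(evac), 0)  # hazards differ across run seeds
  b2 <- run_batch(town, scen, n_runs = 6, master_seed = 17)
  expect_identical(lapply(b1, `[[`, "counts"), lapply(b2, `[[`, "counts"))
  expect_identical(b1[[3]]$events, b2[[3]]$events)
  expect_error(
    run_simulation(town, zero_hazard_timeline(town, horizon = 100),
                   scenario(horizon = 480)),
    "does not cover"
  )
})

test_that("disabling mutual assistance yields exactly zero assists", {
  town <- small_town(seed = 27)
  batch <- run_batch(town, scenario(perception_range = 0, horizon = 480),
                     n_runs = 4, master_seed = 2)
  expect_identical(sum(vapply(batch, function(r) r$counts$n_receiving,
                              numeric(1))), 0)
  expect_false(any(vapply(batch, function(r) any(r$events$type == "divert"),
                          logical(1))))
})
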