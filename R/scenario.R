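#' Evacuation scenario settings
#'
#' The user-settable simulator parameters: evacuation start-time window,
#' perception range (the radius within which an evacuating resident notices
#' a person needing rescue or support; must be a multiple of the 3 m cell),
#' walking speed, per-age-band assistance-need ratios, the mutual-assistance
#' setting for children aged 10-15, and the road-obstruction settings. The
#' defaults reproduce the base morning case: speed 1.5 m/s, perception 15 m
#' (5 cells), rubble passable (residents can thread between rubble piles),
#' fire impassable. Evening runs conventionally use speed 1.0 m/s and
#' perception 9 m (3 cells).
#'
#' Rescue/support mechanics: gathered rescuers succeed the moment the sum
#' of their expected rescue values exceeds `rescue_threshold` (default 1);
#' if a victim is still unrescued `rescue_give_up` seconds (default 300)
#' after the earthquake, rescuers give up and resume their own evacuation
#' (`give_up_from = "rescue_start"` instead runs the clock per attempt).
#' A perception range of 0 disables mutual assistance altogether (the
#' "absence" comparison case).
#'
#' @param time_of_day `"morning"` (everyone home) or `"evening"`
#'   (commuters absent)
#' @param speed walking speed, m/s
#' @param perception_range metres, in 3 m multiples (0 disables assistance)
#' @param start_window evacuation start times drawn uniformly over this
#'   window (seconds after the earthquake), per household
#' @param assistance_ratios see [draw_assistance_flags()]
#' @param children_10_15_assist if `TRUE`, children aged 10-15 also count
#'   as rescuers (eligibility age 10 instead of 16)
#' @param rubble_blocking `"passable"` or `"impassable"`
#' @param rescue_threshold expected-value sum that must be exceeded
#' @param rescue_give_up seconds before rescuers give up
#' @param give_up_from `"earthquake"` (clock from t = 0) or `"rescue_start"`
#' @param buried_prob probability that an occupant of a collapsed building
#'   is buried (victims needing rescue)
#' @param count_rescued_in_success count rescued-then-evacuated victims in
#'   the successful-evacuation total
#' @param horizon simulation length, seconds
#' @return list of class `scenario`
#' @export
scenario <- function(time_of_day = "morning", speed = 1.5,
                     perception_range = 15, start_window = c(0, 120),
                     assistance_ratios = c(`60-69` = 0.1, `70+` = 0.2,
                                           other = 0.05),
                     children_10_15_assist = FALSE,
                     rubble_blocking = "passable",
                     rescue_threshold = 1, rescue_give_up = 300,
                     give_up_from = "earthquake",
                     buried_prob = 1, count_rescued_in_success = TRUE,
                     horizon = 900) {
  stopifnot(time_of_day %in% c("morning", "evening"),
            speed > 0,
            perception_range >= 0, perception_range %% 3 == 0,
            length(start_window) == 2, start_window[1] <= start_window[2],
            rubble_blocking %in% c("passable", "impassable"),
            give_up_from %in% c("earthquake", "rescue_start"),
            buried_prob >= 0, buried_prob <= 1, horizon >= 1)
  structure(as.list(environment()), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$time_of_day, ", speed ", x$speed, " m/s, perception ",
      x$perception_range, " m (", x$perception_range / 3, " cells), rubble ",
      x$rubble_blocking, ", horizon ", x$horizon, " s\n", sep = "")
  invisible(x)
}

#' Instantiate the agent population for a run
#'
#' Morning runs place every roster member at home; evening runs drop
#' residents flagged as commuters. Assistance-need flags missing from the
#' roster are drawn from the scenario's age-band ratios; household
#' evacuation start times are drawn uniformly over the start window
#' (families leave together, so one draw per household). Each agent gets
#' its expected rescue value (0 for assistance-needing residents and for
#' ages below the rescuer eligibility age, 16 by default or 10 when the
#' children setting is on).
#'
#' @param roster roster data.frame
#' @param scen a [scenario()]
#' @param time_of_day override of the scenario's time of day
#' @param seed integer seed
#' @param table rate table
#' @return agents data.frame
#' @export
init_population <- function(roster, scen = scenario(),
                            time_of_day = scen$time_of_day, seed = 1,
                            table = rescue_rate_table()) {
  if (is.null(roster) || nrow(roster) == 0) stop("empty roster")
  agents <- roster
  if (is.null(agents$household_id)) {
    agents$household_id <- seq_len(nrow(agents))
  }
  if (identical(time_of_day, "evening")) {
    comm <- as.logical(agents$commuter %||% FALSE)
    comm[is.na(comm)] <- FALSE
    agents <- agents[!comm, , drop = FALSE]
    if (nrow(agents) == 0) stop("no residents present in the evening variant")
  }
  with_seed(seed, {
    if (is.null(agents$needs_assistance)) {
      agents$needs_assistance <- draw_assistance_flags(
        agents$age, scen$assistance_ratios
      )
    } else {
      na_idx <- is.na(agents$needs_assistance)
      if (any(na_idx)) {
        agents$needs_assistance[na_idx] <- draw_assistance_flags(
          agents$age[na_idx], scen$assistance_ratios
        )
      }
      agents$needs_assistance <- as.logical(agents$needs_assistance)
    }
    hh <- sort(unique(agents$household_id))
    hh_start <- stats::runif(length(hh), scen$start_window[1],
                             scen$start_window[2])
    agents$start_time <- hh_start[match(agents$household_id, hh)]
  })
  min_age <- if (isTRUE(scen$children_10_15_assist)) 10 else 16
  agents$ev <- resident_expected_values(agents, table,
                                        min_rescuer_age = min_age)
  rownames(agents) <- NULL
  agents
}
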