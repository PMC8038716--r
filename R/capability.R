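#' Distance-decay weight for mutual assistance
#'
#' Residents take time to discover a person who cannot evacuate on their own,
#' increasingly so with distance, and beyond a range limit X (default 100 m)
#' discovery is assumed not to happen. The weight applied to a neighbour
#' building's rescue value at distance D is
#' \deqn{dw(D) = \frac{\log_{10}(1+X)}{2\,(\log_{10}(1+D)+1)}, \quad 0 \le D \le X,}
#' and 0 for D > X. With the default X = 100 this gives dw(0) ~ 1.002, decaying
#' strictly monotonically to ~0.33 at 100 m. The logarithm base is exposed
#' because the weight is a modelling choice, not a physical law; base 10 is
#' the default for the dw(0) ~ 1 normalisation.
#'
#' @param d distance in metres (vectorised), >= 0
#' @param x range limit X in metres (default 100)
#' @param log_base logarithm base (default 10)
#' @return numeric vector of weights in \[0, ~1\]
#' @export
#' @examples
#' distance_weight(0)    # ~1.002
#' distance_weight(150)  # 0: beyond the 100 m range limit
distance_weight <- function(d, x = 100, log_base = 10) {
  if (any(is.na(d)) || any(d < 0)) stop("'d' must be non-negative")
  stopifnot(x > 0)
  w <- log(1 + x, base = log_base) / (2 * (log(1 + d, base = log_base) + 1))
  w[d > x] <- 0
  w
}

#' Expected rescue value of a building
#'
#' Rr of building j: the sum of the expected rescue values of the residents
#' of j. Assistance-needing residents and residents below the rescuer
#' eligibility age contribute 0; an empty building scores 0.
#'
#' @param building_id id of the building to score
#' @param roster roster data.frame (`building_id`, `age`, `gender`,
#'   `needs_assistance`)
#' @param table rate table from [rescue_rate_table()]
#' @param min_rescuer_age see [resident_expected_values()]
#' @return numeric scalar Rr >= 0
#' @export
building_expected_value <- function(building_id, roster,
                                    table = rescue_rate_table(),
                                    min_rescuer_age = 16) {
  rows <- roster[roster$building_id == building_id, , drop = FALSE]
  if (nrow(rows) == 0) return(0)
  sum(resident_expected_values(rows, table, min_rescuer_age))
}

#' Building-unit mutual-assistance capability map
#'
#' For each building i, sums the distance-weighted expected rescue values of
#' all buildings j within the range limit whose straight line of sight to i
#' does not cross an impassable barrier (river, railway, wide trunk road):
#' \deqn{capability(i) = \frac{1}{divisor} \sum_j Rr_j \, dw(D_{ij}).}
#' The divisor defaults to 5. By default the target building's own residents
#' are included at distance 0.
#'
#' @param buildings data.frame with columns `id`, `x`, `y` (projected metres)
#' @param roster roster data.frame (see [building_expected_value()])
#' @param barriers barrier features (see [barrier_segments()]), or `NULL`
#' @param table rate table
#' @param range_limit X in metres (default 100)
#' @param divisor scale divisor in the capability formula (default 5)
#' @param include_self include the target building's own Rr at D = 0
#' @param min_rescuer_age rescuer eligibility age
#' @param log_base passed to [distance_weight()]
#' @return data.frame `id`, `rr` (building expected value), `capability`
#' @export
building_capability <- function(buildings, roster, barriers = NULL,
                                table = rescue_rate_table(),
                                range_limit = 100, divisor = 5,
                                include_self = TRUE, min_rescuer_age = 16,
                                log_base = 10) {
  if (is.null(buildings$x) || is.null(buildings$y) ||
      any(is.na(buildings$x)) || any(is.na(buildings$y))) {
    stop("buildings must have non-missing planar coordinates 'x', 'y'")
  }
  bad <- setdiff(unique(roster$building_id), buildings$id)
  if (length(bad)) {
    stop("roster references unknown building id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  n <- nrow(buildings)
  ev <- resident_expected_values(roster, table, min_rescuer_age)
  rr <- vapply(buildings$id, function(b) {
    sum(ev[roster$building_id == b])
  }, numeric(1))

  segs <- barrier_segments(barriers)
  dx <- outer(buildings$x, buildings$x, "-")
  dy <- outer(buildings$y, buildings$y, "-")
  dist <- sqrt(dx^2 + dy^2)
  w <- distance_weight(as.vector(dist), x = range_limit, log_base = log_base)
  w <- matrix(w, n, n)
  if (!include_self) diag(w) <- 0

  if (nrow(segs) > 0 && n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (w[i, j] > 0 &&
            crosses_barrier(buildings$x[i], buildings$y[i],
                            buildings$x[j], buildings$y[j], segs)) {
          w[i, j] <- 0
          w[j, i] <- 0
        }
      }
    }
  }
  data.frame(id = buildings$id, rr = rr,
             capability = as.vector(w %*% rr) / divisor)
}

#' Group-unit capability accounts (surplus / shortage)
#'
#' For districts organised into small neighbourhood groups whose community
#' ties are strong, capability is accounted per group with no distance
#' weighting: ability = sum of member expected values. Two cases are
#' reported: case 1 subtracts every person needing assistance; case 2 first
#' deducts children under 10 from the count needing assistance (an infant
#' can be carried, a walking child led by the hand, by one adult).
#'
#' Children under 10 are always counted among those needing assistance for
#' the accounting, whether or not the roster flags them.
#'
#' @param roster roster data.frame with `group_id`, `age`, `gender`,
#'   `needs_assistance`
#' @param table rate table
#' @param ability optional numeric vector overriding the computed per-group
#'   ability (e.g. values from a completed capability survey), in group
#'   order
#' @param min_rescuer_age rescuer eligibility age
#' @return data.frame, one row per group: `group_id`, `n_assist`,
#'   `n_under10`, `ability`, `surplus_case1`, `surplus_case2`
#' @export
group_accounts <- function(roster, table = rescue_rate_table(),
                           ability = NULL, min_rescuer_age = 16) {
  groups <- sort(unique(roster$group_id))
  ev <- resident_expected_values(roster, table, min_rescuer_age)
  needs <- as.logical(roster$needs_assistance) | roster$age < 10
  acc <- data.frame(
    group_id = groups,
    n_assist = vapply(groups, function(g) {
      sum(needs[roster$group_id == g])
    }, numeric(1)),
    n_under10 = vapply(groups, function(g) {
      sum(roster$age[roster$group_id == g] < 10)
    }, numeric(1)),
    ability = vapply(groups, function(g) {
      sum(ev[roster$group_id == g])
    }, numeric(1))
  )
  if (!is.null(ability)) {
    stopifnot(length(ability) == nrow(acc))
    acc$ability <- ability
  }
  acc$surplus_case1 <- acc$ability - acc$n_assist
  acc$surplus_case2 <- acc$ability - (acc$n_assist - acc$n_under10)
  acc
}

#' District totals over group accounts
#'
#' Sums counts, ability and both surplus cases over all groups; totals are
#' exact sums of the per-group values.
#'
#' @param accounts data.frame from [group_accounts()]
#' @return one-row data.frame of totals
#' @export
district_totals <- function(accounts) {
  stopifnot(nrow(accounts) >= 1)
  data.frame(
    n_groups = nrow(accounts),
    n_assist = sum(accounts$n_assist),
    n_under10 = sum(accounts$n_under10),
    ability = sum(accounts$ability),
    surplus_case1 = sum(accounts$surplus_case1),
    surplus_case2 = sum(accounts$surplus_case2)
  )
}
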