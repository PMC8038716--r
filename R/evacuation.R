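# One-second-step multi-agent evacuation with mutual assistance on the road
# network, under a precomputed (read-only) hazard timeline. Households move
# as units (families do not evacuate apart); victims -- buried occupants of
# collapsed buildings and residents needing evacuation support -- wait at
# their building until gathered rescuers' summed expected value exceeds the
# threshold, until rescuers give up, or until fire makes them unreachable.

# unit / victim state codes
.U_PRE <- 0L; .U_MOVING <- 1L; .U_GOING <- 2L; .U_RESCUING <- 3L
.U_EVAC <- 4L; .U_AWAIT <- 5L; .U_CASUALTY <- 6L
.V_WAITING <- 0L; .V_RESCUED <- 1L; .V_AWAIT <- 2L; .V_CASUALTY <- 3L

#' Build the road-network graph of a town
#'
#' @param town a `town`
#' @return an igraph with vertex names = node ids, edge attributes
#'   `link_id` and `weight` (= link length, m)
#' @export
build_graph <- function(town) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(town$links$from),
               to = as.character(town$links$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(town$nodes$id))
  )
  igraph::E(g)$link_id <- town$links$id
  igraph::E(g)$weight <- town$links$length
  g
}

#' Shortest route to the nearest evacuation site
#'
#' Network-length shortest path from a node to the nearest designated
#' evacuation site, avoiding the currently blocked links; ties between
#' sites are broken by the smallest site id. Returns `NULL` when no site
#' is reachable (the agent must then await public help).
#'
#' @param node starting node id
#' @param town a `town`
#' @param blocked integer vector of blocked link ids
#' @param graph optional prebuilt [build_graph()] result
#' @return `NULL`, or list with `site` (site id), `nodes` (node-id path),
#'   `length` (metres)
#' @export
choose_destination <- function(node, town, blocked = integer(0),
                               graph = NULL) {
  if (is.null(graph)) graph <- build_graph(town)
  if (length(blocked)) {
    graph <- igraph::delete_edges(graph,
                                  which(igraph::E(graph)$link_id %in% blocked))
  }
  route_via(graph, node, town$sites$node, site_ids = town$sites$id)
}

# shortest path from `from` to the nearest of `targets`; returns NULL when
# unreachable. site_ids label the targets (ties -> smallest label).
route_via <- function(graph, from, targets, site_ids = targets) {
  d <- suppressWarnings(igraph::distances(
    graph, v = as.character(from), to = as.character(targets)
  ))[1, ]
  if (all(!is.finite(d))) return(NULL)
  k <- which.min(d)  # first minimum = smallest site id (targets in id order)
  sp <- suppressWarnings(igraph::shortest_paths(
    graph, from = as.character(from), to = as.character(targets[k]),
    output = "vpath"
  ))
  nodes <- as.integer(names(sp$vpath[[1]]))
  list(site = site_ids[k], nodes = nodes, length = unname(d[k]))
}

#' Run one evacuation simulation
#'
#' Steps the world one second at a time until every agent reaches a
#' terminal state (evacuated, awaiting public support, casualty) or the
#' horizon is hit; any agent still unresolved at the horizon is classified
#' as awaiting public support. Deterministic given (town, timeline,
#' scenario, seed).
#'
#' @param town a `town`
#' @param timeline a [build_timeline()] result covering the scenario horizon
#' @param scen a [scenario()]
#' @param seed integer seed (population draws: start times, buried draws,
#'   assistance flags if missing)
#' @return list of class `sim_result`: `agents` (per-resident outcome),
#'   `counts`, `events`, `seed`
#' @export
run_simulation <- function(town, timeline, scen = scenario(), seed = 1) {
  if (timeline$horizon < scen$horizon) {
    stop("hazard timeline (", timeline$horizon,
         " s) does not cover the scenario horizon (", scen$horizon, " s)")
  }
  agents <- init_population(town$roster, scen, seed = derive_seed(seed, 1))
  n <- nrow(agents)
  b_row <- match(agents$building_id, town$buildings$id)

  # --- victims ---------------------------------------------------------
  in_collapsed <- agents$building_id %in% timeline$collapsed
  buried <- in_collapsed &
    with_seed(derive_seed(seed, 2), stats::runif(n)) < scen$buried_prob
  support <- !buried & agents$needs_assistance & agents$age >= 10
  is_victim <- buried | support
  vict_idx <- which(is_victim)
  nv <- length(vict_idx)
  v_agent <- vict_idx
  v_hh <- agents$household_id[vict_idx]
  v_node <- town$buildings$node[b_row[vict_idx]]
  v_x <- town$buildings$x[b_row[vict_idx]]
  v_y <- town$buildings$y[b_row[vict_idx]]
  v_kind <- ifelse(buried[vict_idx], "rescue", "support")
  v_state <- rep(.V_WAITING, nv)
  v_pool <- numeric(nv)
  v_clock0 <- if (identical(scen$give_up_from, "earthquake")) {
    rep(0, nv)
  } else {
    rep(NA_real_, nv)
  }
  v_t <- rep(NA_real_, nv)
  v_engaged <- vector("list", nv)
  v_bign <- timeline$building_ignition[b_row[vict_idx]]  # NA = never burns

  # --- household units -------------------------------------------------
  mobile <- !is_victim
  hh_ids <- sort(unique(agents$household_id[mobile]))
  nu <- length(hh_ids)
  u_members <- lapply(hh_ids, function(h) {
    which(mobile & agents$household_id == h)
  })
  u_extra <- vector("list", nu)            # rescued victims who joined
  u_node0 <- vapply(u_members, function(m) {
    town$buildings$node[b_row[m[1]]]
  }, numeric(1))
  u_brow <- vapply(u_members, function(m) b_row[m[1]], numeric(1))
  u_escort <- vapply(u_members, function(m) any(agents$age[m] < 10),
                     logical(1))
  u_evsum <- vapply(u_members, function(m) sum(agents$ev[m]), numeric(1))
  u_start <- vapply(u_members, function(m) min(agents$start_time[m]),
                    numeric(1))
  u_state <- rep(.U_PRE, nu)
  u_tout <- rep(NA_real_, nu)
  u_site <- rep(NA_integer_, nu)
  u_tgt <- rep(NA_integer_, nu)            # victim index while GOING/RESCUING
  u_bign <- timeline$building_ignition[u_brow]

  # route storage
  r_nodes <- vector("list", nu)
  r_cum <- vector("list", nu)
  r_legs <- vector("list", nu)             # link id per leg
  pos <- numeric(nu)
  li <- integer(nu)
  g_fx <- g_fy <- g_tx <- g_ty <- numeric(nu)

  # --- network state ---------------------------------------------------
  graph <- build_graph(town)
  nlinks <- nrow(town$links)
  blocked_now <- if (identical(scen$rubble_blocking, "impassable")) {
    timeline$rubble$blocked
  } else {
    rep(FALSE, nlinks)
  }
  fire_steps <- timeline$link_fire_step
  link_key <- paste(pmin(town$links$from, town$links$to),
                    pmax(town$links$from, town$links$to), sep = "|")
  link_of <- stats::setNames(town$links$id, link_key)
  g_cur <- NULL
  site_cache <- NULL
  rebuild_graph <- function() {
    g_cur <<- if (any(blocked_now)) {
      igraph::delete_edges(graph,
                           which(blocked_now[igraph::E(graph)$link_id]))
    } else {
      graph
    }
    site_cache <<- new.env(parent = emptyenv())
  }
  rebuild_graph()
  route_to_site <- function(node) {
    key <- as.character(node)
    if (!is.null(site_cache[[key]])) {
      r <- site_cache[[key]]
      return(if (identical(r, "none")) NULL else r)
    }
    r <- route_via(g_cur, node, town$sites$node, town$sites$id)
    site_cache[[key]] <- if (is.null(r)) "none" else r
    r
  }

  events <- list()
  log_event <- function(t, type, victim = NA, unit = NA) {
    events[[length(events) + 1]] <<- data.frame(
      t = t, type = type, victim = victim, unit = unit
    )
  }

  set_route <- function(u, nodes_path) {
    k <- length(nodes_path)
    if (k < 2) {
      r_nodes[[u]] <<- nodes_path
      r_cum[[u]] <<- 0
      r_legs[[u]] <<- integer(0)
      pos[u] <<- 0; li[u] <<- 0L
      return(TRUE)
    }
    legs <- unname(link_of[paste(pmin(nodes_path[-k], nodes_path[-1]),
                                 pmax(nodes_path[-k], nodes_path[-1]),
                                 sep = "|")])
    lens <- town$links$length[legs]
    r_nodes[[u]] <<- nodes_path
    r_cum[[u]] <<- c(0, cumsum(lens))
    r_legs[[u]] <<- legs
    pos[u] <<- 0
    li[u] <<- 1L
    a <- nodes_path[1]; b <- nodes_path[2]
    g_fx[u] <<- town$nodes$x[a]; g_fy[u] <<- town$nodes$y[a]
    g_tx[u] <<- town$nodes$x[b]; g_ty[u] <<- town$nodes$y[b]
    TRUE
  }

  unit_node <- function(u) {
    # node the unit is at (only valid when pos sits on a node)
    r_nodes[[u]][max(1L, li[u])]
  }

  finish_unit <- function(u, state, t) {
    u_state[u] <<- state
    u_tout[u] <<- t
  }

  # send unit toward the site network-nearest to `from`; AWAIT when cut off
  head_to_site <- function(u, from, t) {
    r <- route_to_site(from)
    if (is.null(r)) {
      finish_unit(u, .U_AWAIT, t)
      log_event(t, "no_route", unit = u)
      return(invisible(NULL))
    }
    u_site[u] <<- r$site
    u_tgt[u] <<- NA_integer_
    set_route(u, r$nodes)
    if (length(r$nodes) < 2) {
      finish_unit(u, .U_EVAC, t)
    } else {
      u_state[u] <<- .U_MOVING
    }
    invisible(NULL)
  }

  engage <- function(u, v, t) {
    u_state[u] <<- .U_RESCUING
    u_tgt[u] <<- v
    v_engaged[[v]] <<- union(v_engaged[[v]], u)
    v_pool[v] <<- v_pool[v] + u_evsum[u]
    if (is.na(v_clock0[v])) v_clock0[v] <<- t
    log_event(t, "engage", victim = v, unit = u)
    if (v_pool[v] > scen$rescue_threshold) resolve_victim(v, t)
    invisible(NULL)
  }

  # rescue/support succeeded: victim joins the first engaged unit
  resolve_victim <- function(v, t) {
    v_state[v] <<- .V_RESCUED
    v_t[v] <<- t
    units <- v_engaged[[v]]
    log_event(t, if (v_kind[v] == "rescue") "rescued" else "supported",
              victim = v, unit = units[1])
    u_extra[[units[1]]] <<- c(u_extra[[units[1]]], v_agent[v])
    for (u in units) release_unit(u, t)
    v_engaged[[v]] <<- integer(0)
    invisible(NULL)
  }

  # a rescuing/going unit is freed (success, give-up, or victim casualty):
  # engage another open victim of its own household, else head to the site
  release_unit <- function(u, t) {
    node <- if (u_state[u] == .U_RESCUING) {
      v_node[u_tgt[u]]
    } else {
      unit_node(u)
    }
    u_tgt[u] <<- NA_integer_
    own <- which(v_state == .V_WAITING & v_hh == hh_ids[u] &
                   v_node == node)
    if (length(own) && scen$perception_range > 0 &&
        t < give_up_limit) {
      engage(u, own[1], t)
    } else {
      head_to_site(u, node, t)
    }
    invisible(NULL)
  }

  give_up_limit <- if (identical(scen$give_up_from, "earthquake")) {
    scen$rescue_give_up
  } else {
    Inf
  }
  assistance_on <- scen$perception_range > 0
  segs <- town$barriers

  abandon_victim <- function(v, t, why) {
    old <- v_state[v]
    v_state[v] <<- if (identical(why, "fire")) .V_CASUALTY else .V_AWAIT
    v_t[v] <<- t
    log_event(t, paste0("victim_", why), victim = v)
    units <- v_engaged[[v]]
    v_engaged[[v]] <<- integer(0)
    if (old == .V_WAITING && length(units)) {
      for (u in units) release_unit(u, t)
    }
    invisible(NULL)
  }

  # ---- main loop ------------------------------------------------------
  for (t in 0:scen$horizon) {
    # 1. fire reaches buildings: occupants and waiting victims are lost
    if (nv) {
      burn_v <- which(v_state == .V_WAITING & !is.na(v_bign) & v_bign <= t)
      for (v in burn_v) abandon_victim(v, t, "fire")
    }
    burn_u <- which(u_state == .U_PRE & !is.na(u_bign) & u_bign <= t)
    for (u in burn_u) {
      finish_unit(u, .U_CASUALTY, t)
      log_event(t, "unit_fire", unit = u)
    }
    # newly fire-blocked links
    newly <- which(!blocked_now & !is.na(fire_steps) & fire_steps <= t)
    if (length(newly)) {
      blocked_now[newly] <- TRUE
      rebuild_graph()
      for (u in which(u_state %in% c(.U_MOVING, .U_GOING))) {
        if (li[u] >= 1 && li[u] <= length(r_legs[[u]]) &&
            blocked_now[r_legs[[u]][li[u]]]) {
          # fall back to the near end of the now-burning link and replan
          pos[u] <- r_cum[[u]][li[u]]
          node <- r_nodes[[u]][li[u]]
          if (u_state[u] == .U_GOING) {
            v <- u_tgt[u]
            p <- route_via(g_cur, node, v_node[v])
            if (!is.null(p) && v_state[v] == .V_WAITING) {
              set_route(u, p$nodes)
            } else {
              head_to_site(u, node, t)
            }
          } else {
            head_to_site(u, node, t)
          }
        }
      }
    }
    # 2. evacuation starts
    for (u in which(u_state == .U_PRE & u_start <= t)) {
      own <- which(v_state == .V_WAITING & v_hh == hh_ids[u] &
                     v_node == u_node0[u])
      if (assistance_on && t < give_up_limit && length(own)) {
        engage(u, own[1], t)
      } else {
        head_to_site(u, u_node0[u], t)
      }
    }
    # 3. give-up clock
    if (nv) {
      expire <- which(v_state == .V_WAITING & !is.na(v_clock0) &
                        t >= v_clock0 + scen$rescue_give_up &
                        (identical(scen$give_up_from, "earthquake") |
                           lengths(v_engaged) > 0))
      for (v in expire) abandon_victim(v, t, "abandoned")
    }
    # 4. perception: evacuating units (not escorting small children) divert
    if (assistance_on && t < give_up_limit && nv) {
      open_v <- which(v_state == .V_WAITING)
      movers <- if (length(open_v)) {
        which(u_state == .U_MOVING & !u_escort & u_evsum > 0)
      } else {
        integer(0)
      }
      for (u in movers) {
        if (li[u] < 1) next
        ll <- r_cum[[u]][li[u] + 1L] - r_cum[[u]][li[u]]
        fr <- if (ll > 0) (pos[u] - r_cum[[u]][li[u]]) / ll else 0
        ux <- g_fx[u] + fr * (g_tx[u] - g_fx[u])
        uy <- g_fy[u] + fr * (g_ty[u] - g_fy[u])
        d <- sqrt((v_x[open_v] - ux)^2 + (v_y[open_v] - uy)^2)
        near <- open_v[d <= scen$perception_range]
        dd <- d[d <= scen$perception_range]
        if (!length(near)) next
        o <- order(dd, near)
        target <- NA_integer_
        for (k in o) {
          if (!crosses_barrier(ux, uy, v_x[near[k]], v_y[near[k]], segs)) {
            target <- near[k]
            break
          }
        }
        if (is.na(target)) next
        # divert: continue to the end of the current leg, then to the victim
        from <- r_nodes[[u]][li[u] + 1L]
        p <- route_via(g_cur, from, v_node[target])
        if (is.null(p)) next
        keep_from <- r_nodes[[u]][li[u]]
        new_nodes <- c(keep_from, p$nodes)
        off <- pos[u] - r_cum[[u]][li[u]]
        set_route(u, new_nodes)
        pos[u] <- off
        u_state[u] <- .U_GOING
        u_tgt[u] <- target
        log_event(t, "divert", victim = target, unit = u)
      }
    }
    # 5. movement
    active <- which(u_state %in% c(.U_MOVING, .U_GOING))
    if (length(active)) {
      pos[active] <- pos[active] + scen$speed
      for (u in active) {
        repeat {
          cu <- r_cum[[u]]
          k <- li[u]
          if (k >= length(r_legs[[u]]) + 1L) break
          if (pos[u] < cu[k + 1L] - 1e-9) break
          # reached node k+1
          if (k + 1L == length(r_nodes[[u]])) {
            # final node of the route
            if (u_state[u] == .U_GOING) {
              v <- u_tgt[u]
              if (v_state[v] == .V_WAITING) {
                engage(u, v, t)
              } else {
                release_unit_at <- r_nodes[[u]][k + 1L]
                u_tgt[u] <- NA_integer_
                head_to_site(u, release_unit_at, t)
              }
            } else {
              finish_unit(u, .U_EVAC, t)
            }
            break
          }
          nxt <- r_legs[[u]][k + 1L]
          if (blocked_now[nxt]) {
            pos[u] <- cu[k + 1L]
            node <- r_nodes[[u]][k + 1L]
            # advance the anchor so unit_node() reports this node
            r_nodes[[u]] <- r_nodes[[u]][(k + 1L):length(r_nodes[[u]])]
            r_legs[[u]] <- r_legs[[u]][-seq_len(k)]
            r_cum[[u]] <- cu[(k + 1L):length(cu)] - cu[k + 1L]
            pos[u] <- 0; li[u] <- 1L
            if (u_state[u] == .U_GOING && v_state[u_tgt[u]] == .V_WAITING) {
              p <- route_via(g_cur, node, v_node[u_tgt[u]])
              if (is.null(p)) {
                head_to_site(u, node, t)
              } else {
                set_route(u, p$nodes)
              }
            } else {
              head_to_site(u, node, t)
            }
            break
          }
          li[u] <- k + 1L
          a <- r_nodes[[u]][k + 1L]; b2 <- r_nodes[[u]][k + 2L]
          g_fx[u] <- town$nodes$x[a]; g_fy[u] <- town$nodes$y[a]
          g_tx[u] <- town$nodes$x[b2]; g_ty[u] <- town$nodes$y[b2]
        }
      }
    }
    if (all(u_state >= .U_EVAC) && (nv == 0 || all(v_state != .V_WAITING))) {
      break
    }
  }

  # horizon reached: everyone unresolved awaits public help
  for (u in which(u_state < .U_EVAC)) finish_unit(u, .U_AWAIT, scen$horizon)
  for (v in which(v_state == .V_WAITING)) {
    v_state[v] <- .V_AWAIT
    v_t[v] <- scen$horizon
  }

  # ---- per-agent outcomes --------------------------------------------
  outcome <- rep(NA_character_, n)
  t_out <- rep(NA_real_, n)
  site_out <- rep(NA_integer_, n)
  unit_outcome <- c("evacuated", "awaiting_public", "casualty")[
    match(u_state, c(.U_EVAC, .U_AWAIT, .U_CASUALTY))
  ]
  for (u in seq_len(nu)) {
    idx <- c(u_members[[u]], u_extra[[u]])
    outcome[idx] <- unit_outcome[u]
    t_out[idx] <- u_tout[u]
    if (u_state[u] == .U_EVAC) site_out[idx] <- u_site[u]
  }
  # victims not rescued carry their own terminal state
  unres <- which(v_state != .V_RESCUED)
  outcome[v_agent[unres]] <- c("awaiting_public", "casualty")[
    match(v_state[unres], c(.V_AWAIT, .V_CASUALTY))
  ]
  t_out[v_agent[unres]] <- v_t[unres]

  received <- logical(n)
  received[v_agent[v_state == .V_RESCUED]] <- TRUE
  was_victim <- logical(n)
  was_victim[v_agent] <- TRUE

  res_agents <- data.frame(
    resident_id = agents$resident_id,
    household_id = agents$household_id,
    building_id = agents$building_id,
    outcome = outcome, t_out = t_out, site = site_out,
    was_victim = was_victim, victim_kind = NA_character_,
    received_assistance = received
  )
  res_agents$victim_kind[v_agent] <- v_kind

  n_evac <- sum(outcome == "evacuated")
  if (!isTRUE(scen$count_rescued_in_success)) {
    n_evac <- n_evac - sum(received & outcome == "evacuated")
  }
  counts <- list(
    n_present = n,
    n_evacuated = n_evac,
    n_awaiting = sum(outcome == "awaiting_public"),
    n_casualty = sum(outcome == "casualty"),
    n_requiring = nv,
    n_receiving = sum(v_state == .V_RESCUED)
  )
  events <- if (length(events)) {
    do.call(rbind, events)
  } else {
    data.frame(t = numeric(0), type = character(0), victim = numeric(0),
               unit = numeric(0))
  }
  structure(list(agents = res_agents, counts = counts, events = events,
                 seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  with(x$counts, cat(
    "<sim_result> ", n_present, " residents: ", n_evacuated, " evacuated, ",
    n_awaiting, " awaiting public help, ", n_casualty, " casualties; ",
    n_receiving, "/", n_requiring, " received mutual assistance\n", sep = ""
  ))
  invisible(x)
}

#' Run a batch of simulations
#'
#' Repeats hazard generation + evacuation `n_runs` times (the conventional
#' protocol is ten) with independent per-run seeds derived from the master
#' seed; results are order-stable and the whole batch is reproducible.
#'
#' @param town a `town`
#' @param scen a [scenario()]
#' @param n_runs number of runs (default 10)
#' @param master_seed master seed
#' @param collapse_config,fire passed to [build_timeline()]
#' @param rubble_k rubble intrusion scale
#' @return list of class `sim_batch` of `sim_result`s
#' @export
run_batch <- function(town, scen = scenario(), n_runs = 10, master_seed = 1,
                      collapse_config = default_collapse_config(),
                      fire = fire_params(), rubble_k = 0.5) {
  stopifnot(n_runs >= 1)
  field <- rasterize_town(town)
  adjacency <- building_adjacent_links(town)
  out <- lapply(seq_len(n_runs), function(i) {
    run_seed <- derive_seed(master_seed, i)
    tl <- build_timeline(town, collapse_config, fire,
                         horizon = scen$horizon,
                         seed = derive_seed(run_seed, 1),
                         rubble_k = rubble_k,
                         field = field, adjacency = adjacency)
    run_simulation(town, tl, scen, seed = derive_seed(run_seed, 2))
  })
  structure(out, class = "sim_batch")
}

#' @export
print.sim_batch <- function(x, ...) {
  cat("<sim_batch> ", length(x), " runs; successful evacuations: ",
      paste(vapply(x, function(r) r$counts$n_evacuated, numeric(1)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}
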