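# Agent-based synthetic colony simulator.
#
# Movement model: individuals alternate exponentially distributed rest bouts
# (spent in the nest chamber) and active bouts during which they make "trips"
# -- shortest-path walks between boxes with short exponential transit dwells
# in pipes and a longer dwell at the destination box.  Rest-rhythm coupling
# is planted through a colony-level "rest call": every spontaneous rest onset
# is broadcast, and each active individual joins the caller with probability
# equal to the coupling matrix entry.  Co-location preference is planted by
# giving each planted pair a shared, slowly changing preferred destination
# box.  Follower-followee relations are planted by letting the follower
# shadow the followee's trajectory at a fixed sub-lag delay, so that every
# movement of the followee is re-traced within the follow lag.

#' Colony simulation configuration
#'
#' Bundles all parameters of the synthetic colony generator.  Bout and dwell
#' parameters may be scalars or length-\code{n_individuals} vectors, which
#' allows planting distinct behavioral phenotypes.
#'
#' @param n_individuals Number of individuals.
#' @param duration_s Recording length in seconds (integer multiple of
#'   \code{tick_s}).
#' @param tick_s Tick resolution in seconds (default 0.1).
#' @param rest_bout_mean_s Mean rest-bout duration (default 5000 s, giving
#'   multi-hour rests in the upper mode of the nest-stay distribution).
#' @param active_bout_mean_s Mean active-bout duration (default 3600 s).
#' @param box_dwell_mean_s Mean dwell at a destination box (default 30 s).
#' @param nest_visit_mean_s Mean dwell for short nest visits while active
#'   (default 6 s, the lower mode of the nest-stay distribution).
#' @param pipe_transit_mean_s,box_transit_mean_s Mean transit dwells while
#'   walking (defaults 2 s).
#' @param resettle_mean_s Mean delay until interrupted resters return to the
#'   nest after a disturbance ends (default 300 s).
#' @param nest_cell,toilet_cell,garbage_cell Box cell ids of the functional
#'   chambers.
#' @param coupling Symmetric n x n matrix in \code{[0, 1]}: probability that
#'   an active individual joins the other's rest onset.  Diagonal ignored.
#' @param co_location Symmetric n x n matrix in \code{[0, 1]}: probability
#'   that a trip is directed to the pair's shared preferred box.
#' @param follow Directed n x n matrix in \code{[0, 1]}: \code{follow[a, b]}
#'   is the probability that one of a's active bouts is spent shadowing b
#'   (re-tracing b's movements within \code{follow_lag_s}); a value of 1
#'   makes a shadow b for the whole recording.
#' @param follow_lag_s Maximum re-trace lag in seconds (default 3).
#' @param disturbance_rate_per_day Expected number of colony-wide
#'   disturbance episodes per day (default 2); each forces all individuals
#'   out of the nest for 10 to 30 minutes.
#' @param miss_rate Probability that a true reader crossing emits no
#'   detection.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param ids Individual ids (default \code{ind01}, \code{ind02}, ...).
#' @return A validated list of class \code{colony_config}.
#' @export
colony_config <- function(n_individuals,
                          duration_s,
                          tick_s = 0.1,
                          rest_bout_mean_s = 5000,
                          active_bout_mean_s = 3600,
                          box_dwell_mean_s = 30,
                          nest_visit_mean_s = 6,
                          pipe_transit_mean_s = 2,
                          box_transit_mean_s = 2,
                          resettle_mean_s = 300,
                          nest_cell = cell_id(0, 0),
                          toilet_cell = cell_id(0, 4),
                          garbage_cell = cell_id(2, 2),
                          coupling = NULL,
                          co_location = NULL,
                          follow = NULL,
                          follow_lag_s = 3,
                          disturbance_rate_per_day = 2,
                          miss_rate = 0,
                          seed = 1L,
                          ids = sprintf("ind%02d", seq_len(n_individuals))) {
  n <- n_individuals
  zero <- matrix(0, n, n)
  if (is.null(coupling)) coupling <- zero
  if (is.null(co_location)) co_location <- zero
  if (is.null(follow)) follow <- zero

  chk_mat <- function(m, name, symmetric) {
    if (!is.matrix(m) || !all(dim(m) == n))
      stop("configuration error: ", name, " must be a ", n, "x", n,
           " matrix", call. = FALSE)
    if (any(m < 0 | m > 1))
      stop("configuration error: ", name, " entries must lie in [0, 1]",
           call. = FALSE)
    if (symmetric && !isTRUE(all.equal(m, t(m))))
      stop("configuration error: ", name, " must be symmetric",
           call. = FALSE)
    diag(m) <- 0
    m
  }
  coupling <- chk_mat(coupling, "coupling", TRUE)
  co_location <- chk_mat(co_location, "co_location", TRUE)
  follow <- chk_mat(follow, "follow", FALSE)

  chk_pos <- function(x, name, len_ok = c(1L, n)) {
    if (!length(x) %in% len_ok || any(x <= 0))
      stop("configuration error: ", name,
           " must be positive (scalar or one value per individual)",
           call. = FALSE)
    rep_len(as.numeric(x), n)
  }
  if (tick_s <= 0)
    stop("configuration error: tick_s must be positive", call. = FALSE)
  if (abs(duration_s / tick_s - round(duration_s / tick_s)) > 1e-8)
    stop("configuration error: duration_s must be an integer multiple of ",
         "tick_s", call. = FALSE)
  if (miss_rate < 0 || miss_rate > 1)
    stop("configuration error: miss_rate must lie in [0, 1]", call. = FALSE)
  if (follow_lag_s <= 0)
    stop("configuration error: follow_lag_s must be positive", call. = FALSE)
  if (disturbance_rate_per_day < 0)
    stop("configuration error: disturbance_rate_per_day must be ",
         "non-negative", call. = FALSE)
  if (length(ids) != n || anyDuplicated(ids))
    stop("configuration error: ids must be ", n, " unique values",
         call. = FALSE)
  kinds <- grid_cell_kinds()
  for (nm in c("nest_cell", "toilet_cell", "garbage_cell")) {
    cc <- get(nm)
    if (length(cc) != 1 || kinds[cc] != "box")
      stop("configuration error: ", nm, " must be a single box cell",
           call. = FALSE)
  }

  structure(list(
    n_individuals = n, duration_s = duration_s, tick_s = tick_s,
    rest_bout_mean_s = chk_pos(rest_bout_mean_s, "rest_bout_mean_s"),
    active_bout_mean_s = chk_pos(active_bout_mean_s, "active_bout_mean_s"),
    box_dwell_mean_s = chk_pos(box_dwell_mean_s, "box_dwell_mean_s"),
    nest_visit_mean_s = chk_pos(nest_visit_mean_s, "nest_visit_mean_s"),
    pipe_transit_mean_s = pipe_transit_mean_s,
    box_transit_mean_s = box_transit_mean_s,
    resettle_mean_s = resettle_mean_s,
    nest_cell = nest_cell, toilet_cell = toilet_cell,
    garbage_cell = garbage_cell,
    coupling = coupling, co_location = co_location, follow = follow,
    follow_lag_s = follow_lag_s,
    disturbance_rate_per_day = disturbance_rate_per_day,
    miss_rate = miss_rate, seed = as.integer(seed), ids = ids),
    class = "colony_config")
}

individual_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647)
}

# Colony-wide disturbance episodes: forced-active intervals of 10-30 min.
sim_disturbances <- function(cfg) {
  n_ev <- stats::rpois(1, cfg$disturbance_rate_per_day *
                            cfg$duration_s / 86400)
  if (n_ev == 0) return(matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("start", "end"))))
  start <- sort(stats::runif(n_ev, 0, cfg$duration_s))
  end <- pmin(start + stats::runif(n_ev, 600, 1800), cfg$duration_s)
  # merge overlapping episodes
  keep_s <- start[1]; keep_e <- end[1]
  for (k in seq_len(n_ev)[-1]) {
    if (start[k] <= keep_e[length(keep_e)]) {
      keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], end[k])
    } else {
      keep_s <- c(keep_s, start[k]); keep_e <- c(keep_e, end[k])
    }
  }
  cbind(start = keep_s, end = keep_e)
}

# Alternating rest/active schedule with rest-call coupling and disturbance
# truncation.  Returns a list of per-individual matrices (start, end).
sim_rest_schedule <- function(cfg, dist) {
  n <- cfg$n_individuals
  T_end <- cfg$duration_s
  d_start <- dist[, 1]; d_end <- dist[, 2]

  in_dist <- function(t) {
    k <- findInterval(t, d_start)
    k > 0 && t < d_end[k]
  }
  dist_end_at <- function(t) d_end[findInterval(t, d_start)]
  next_dist_start <- function(t) {
    later <- d_start[d_start > t]
    if (length(later)) later[1] else Inf
  }

  rest_s <- lapply(seq_len(n), function(i) numeric(0))
  rest_e <- rest_s
  r_until <- numeric(n)                 # resting until this time (0 = active)
  nxt <- stats::rexp(n, 1 / cfg$active_bout_mean_s)
  # stationary start: part of the colony is already resting at time zero
  p_rest0 <- cfg$rest_bout_mean_s /
    (cfg$rest_bout_mean_s + cfg$active_bout_mean_s)
  rest0 <- stats::runif(n) < p_rest0
  for (i in which(rest0)) {
    end <- min(stats::rexp(1, 1 / cfg$rest_bout_mean_s), T_end)
    if (nrow(dist) > 0 && dist[1, 1] < end) end <- dist[1, 1]
    if (end > 0) {
      rest_s[[i]] <- 0; rest_e[[i]] <- end; r_until[i] <- end
      nxt[i] <- end + stats::rexp(1, 1 / cfg$active_bout_mean_s[i])
    }
  }

  start_rest <- function(i, t, end_at = NULL) {
    # joiners adopt the caller's bout end (jittered), so a coupled pair
    # shares the whole rest bout, not just its onset
    d <- if (is.null(end_at)) stats::rexp(1, 1 / cfg$rest_bout_mean_s[i])
         else max(end_at + stats::runif(1, 0, 30) - t, 1)
    nd <- next_dist_start(t)
    end <- min(t + d, T_end, nd)
    if (end > t) {
      rest_s[[i]] <<- c(rest_s[[i]], t)
      rest_e[[i]] <<- c(rest_e[[i]], end)
      r_until[i] <<- end
    }
    if (end == nd && nd < T_end) {
      # rest cut short by a disturbance; re-settle shortly after it ends
      nxt[i] <<- dist_end_at(nd) + stats::rexp(1, 1 / cfg$resettle_mean_s)
    } else {
      nxt[i] <<- end + stats::rexp(1, 1 / cfg$active_bout_mean_s[i])
    }
  }

  repeat {
    i <- which.min(nxt)
    t <- nxt[i]
    if (t >= T_end) break
    if (in_dist(t)) {
      nxt[i] <- dist_end_at(t) + stats::rexp(1, 1 / cfg$resettle_mean_s)
      next
    }
    start_rest(i, t)                    # spontaneous onset = rest call
    caller_end <- r_until[i]
    joiners <- which(cfg$coupling[, i] > 0 & r_until <= t &
                       seq_len(n) != i)
    for (j in joiners) {
      if (stats::runif(1) < cfg$coupling[j, i]) {
        tj <- t + stats::runif(1, 0, 5)
        if (tj < T_end && !in_dist(tj)) start_rest(j, tj, caller_end)
      }
    }
  }
  lapply(seq_len(n), function(i) cbind(start = rest_s[[i]],
                                       end = rest_e[[i]]))
}

# Shared preferred destination boxes for planted co-location pairs: a step
# function over time, redrawn hourly from the non-nest boxes.
sim_pair_preferences <- function(cfg, layout, step_s = 3600) {
  pairs <- which(upper.tri(cfg$co_location) & cfg$co_location > 0,
                 arr.ind = TRUE)
  if (nrow(pairs) == 0) return(list(pairs = pairs, breaks = NULL,
                                    boxes = NULL))
  breaks <- seq(0, cfg$duration_s, by = step_s)
  candidates <- setdiff(layout$boxes, cfg$nest_cell)
  boxes <- matrix(sample(candidates, nrow(pairs) * length(breaks),
                         replace = TRUE),
                  nrow = nrow(pairs))
  list(pairs = pairs, breaks = breaks, boxes = boxes)
}

pref_box_at <- function(prefs, pair_row, t) {
  prefs$boxes[pair_row, findInterval(t, prefs$breaks)]
}

# Build one individual's trajectory (entry times + cells) from its rest
# schedule by stringing together trips.  A trip never enters a pipe whose
# exit would fall beyond the recording end, so every trajectory ends in a
# box.
build_base_trajectory <- function(i, cfg, layout, rest_iv, prefs) {
  T_end <- cfg$duration_s
  nest <- cfg$nest_cell
  co <- cfg$co_location[i, ]
  partners <- which(co > 0)
  partner_rows <- if (length(partners)) vapply(partners, function(j) {
    hit <- which((prefs$pairs[, 1] == min(i, j) &
                    prefs$pairs[, 2] == max(i, j)) |
                   (prefs$pairs[, 1] == max(i, j) &
                      prefs$pairs[, 2] == min(i, j)))
    hit[1]
  }, integer(1)) else integer(0)

  acc_t <- vector("list", 256); acc_c <- vector("list", 256); na <- 0L
  push <- function(tv, cv) {
    na <<- na + 1L
    if (na > length(acc_t)) {
      length(acc_t) <<- 2L * na; length(acc_c) <<- 2L * na
    }
    acc_t[[na]] <<- tv; acc_c[[na]] <<- cv
  }
  push(0, nest)
  # box dwells are floored just above the tracker's same-reader
  # re-detection threshold so a box visit is always distinguishable from
  # lingering inside the antenna ring
  dwell_floor <- 0.4
  rdwell <- function(n, mean) dwell_floor + stats::rexp(n, 1 / mean)
  t_now <- rdwell(1, cfg$nest_visit_mean_s[i]); cur <- nest

  choose_dest <- function(t) {
    for (k in seq_along(partners)) {
      if (stats::runif(1) < co[partners[k]])
        return(pref_box_at(prefs, partner_rows[k], t))
    }
    sample(setdiff(layout$boxes, cur), 1)
  }

  # walk cur -> dest starting at time t_now; returns FALSE if truncated at T
  do_walk <- function(dest, final_dwell_mean) {
    path <- layout$paths[[cur, dest]]
    if (length(path) > 1) {
      steps <- path[-1]
      k <- length(steps)
      dwell <- numeric(k)
      is_pipe <- layout$kind[steps] == "pipe"
      # pipe transits are floored above the tick so that every crossing is
      # resolvable in the tick-level location series
      dwell[is_pipe] <- pmax(1.6 * cfg$tick_s,
                             stats::rexp(sum(is_pipe),
                                         1 / cfg$pipe_transit_mean_s))
      dwell[!is_pipe] <- rdwell(sum(!is_pipe), cfg$box_transit_mean_s)
      dwell[k] <- if (layout$kind[steps[k]] == "pipe")
        stats::rexp(1, 1 / final_dwell_mean)
      else rdwell(1, final_dwell_mean)
      entry <- t_now + c(0, cumsum(dwell[-k]))
      exit <- entry + dwell
      # pipe-end guard: stop before entering a pipe we could not leave
      bad <- which(is_pipe & exit >= T_end)
      if (length(bad)) {
        keep <- seq_len(min(bad) - 1L)
        if (length(keep)) push(entry[keep], steps[keep])
        last_box <- if (length(keep)) steps[max(keep)] else cur
        cur <<- last_box
        t_now <<- T_end
        return(FALSE)
      }
      push(entry, steps)
      cur <<- dest
      t_now <<- exit[k]
    } else {
      t_now <<- t_now + stats::rexp(1, 1 / final_dwell_mean)
    }
    TRUE
  }

  run_active <- function(until_t) {
    while (t_now < until_t && t_now < T_end) {
      dest <- choose_dest(t_now)
      dwell_mean <- if (dest == nest) cfg$nest_visit_mean_s[i]
                    else cfg$box_dwell_mean_s[i]
      if (!do_walk(dest, dwell_mean)) return(invisible())
    }
  }

  iv <- rest_iv[[i]]
  for (r in seq_len(nrow(iv))) {
    run_active(iv[r, 1])
    if (t_now >= T_end) break
    # travel to the nest and rest until the bout ends
    if (cur != nest) {
      if (!do_walk(nest, 1e-9)) break   # arrive, dwell handled below
    }
    t_now <- max(t_now, iv[r, 2])
  }
  if (t_now < T_end) run_active(T_end)

  tt <- unlist(acc_t[seq_len(na)], use.names = FALSE)
  cc <- unlist(acc_c[seq_len(na)], use.names = FALSE)
  finalize_trajectory(tt, cc, T_end)
}

finalize_trajectory <- function(tt, cc, T_end) {
  keep <- tt < T_end
  tt <- tt[keep]; cc <- cc[keep]
  # merge consecutive identical cells, enforce strictly increasing times
  changed <- c(TRUE, cc[-1] != cc[-length(cc)])
  tt <- tt[changed]; cc <- cc[changed]
  if (is.unsorted(tt, strictly = TRUE)) {
    o <- order(tt)
    tt <- tt[o]; cc <- cc[o]
    changed <- c(TRUE, cc[-1] != cc[-length(cc)])
    tt <- tt[changed]; cc <- cc[changed]
  }
  data.frame(t_s = tt, cell = as.integer(cc))
}

# Follower trajectory: delayed copy of the followee with shortest-path
# bridging into and out of shadow episodes.
build_follow_trajectory <- function(i, j, p, cfg, layout, rest_iv, prefs,
                                    traj_j) {
  T_end <- cfg$duration_s
  delay <- stats::runif(1, 0.3, 0.9 * cfg$follow_lag_s)
  if (p >= 1) {
    tt <- c(0, traj_j$t_s[-1] + delay)
    cc <- c(traj_j$cell[1], traj_j$cell[-1])
    return(finalize_trajectory(tt, cc, T_end))
  }
  followee_cell <- function(t) {
    traj_j$cell[max(1L, findInterval(t, traj_j$t_s))]
  }
  base <- build_base_trajectory(i, cfg, layout, rest_iv, prefs)
  iv <- rest_iv[[i]]
  act_start <- c(0, iv[, 2]); act_end <- c(iv[, 1], T_end)
  ok <- act_end > act_start
  act_start <- act_start[ok]; act_end <- act_end[ok]
  shadow <- stats::runif(length(act_start)) < p
  if (!any(shadow)) return(base)

  tt <- base$t_s[1]; cc <- base$cell[1]
  t_now <- 0; cur <- base$cell[1]
  copy_base <- function(from, to) {
    sel <- which(base$t_s > from & base$t_s < to)
    if (length(sel)) {
      tt <<- c(tt, base$t_s[sel]); cc <<- c(cc, base$cell[sel])
      cur <<- base$cell[max(sel)]
    }
    t_now <<- to
  }
  for (k in seq_along(act_start)) {
    if (!shadow[k]) next
    s <- act_start[k]; e <- act_end[k]
    copy_base(t_now, s)
    # bridge: walk to the followee's delayed position until locked on a box
    locked <- FALSE
    for (it in 1:20) {
      target <- followee_cell(t_now - delay)
      if (layout$kind[target] != "box") {       # wait for it to reach a box
        nxt <- traj_j$t_s[traj_j$t_s > t_now - delay]
        t_now <- if (length(nxt)) nxt[1] + delay else e
        if (t_now >= e) break
        next
      }
      if (cur == target) { locked <- TRUE; break }
      path <- layout$paths[[cur, target]]
      steps <- path[-1]
      dw <- pmax(1.6 * cfg$tick_s, stats::rexp(length(steps), 1 / cfg$pipe_transit_mean_s))
      entry <- t_now + c(0, cumsum(dw[-length(dw)]))
      entry <- entry[entry < min(e, T_end)]
      if (!length(entry)) break
      steps <- steps[seq_along(entry)]
      tt <- c(tt, entry); cc <- c(cc, steps)
      cur <- steps[length(steps)]
      t_now <- entry[length(entry)] + dw[length(entry)]
      if (t_now >= e) break
    }
    if (locked) {
      sel <- which(traj_j$t_s + delay > t_now & traj_j$t_s + delay < e)
      if (length(sel)) {
        tt <- c(tt, traj_j$t_s[sel] + delay)
        cc <- c(cc, traj_j$cell[sel])
        cur <- traj_j$cell[max(sel)]
        t_now <- traj_j$t_s[max(sel)] + delay
      }
      # run the copy on until the follower is parked in a box
      if (layout$kind[cur] != "box") {
        sel2 <- which(traj_j$t_s + delay >= t_now)
        for (m in sel2) {
          tt <- c(tt, traj_j$t_s[m] + delay)
          cc <- c(cc, traj_j$cell[m])
          cur <- traj_j$cell[m]
          t_now <- traj_j$t_s[m] + delay
          if (layout$kind[cur] == "box") break
        }
      }
      t_now <- max(t_now, e)
    } else {
      t_now <- max(t_now, e)
    }
    # after the episode, glue back onto the base trajectory at the next
    # point where the base is in the same cell; otherwise walk to the nest
    # and wait for the next rest bout
    if (cur != cfg$nest_cell) {
      path <- layout$paths[[cur, cfg$nest_cell]]
      steps <- path[-1]
      if (length(steps)) {
        dw <- pmax(1.6 * cfg$tick_s, stats::rexp(length(steps), 1 / cfg$pipe_transit_mean_s))
        entry <- t_now + c(0, cumsum(dw[-length(dw)]))
        keep <- entry < T_end
        tt <- c(tt, entry[keep]); cc <- c(cc, steps[keep])
        if (any(keep)) cur <- steps[max(which(keep))]
        t_now <- if (all(keep)) entry[length(entry)] + dw[length(dw)]
                 else T_end
      }
    }
    # replace the remainder of the base with nest residence until the next
    # shadow decision point; simplest faithful continuation: stay in nest
    # until the next rest bout ends, then the base trajectory is re-entered
    # at the following activity period
  }
  # after the last shadow episode the individual keeps its own schedule by
  # resting in the nest and making fresh trips; approximate by holding the
  # nest until the recording end (it is already there)
  finalize_trajectory(tt, cc, T_end)
}

#' Simulate a colony recording
#'
#' Runs the agent-based generator and emits both the complete ground truth
#' and the (possibly lossy) RFID detection log.
#'
#' @param config A [colony_config()].
#' @param layout A \code{grid_layout} (default: canonical burrow).
#' @return A list with elements \code{detections} (data frame
#'   \code{time_s}, \code{tag}, \code{reader}) and \code{truth}
#'   (class \code{simulation_truth}: per-individual trajectories, rest
#'   schedules, disturbance intervals, planted matrices).
#' @export
simulate_colony <- function(config, layout = build_layout()) {
  stopifnot(inherits(config, "colony_config"),
            inherits(layout, "grid_layout"))
  if (layout$kind[config$nest_cell] != "box")
    stop("configuration error: nest_cell is not a box in this layout",
         call. = FALSE)

  set.seed(individual_seed(config$seed, 0L))   # colony-level stream
  dist <- sim_disturbances(config)
  rest_iv <- sim_rest_schedule(config, dist)
  prefs <- sim_pair_preferences(config, layout)

  # follower ordering: followees before followers; reject cyclic designs
  n <- config$n_individuals
  order <- integer(0); remaining <- seq_len(n)
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(a) {
      deps <- which(config$follow[a, ] > 0)
      !any(deps %in% remaining & deps != a)
    }, logical(1))]
    if (!length(free))
      stop("configuration error: follow matrix contains a cycle",
           call. = FALSE)
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }

  trajectories <- vector("list", n)
  for (i in order) {
    set.seed(individual_seed(config$seed, i))
    fl <- config$follow[i, ]
    if (any(fl > 0)) {
      j <- which.max(fl)
      trajectories[[i]] <- build_follow_trajectory(
        i, j, fl[j], config, layout, rest_iv, prefs, trajectories[[j]])
    } else {
      trajectories[[i]] <- build_base_trajectory(i, config, layout,
                                                 rest_iv, prefs)
    }
  }
  names(trajectories) <- config$ids
  names(rest_iv) <- config$ids

  truth <- structure(list(trajectories = trajectories,
                          rest_intervals = rest_iv,
                          disturbance_intervals = dist,
                          config = config, layout = layout),
                     class = "simulation_truth")
  detections <- emit_detection_log(truth, layout, config$miss_rate,
                                   individual_seed(config$seed, n + 1L))
  list(detections = detections, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth>", length(x$trajectories), "individuals,",
      x$config$duration_s, "s,",
      sum(vapply(x$trajectories, nrow, integer(1))), "cell entries,",
      nrow(x$disturbance_intervals), "disturbance(s)\n")
  invisible(x)
}

#' Emit an RFID detection log from simulated ground truth
#'
#' A detection is produced whenever a trajectory crosses a reader-bearing
#' pipe end (every box-pipe transition); each crossing is dropped
#' independently with probability \code{miss_rate}.
#'
#' @param truth A \code{simulation_truth}.
#' @param layout A \code{grid_layout}.
#' @param miss_rate Per-crossing drop probability.
#' @param seed Integer seed for the drop draws.
#' @return Data frame \code{time_s}, \code{tag}, \code{reader}, sorted by
#'   (time, individual, reader).
#' @export
emit_detection_log <- function(truth, layout = truth$layout,
                               miss_rate = truth$config$miss_rate,
                               seed = truth$config$seed) {
  rd <- layout$readers
  key <- paste(rd$pipe, rd$end_box)
  logs <- lapply(names(truth$trajectories), function(id) {
    tr <- truth$trajectories[[id]]
    if (nrow(tr) < 2) return(NULL)
    a <- tr$cell[-nrow(tr)]; b <- tr$cell[-1]; t <- tr$t_s[-1]
    a_pipe <- layout$kind[a] == "pipe"
    pipe <- ifelse(a_pipe, a, b)
    box <- ifelse(a_pipe, b, a)
    reader <- rd$reader[match(paste(pipe, box), key)]
    if (anyNA(reader))
      stop("data-integrity error: non box-pipe transition in trajectory of ",
           id, call. = FALSE)
    data.frame(time_s = t, tag = id, reader = reader,
               stringsAsFactors = FALSE)
  })
  log <- do.call(rbind, logs)
  if (is.null(log))
    return(data.frame(time_s = numeric(0), tag = character(0),
                      reader = character(0), stringsAsFactors = FALSE))
  if (miss_rate > 0) {
    set.seed(seed)
    log <- log[stats::runif(nrow(log)) >= miss_rate, , drop = FALSE]
  }
  log <- log[order(log$time_s, log$tag, log$reader), , drop = FALSE]
  rownames(log) <- NULL
  log
}

#' Expand simulated ground truth to a tick-level location series
#'
#' @param truth A \code{simulation_truth}.
#' @param tick_s Tick length (default: the configured tick).
#' @return A [location_series()] without unknown values.
#' @export
truth_location_series <- function(truth, tick_s = truth$config$tick_s) {
  n_ticks <- round(truth$config$duration_s / tick_s)
  times <- (seq_len(n_ticks) - 1L) * tick_s
  cells <- vapply(truth$trajectories, function(tr) {
    tr$cell[pmax(1L, findInterval(times, tr$t_s))]
  }, integer(n_ticks))
  location_series(cells, tick_s)
}

#' Planted rest/active flags at regular sample times
#'
#' @param truth A \code{simulation_truth}.
#' @param interval_s Sampling interval in seconds.
#' @return Logical matrix (samples x individuals); \code{TRUE} = resting.
#' @export
truth_rest_series <- function(truth, interval_s = 10) {
  times <- seq(0, truth$config$duration_s - interval_s, by = interval_s)
  out <- vapply(truth$rest_intervals, function(iv) {
    if (nrow(iv) == 0) return(rep(FALSE, length(times)))
    k <- findInterval(times, iv[, 1])
    k > 0 & times < iv[pmax(k, 1L), 2]
  }, logical(length(times)))
  colnames(out) <- names(truth$rest_intervals)
  out
}

#' Uncategorized stay events straight from simulated trajectories
#'
#' @param truth A \code{simulation_truth}.
#' @return Data frame \code{individual}, \code{start_s}, \code{end_s},
#'   \code{cell} of maximal single-cell stays.
#' @export
truth_stay_events <- function(truth) {
  T_end <- truth$config$duration_s
  out <- lapply(names(truth$trajectories), function(id) {
    tr <- truth$trajectories[[id]]
    data.frame(individual = id,
               start_s = tr$t_s,
               end_s = c(tr$t_s[-1], T_end),
               cell = tr$cell, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank dyads by planted relationship strength
#'
#' Recovery oracle: orders dyads by the strengths planted in the
#' configuration matrices, strongest first, dropping zero entries.
#'
#' @param truth A \code{simulation_truth}.
#' @return A list with data frames \code{coupling}, \code{co_location}
#'   (unordered pairs: \code{a}, \code{b}, \code{strength}) and
#'   \code{follow} (directed: \code{follower}, \code{followee},
#'   \code{strength}).
#' @export
expected_index_ranking <- function(truth) {
  cfg <- truth$config
  sym_rank <- function(m) {
    idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
    d <- data.frame(a = cfg$ids[idx[, 1]], b = cfg$ids[idx[, 2]],
                    strength = m[idx], stringsAsFactors = FALSE)
    d[order(-d$strength, d$a, d$b), , drop = FALSE]
  }
  idx <- which(cfg$follow > 0, arr.ind = TRUE)
  fol <- data.frame(follower = cfg$ids[idx[, 1]],
                    followee = cfg$ids[idx[, 2]],
                    strength = cfg$follow[idx], stringsAsFactors = FALSE)
  fol <- fol[order(-fol$strength, fol$follower, fol$followee), , drop = FALSE]
  r <- list(coupling = sym_rank(cfg$coupling),
            co_location = sym_rank(cfg$co_location),
            follow = fol)
  lapply(r, function(d) { rownames(d) <- NULL; d })
}
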