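# Dyadic relationship quantification: activity-rhythm synchrony, spatial
# proximity and directional follow counts, compared against
# cyclic-permutation surrogate distributions to yield standardized indices,
# rank p-values and significance classes.

#' Binarize stay events into an activity vector
#'
#' Samples the Rest/Active state of one individual at regular intervals:
#' 1 = Rest, 0 = Active (any non-Rest category); samples inside excluded
#' (disturbance) intervals or unknown gaps are \code{NA}.
#'
#' @param events Classified stay events.
#' @param individual Individual id.
#' @param duration_s Recording length in seconds.
#' @param interval_s Sampling interval (default 10 s).
#' @param exclusions Two-column matrix of excluded intervals (start, end).
#' @return Integer vector with attribute \code{interval_s}.
#' @export
binarize_activity <- function(events, individual, duration_s,
                              interval_s = 10, exclusions = NULL) {
  n <- floor(duration_s / interval_s)
  state <- integer(n)                      # default Active
  ev <- events[events$individual == individual, , drop = FALSE]
  paint <- function(state, rows, value) {
    if (length(rows) == 0) return(state)
    k0 <- pmax(tick_index(ev$start_s[rows], interval_s), 0L)
    k1 <- pmin(tick_index(ev$end_s[rows], interval_s) - 1L, n - 1L)
    keep <- k1 >= k0
    if (any(keep)) {
      len <- k1[keep] - k0[keep] + 1L
      state[sequence(len, from = k0[keep] + 1L)] <- value
    }
    state
  }
  state <- paint(state, which(!is.na(ev$category) & ev$category == "Rest"),
                 1L)
  state <- paint(state, which(is.na(ev$category)), NA_integer_)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    k0 <- pmax(tick_index(exclusions[, 1], interval_s), 0L)
    k1 <- pmin(tick_index(exclusions[, 2], interval_s) - 1L, n - 1L)
    keep <- k1 >= k0
    if (any(keep)) {
      len <- k1[keep] - k0[keep] + 1L
      state[sequence(len, from = k0[keep] + 1L)] <- NA_integer_
    }
  }
  structure(state, interval_s = interval_s)
}

#' Count state-synchrony samples of a dyad
#'
#' The number of sample points at which both individuals are observed and in
#' the same (Rest/Active) state.
#'
#' @param a,b Equal-length activity vectors from [binarize_activity()].
#' @return Integer count.
#' @export
count_synchrony <- function(a, b) {
  if (length(a) != length(b))
    stop("input error: activity vectors differ in length", call. = FALSE)
  sum(!is.na(a) & !is.na(b) & a == b)
}

#' Joint same-cell samples of a dyad outside the nest
#'
#' Restricts the two location series to samples where both individuals are
#' active and outside the nest, and counts samples in the same grid cell.
#' Surrogate shifts are drawn on vectors rebuilt over this restricted index
#' set only.
#'
#' @param loc_a,loc_b Integer cell vectors sampled at \code{interval_s}
#'   (NA = unknown).
#' @param act_a,act_b Matching activity vectors (1 = Rest, 0 = Active).
#' @param nest Nest cell id per sample (vector or scalar).
#' @return List with \code{count}, the restricted index set \code{idx} and
#'   the restricted cell vectors \code{cells_a}, \code{cells_b};
#'   \code{undefined} flags an empty restricted set.
#' @export
count_proximity <- function(loc_a, loc_b, act_a, act_b, nest) {
  stopifnot(length(loc_a) == length(loc_b))
  nest <- rep_len(nest, length(loc_a))
  idx <- which(!is.na(act_a) & !is.na(act_b) & act_a == 0L & act_b == 0L &
                 !is.na(loc_a) & !is.na(loc_b) &
                 loc_a != nest & loc_b != nest)
  if (length(idx) == 0)
    return(list(count = 0L, idx = idx, cells_a = integer(0),
                cells_b = integer(0), undefined = TRUE))
  ca <- loc_a[idx]; cb <- loc_b[idx]
  list(count = sum(ca == cb), idx = idx, cells_a = ca, cells_b = cb,
       undefined = FALSE)
}

#' Extract movement events from a location series
#'
#' One event per change of cell between consecutive defined ticks;
#' transitions into or out of unknown stretches produce no event.
#'
#' @param cells Integer cell vector at tick resolution (one individual).
#' @param tick_s Tick length in seconds.
#' @param layout A \code{grid_layout} used to verify grid adjacency.
#' @return Data frame \code{time_s}, \code{from}, \code{to}.
#' @export
extract_movements <- function(cells, tick_s, layout = build_layout()) {
  n <- length(cells)
  if (n < 2) return(data.frame(time_s = numeric(0), from = integer(0),
                               to = integer(0)))
  prev <- cells[-n]; nxt <- cells[-1]
  ch <- which(!is.na(prev) & !is.na(nxt) & prev != nxt)
  from <- prev[ch]; to <- nxt[ch]
  bad <- which(!mapply(function(f, t) t %in% layout$adjacency[[f]],
                       from, to))
  if (length(bad))
    stop("data-integrity error: non-adjacent transition ", from[bad[1]],
         " -> ", to[bad[1]], call. = FALSE)
  data.frame(time_s = ch * tick_s, from = from, to = to)
}

#' Movement events straight from a simulated trajectory
#'
#' Equivalent to [extract_movements()] on the expanded tick series of a
#' noise-free trajectory, but read directly off the cell-entry list.
#'
#' @param traj One element of \code{truth$trajectories} (data frame
#'   \code{t_s}, \code{cell}).
#' @return Data frame \code{time_s}, \code{from}, \code{to}.
#' @export
movements_from_trajectory <- function(traj) {
  n <- nrow(traj)
  if (n < 2) return(data.frame(time_s = numeric(0), from = integer(0),
                               to = integer(0)))
  data.frame(time_s = traj$t_s[-1], from = traj$cell[-n],
             to = traj$cell[-1])
}

#' Count directed follow events
#'
#' For each movement of the followee (a path between adjacent cells), counts
#' 1 if the follower performs a movement along the identical path within
#' \code{window_s} afterwards (window closed on the right); each followee
#' movement contributes at most one count.
#'
#' @param followee,follower Movement event data frames from
#'   [extract_movements()], time-sorted.
#' @param window_s Follow window in seconds (default 3).
#' @return Integer count.
#' @export
count_follows <- function(followee, follower, window_s = 3) {
  pairs <- follow_candidate_pairs(followee, follower, window_s)
  count_follows_from_pairs(pairs, shift = 0L)
}

# All (followee event, follower event) pairs with the follower event inside
# the window; path labels are kept so surrogate shifts can be re-scored
# without recomputing windows.
follow_candidate_pairs <- function(followee, follower, window_s) {
  pe <- followee$from * 32L + followee$to
  pf <- follower$from * 32L + follower$to
  tf <- follower$time_s
  lo <- findInterval(followee$time_s, tf) + 1L             # first > t
  hi <- findInterval(followee$time_s + window_s + 1e-9, tf) # last <= t + w
  len <- pmax(hi - lo + 1L, 0L)
  i <- rep(seq_along(pe), len)
  j <- sequence(len[len > 0], from = lo[len > 0])
  list(i = i, j = j, path_e = pe, path_f = pf,
       n_e = length(pe), n_f = length(pf))
}

count_follows_from_pairs <- function(pairs, shift = 0L) {
  if (length(pairs$i) == 0 || pairs$n_f == 0) return(0L)
  jj <- if (shift == 0L) pairs$j else
    ((pairs$j - 1L + shift) %% pairs$n_f) + 1L
  hit <- pairs$path_f[jj] == pairs$path_e[pairs$i]
  if (!any(hit)) return(0L)
  sum(tabulate(pairs$i[hit], nbins = pairs$n_e) > 0L)
}

circular_shift <- function(x, k) {
  n <- length(x)
  if (n == 0 || k %% n == 0) return(x)
  k <- k %% n
  c(x[(n - k + 1L):n], x[seq_len(n - k)])
}

classify_dyad <- function(n_actual, sims) {
  n_s <- length(sims)
  sd_s <- stats::sd(sims)
  mean_s <- mean(sims)
  r_high <- (1 + sum(sims >= n_actual)) / (1 + n_s)
  r_low <- (1 + sum(sims <= n_actual)) / (1 + n_s)
  flagged <- !is.finite(sd_s) || sd_s == 0
  list(n_actual = n_actual,
       surrogate_mean = mean_s,
       surrogate_sd = sd_s,
       index = if (flagged) NA_real_ else (n_actual - mean_s) / sd_s,
       p_value = min(r_high, r_low),
       class = if (flagged) "ns" else if (r_high <= 0.025) "significant_high"
               else if (r_low <= 0.025) "significant_low" else "ns",
       flagged = flagged)
}

#' Standardized dyadic index against a cyclic-shift surrogate distribution
#'
#' Builds \code{n_surrogates} circular shifts of \code{vec_b} (offsets drawn
#' uniformly with replacement from 1..L-1), applies \code{count_fn} to each,
#' and standardizes the actual count within the surrogate distribution.  The
#' rank p-value is the add-one proportion of values at least as extreme in
#' the actual value's tail; dyads in the top (bottom) 2.5 percent are
#' classified \code{significant_high} (\code{significant_low}).
#'
#' @param count_fn Function of two vectors returning a count.
#' @param vec_a,vec_b The dyad's (restricted) state or cell vectors.
#' @param n_surrogates Number of surrogates (>= 19).
#' @param seed Integer seed for the offset draws.
#' @return List: \code{n_actual}, \code{surrogate_mean},
#'   \code{surrogate_sd}, \code{index}, \code{p_value}, \code{class},
#'   \code{flagged} (TRUE when the surrogate sd is 0 and the index is
#'   undefined).
#' @export
cyclic_surrogate_index <- function(count_fn, vec_a, vec_b,
                                   n_surrogates = 999, seed = 1) {
  stopifnot(n_surrogates >= 19)
  L <- length(vec_b)
  if (L < 2) {
    res <- classify_dyad(count_fn(vec_a, vec_b), rep(0, n_surrogates))
    res$flagged <- TRUE
    res$index <- NA_real_
    res$class <- "ns"
    return(res)
  }
  set.seed(seed)
  offsets <- sample.int(L - 1L, n_surrogates, replace = TRUE)
  sims <- vapply(offsets,
                 function(k) as.numeric(count_fn(vec_a,
                                                 circular_shift(vec_b, k))),
                 numeric(1))
  classify_dyad(as.numeric(count_fn(vec_a, vec_b)), sims)
}

# compact a dyad's vectors over the jointly observed index mask
compact_pair <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

#' Synchrony index for one dyad
#'
#' @param a,b Activity vectors from [binarize_activity()].
#' @param n_surrogates Number of cyclic surrogates (9999 in a full-scale
#'   analysis).
#' @param seed Integer seed.
#' @return See [cyclic_surrogate_index()].
#' @export
dyad_synchrony <- function(a, b, n_surrogates = 9999, seed = 1) {
  cp <- compact_pair(a, b)
  cyclic_surrogate_index(function(x, y) sum(x == y), cp$a, cp$b,
                         n_surrogates, seed)
}

#' Proximity index for one dyad
#'
#' @param prox Output of [count_proximity()].
#' @inheritParams dyad_synchrony
#' @return See [cyclic_surrogate_index()]; undefined (flagged) when the
#'   restricted index set is empty.
#' @export
dyad_proximity <- function(prox, n_surrogates = 9999, seed = 1) {
  if (prox$undefined) {
    return(list(n_actual = 0L, surrogate_mean = NA_real_,
                surrogate_sd = NA_real_, index = NA_real_,
                p_value = NA_real_, class = "ns", flagged = TRUE))
  }
  cyclic_surrogate_index(function(x, y) sum(x == y), prox$cells_a,
                         prox$cells_b, n_surrogates, seed)
}

#' Follow index for one directed dyad
#'
#' Surrogates preserve the follower's movement timing vector and circularly
#' shift its path (trajectory) vector.
#'
#' @param followee,follower Movement event data frames.
#' @param window_s Follow window (default 3 s).
#' @param n_surrogates Number of surrogates (999 in a full-scale analysis).
#' @param seed Integer seed.
#' @return See [cyclic_surrogate_index()].
#' @export
dyad_follow <- function(followee, follower, window_s = 3,
                        n_surrogates = 999, seed = 1) {
  stopifnot(n_surrogates >= 19)
  pairs <- follow_candidate_pairs(followee, follower, window_s)
  L <- pairs$n_f
  if (L < 2) {
    return(list(n_actual = count_follows_from_pairs(pairs),
                surrogate_mean = NA_real_, surrogate_sd = NA_real_,
                index = NA_real_, p_value = NA_real_, class = "ns",
                flagged = TRUE))
  }
  set.seed(seed)
  offsets <- sample.int(L - 1L, n_surrogates, replace = TRUE)
  sims <- vapply(offsets,
                 function(k) as.numeric(count_follows_from_pairs(pairs, k)),
                 numeric(1))
  classify_dyad(as.numeric(count_follows_from_pairs(pairs)), sims)
}

#' Yeo-Johnson transform and z-standardize follow indices
#'
#' @param x Numeric vector of follow indices over all directed dyads
#'   (missing or undefined entries propagate).
#' @return Transformed vector with attribute \code{lambda}.
#' @export
transform_follow_indices <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2)
    stop("parameter error: need >= 2 finite indices", call. = FALSE)
  if (stats::sd(x[ok]) == 0)
    stop("parameter error: all indices identical; z-transform undefined",
         call. = FALSE)
  lam <- power_lambda(x[ok], family = "yjPower")
  y <- x
  y[ok] <- car::yjPower(x[ok], lam)
  y[ok] <- (y[ok] - mean(y[ok])) / stats::sd(y[ok])
  structure(y, lambda = lam)
}

#' Dyadic index table for a colony
#'
#' Runs the chosen relationship quantification over all dyads (unordered for
#' synchrony/proximity, ordered follower-followee for follow) and returns a
#' long-form result table.
#'
#' @param data For \code{type = "synchrony"}: a samples x individuals matrix
#'   of activity states (from [binarize_activity()]).  For
#'   \code{"proximity"}: a list with \code{loc} (samples x individuals cell
#'   matrix), \code{act} (activity matrix) and \code{nest} (nest cell per
#'   sample).  For \code{"follow"}: a named list of movement event data
#'   frames.
#' @param type One of \code{"synchrony"}, \code{"proximity"},
#'   \code{"follow"}.
#' @param n_surrogates Number of surrogates per dyad.
#' @param seed Integer base seed (each dyad uses a derived seed).
#' @param window_s Follow window (follow only).
#' @return Data frame \code{a}, \code{b}, \code{n_actual},
#'   \code{surrogate_mean}, \code{surrogate_sd}, \code{index},
#'   \code{p_value}, \code{class}, \code{flagged}; for follow, \code{a} is
#'   the follower and \code{b} the followee.
#' @export
dyad_index_table <- function(data, type = c("synchrony", "proximity",
                                            "follow"),
                             n_surrogates = 999, seed = 1, window_s = 3) {
  type <- match.arg(type)
  ids <- if (type == "follow") names(data) else colnames(
    if (type == "proximity") data$act else data)
  n <- length(ids)
  pairs <- if (type == "follow") {
    subset(expand.grid(ai = seq_len(n), bi = seq_len(n)), ai != bi)
  } else {
    w <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    data.frame(ai = w[, 1], bi = w[, 2])
  }
  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    ai <- pairs$ai[r]; bi <- pairs$bi[r]
    dseed <- individual_seed(seed, ai * n + bi)
    res <- switch(type,
      synchrony = dyad_synchrony(data[, ai], data[, bi], n_surrogates,
                                 dseed),
      proximity = dyad_proximity(
        count_proximity(data$loc[, ai], data$loc[, bi],
                        data$act[, ai], data$act[, bi], data$nest),
        n_surrogates, dseed),
      follow = dyad_follow(data[[bi]], data[[ai]], window_s, n_surrogates,
                           dseed))
    rows[[r]] <- data.frame(a = ids[ai], b = ids[bi],
                            n_actual = res$n_actual,
                            surrogate_mean = res$surrogate_mean,
                            surrogate_sd = res$surrogate_sd,
                            index = res$index, p_value = res$p_value,
                            class = res$class, flagged = res$flagged,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "type") <- type
  attr(out, "directed") <- type == "follow"
  out
}
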