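# Stay-event construction: chamber annotation, segmentation, classification
# and the cleaning rules (disturbance phases, nest-adjacent rests, sub-nests,
# long-gap fill).

#' Chamber annotation
#'
#' Holds the time-varying nest location plus the (manually annotated) toilet
#' and garbage chambers.
#'
#' @param nest Data frame \code{time_s}, \code{cell}: nest box per sample
#'   time (step function, left-closed).
#' @param toilet,garbage Either a single box cell id or a data frame
#'   \code{time_s}, \code{cell} for time-varying annotations.
#' @return An object of class \code{chamber_annotation}.
#' @export
chamber_annotation <- function(nest, toilet, garbage) {
  as_step <- function(x) {
    if (is.data.frame(x)) x else data.frame(time_s = 0, cell = x)
  }
  structure(list(nest = as_step(nest), toilet = as_step(toilet),
                 garbage = as_step(garbage)),
            class = "chamber_annotation")
}

step_lookup <- function(step, t) {
  step$cell[pmax(1L, findInterval(t, step$time_s))]
}

#' Nest location of an annotation at given times
#' @param annotation A \code{chamber_annotation}.
#' @param t Numeric vector of times in seconds.
#' @return Integer cell ids.
#' @export
nest_at <- function(annotation, t) step_lookup(annotation$nest, t)

#' Annotate the nest chamber by windowed majority occupancy
#'
#' At each sample time, the nest is the box with the highest mean occupant
#' count over a centered window (partial windows at the recording edges use
#' the available part).  Ties are broken by the lowest (row, col).  Samples
#' whose window contains no located individual carry the previous nest
#' forward.
#'
#' @param series A [location_series()] for the whole colony.
#' @param sample_s Sampling interval in seconds (default 10).
#' @param window_s Window width in seconds (default 21600, i.e. 6 hours).
#' @param layout A \code{grid_layout}.
#' @return Data frame \code{time_s}, \code{cell} (the nest part of a
#'   [chamber_annotation()]).
#' @export
annotate_nest <- function(series, sample_s = 10, window_s = 21600,
                          layout = build_layout()) {
  tick_s <- attr(series, "tick_s")
  step <- round(sample_s / tick_s)
  stopifnot(step >= 1)
  rows <- seq(1L, nrow(series), by = step)
  times <- (rows - 1L) * tick_s
  boxes <- layout$boxes
  # occupant count per sample per box
  occ <- matrix(0L, length(rows), length(boxes))
  for (j in seq_len(ncol(series))) {
    cl <- series[rows, j]
    m <- match(cl, boxes)
    ok <- !is.na(m)
    if (any(ok))
      occ[cbind(which(ok), m[ok])] <- occ[cbind(which(ok), m[ok])] + 1L
  }
  half <- round(window_s / 2 / sample_s)
  n <- length(rows)
  cs <- rbind(0, apply(occ, 2, cumsum))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  win_mean <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1L)
  any_occ <- rowSums(win_mean) > 0
  nest <- boxes[max.col(win_mean, ties.method = "first")]
  # carry forward through all-unknown windows
  if (!all(any_occ)) {
    nest[!any_occ] <- NA_integer_
    if (is.na(nest[1])) nest[1] <- nest[which(!is.na(nest))[1]]
    for (k in which(is.na(nest))) nest[k] <- nest[k - 1L]
  }
  data.frame(time_s = times, cell = nest)
}

#' Segment a location series into maximal single-cell stays
#'
#' Unknown runs are emitted as gap records (\code{cell = NA}); stays on
#' either side of a gap are not merged.
#'
#' @param series A [location_series()].
#' @return Data frame \code{individual}, \code{start_s}, \code{end_s},
#'   \code{cell} (NA for gaps).
#' @export
segment_stays <- function(series) {
  tick_s <- attr(series, "tick_s")
  out <- lapply(colnames(series), function(id) {
    x <- series[, id]
    code <- ifelse(is.na(x), 0L, x)
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(individual = id,
               start_s = starts * tick_s,
               end_s = ends * tick_s,
               cell = ifelse(r$values == 0L, NA_integer_, r$values),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Locate modes and antimodes of a stay-duration distribution
#'
#' Kernel density estimation on log-durations (Silverman's bandwidth);
#' local maxima and minima are back-transformed to seconds.
#'
#' @param durations Numeric vector of stay durations in seconds (>= 2
#'   values required).
#' @return List with numeric vectors \code{modes} and \code{antimodes}
#'   (antimodes lie between modes; empty for unimodal input).
#' @export
find_duration_modes <- function(durations) {
  durations <- durations[is.finite(durations) & durations > 0]
  if (length(durations) < 2)
    stop("estimation error: need at least 2 positive durations",
         call. = FALSE)
  d <- stats::density(log(durations))
  y <- d$y
  interior <- 2:(length(y) - 1)
  is_max <- y[interior] > y[interior - 1] & y[interior] >= y[interior + 1]
  is_min <- y[interior] < y[interior - 1] & y[interior] <= y[interior + 1]
  modes <- exp(d$x[interior[is_max]])
  anti <- exp(d$x[interior[is_min]])
  if (length(modes) >= 2) {
    anti <- anti[anti > min(modes) & anti < max(modes)]
  } else {
    anti <- numeric(0)
  }
  list(modes = modes, antimodes = anti)
}

#' Classify stay events into the five behavioral categories
#'
#' Nest-cell stays longer than \code{rest_threshold_s} become \code{Rest},
#' shorter ones \code{Nest} (the threshold itself is \code{Nest}: "more
#' than" is strict).  Elsewhere the chamber function at the event midpoint
#' decides \code{Toilet} or \code{Garbage}; pipes and unannotated boxes are
#' \code{Other}.  Gap records keep \code{NA}.
#'
#' @param events Output of [segment_stays()] (or [truth_stay_events()]).
#' @param annotation A [chamber_annotation()].
#' @param rest_threshold_s Rest duration threshold in seconds (default 600).
#' @return The events with a \code{category} column.
#' @export
classify_stays <- function(events, annotation, rest_threshold_s = 600) {
  mid <- (events$start_s + events$end_s) / 2
  dur <- events$end_s - events$start_s
  nest <- nest_at(annotation, mid)
  toilet <- step_lookup(annotation$toilet, mid)
  garbage <- step_lookup(annotation$garbage, mid)
  cat <- rep(NA_character_, nrow(events))
  known <- !is.na(events$cell)
  cat[known] <- "Other"
  cat[known & events$cell == toilet] <- "Toilet"
  cat[known & events$cell == garbage] <- "Garbage"
  in_nest <- known & events$cell == nest
  cat[in_nest] <- ifelse(dur[in_nest] > rest_threshold_s, "Rest", "Nest")
  events$category <- cat
  events
}

#' Colony rest-fraction time series
#'
#' Fraction of colony members in the \code{Rest} state at regular sample
#' times.
#'
#' @param events Classified stay events.
#' @param n_individuals Colony size (the denominator).
#' @param duration_s Recording length in seconds.
#' @param sample_s Sampling interval (default 10 s).
#' @return Data frame \code{time_s}, \code{fraction}.
#' @export
rest_fraction_series <- function(events, n_individuals, duration_s,
                                 sample_s = 10) {
  n <- floor(duration_s / sample_s)
  acc <- numeric(n + 1L)
  r <- events[!is.na(events$category) & events$category == "Rest", ,
              drop = FALSE]
  if (nrow(r) > 0) {
    k0 <- pmax(tick_index(r$start_s, sample_s), 0L)
    k1 <- pmin(tick_index(r$end_s, sample_s) - 1L, n - 1L)
    ok <- k1 >= k0
    for (i in which(ok)) {
      acc[k0[i] + 1L] <- acc[k0[i] + 1L] + 1
      acc[k1[i] + 2L] <- acc[k1[i] + 2L] - 1
    }
  }
  data.frame(time_s = (seq_len(n) - 1L) * sample_s,
             fraction = cumsum(acc)[seq_len(n)] / n_individuals)
}

#' Detect colony-wide disturbance phases
#'
#' A disturbance phase is a maximal interval in which the resting fraction
#' stays below \code{low} and dips below \code{dip} at least once.  These
#' intervals are excluded from downstream analyses.
#'
#' @param rest_frac Data frame \code{time_s}, \code{fraction} from
#'   [rest_fraction_series()] (regularly sampled).
#' @param low Upper bound of the phase (default 0.25).
#' @param dip Required minimum dip (default 0.10).
#' @return Two-column matrix of \code{start}/\code{end} times in seconds.
#' @export
detect_disturbances <- function(rest_frac, low = 0.25, dip = 0.10) {
  stopifnot(nrow(rest_frac) > 0)
  sample_s <- if (nrow(rest_frac) > 1)
    rest_frac$time_s[2] - rest_frac$time_s[1] else 1
  below <- rest_frac$fraction < low
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- NULL
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    if (any(rest_frac$fraction[idx] < dip)) {
      out <- rbind(out, c(rest_frac$time_s[starts[k]],
                          rest_frac$time_s[ends[k]] + sample_s))
    }
  }
  if (is.null(out)) out <- matrix(numeric(0), 0, 2)
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Apply the stay-event cleaning rules
#'
#' Three corrections, in order: (a) stays longer than
#' \code{rest_threshold_s} in pipes adjacent to the current nest are
#' reclassified \code{Rest}; (b) non-nest boxes where at least
#' \code{subnest_min} individuals co-reside continuously for more than
#' \code{rest_threshold_s} become sub-nests, and stays longer than the
#' threshold there are reclassified \code{Rest}; (c) unknown gaps longer
#' than \code{na_fill_s} are relocated to the nest and classified
#' \code{Rest}.  The function is idempotent.
#'
#' @param events Classified stay events.
#' @param annotation A [chamber_annotation()].
#' @param duration_s Recording length in seconds.
#' @param layout A \code{grid_layout}.
#' @param rest_threshold_s Rest duration threshold (default 600 s).
#' @param subnest_min Minimum co-residing individuals for a sub-nest
#'   (default 5).
#' @param na_fill_s Unknown-gap fill threshold (default 1800 s, i.e. 30
#'   minutes).
#' @param sample_s Sampling interval for the sub-nest occupancy scan
#'   (default 10 s).
#' @return Corrected stay events.
#' @export
apply_corrections <- function(events, annotation, duration_s,
                              layout = build_layout(),
                              rest_threshold_s = 600, subnest_min = 5,
                              na_fill_s = 1800, sample_s = 10) {
  dur <- events$end_s - events$start_s
  mid <- (events$start_s + events$end_s) / 2
  nest_mid <- nest_at(annotation, mid)

  # (a) long stays in nest-adjacent pipes
  known <- !is.na(events$cell)
  adj_pipe <- known & dur > rest_threshold_s &
    layout$kind[ifelse(known, events$cell, 1L)] == "pipe" &
    mapply(function(cl, nst) !is.na(cl) && cl %in% layout$adjacency[[nst]],
           events$cell, nest_mid)
  events$category[adj_pipe] <- "Rest"

  # (b) sub-nests: occupancy runs of >= subnest_min individuals > threshold
  n_samples <- floor(duration_s / sample_s)
  box_ids <- layout$boxes
  for (b in box_ids) {
    ev_b <- events[known & events$cell == b, , drop = FALSE]
    if (nrow(ev_b) == 0) next
    acc <- numeric(n_samples + 1L)
    k0 <- pmax(tick_index(ev_b$start_s, sample_s), 0L)
    k1 <- pmin(tick_index(ev_b$end_s, sample_s) - 1L, n_samples - 1L)
    for (i in which(k1 >= k0)) {
      acc[k0[i] + 1L] <- acc[k0[i] + 1L] + 1
      acc[k1[i] + 2L] <- acc[k1[i] + 2L] - 1
    }
    occ <- cumsum(acc)[seq_len(n_samples)]
    t_samp <- (seq_len(n_samples) - 1L) * sample_s
    crowded <- occ >= subnest_min & step_lookup(annotation$nest, t_samp) != b
    r <- rle(crowded)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths * sample_s > rest_threshold_s)) {
      s0 <- t_samp[starts[k]]; s1 <- t_samp[ends[k]] + sample_s
      hit <- known & events$cell == b & dur > rest_threshold_s &
        mid >= s0 & mid < s1
      events$category[hit] <- "Rest"
    }
  }

  # (c) long unknown gaps: relocate to the nest as Rest
  gap <- is.na(events$cell) & dur > na_fill_s
  if (any(gap)) {
    events$cell[gap] <- nest_mid[gap]
    events$category[gap] <- "Rest"
  }
  events
}
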