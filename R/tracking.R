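# Location series container -------------------------------------------------

#' Construct a location series collection
#'
#' A location series holds, for each individual, the occupied grid cell at
#' fixed ticks; \code{NA} marks ticks where the location is unknown.
#'
#' @param cells Integer matrix (ticks x individuals) of cell ids with
#'   \code{NA} for unknown; column names are individual ids.
#' @param tick_s Tick length in seconds.
#' @return An object of class \code{location_series}.
#' @export
location_series <- function(cells, tick_s) {
  stopifnot(is.matrix(cells), !is.null(colnames(cells)), tick_s > 0)
  structure(cells, tick_s = tick_s, class = c("location_series", "matrix"))
}

#' @export
print.location_series <- function(x, ...) {
  cat("<location_series>", ncol(x), "individuals x", nrow(x),
      "ticks @", attr(x, "tick_s"), "s;",
      sprintf("%.2f%% unknown\n", 100 * mean(is.na(x))))
  invisible(x)
}

tick_index <- function(t, tick_s) {
  # 0-based index of the first tick whose start time is >= t
  as.integer(ceiling(t / tick_s - 1e-9))
}

# RFID reconstruction --------------------------------------------------------

#' Reconstruct grid locations from an RFID detection log
#'
#' Converts raw detection records into per-individual tick-level grid
#' locations.  An individual detected by a reader is placed in that reader's
#' pipe cell.  The interval between two successive detections is assigned:
#' the shared pipe when both readers flank one pipe; the shared box when the
#' readers' pipes meet at one box; the reader's end box after a same-reader
#' re-detection gap longer than \code{redetect_s}; the pipe itself for
#' same-reader gaps within \code{redetect_s}; and unknown (\code{NA}) when
#' the readers are non-adjacent.  Ticks before the first detection are
#' unknown; ticks after the final detection follow the same-reader rule
#' against the recording end.
#'
#' @param log Data frame with columns \code{time_s}, \code{tag},
#'   \code{reader}, sorted by time.
#' @param layout A \code{grid_layout}.
#' @param tick_s Tick length in seconds (default 0.1).
#' @param redetect_s Same-reader re-detection threshold in seconds
#'   (default 0.3; gaps strictly greater are assigned to the end box).
#' @param duration_s Recording length in seconds; defaults to the last
#'   detection time rounded up to a whole tick.
#' @param tags Individuals to include (default: all tags present in the log).
#' @return A [location_series()] with one column per individual.
#' @export
reconstruct_locations <- function(log, layout, tick_s = 0.1,
                                  redetect_s = 0.3, duration_s = NULL,
                                  tags = NULL) {
  stopifnot(all(c("time_s", "tag", "reader") %in% names(log)))
  if (is.unsorted(log$time_s))
    stop("input error: detection log must be sorted by time_s", call. = FALSE)
  unknown <- setdiff(unique(log$reader), layout$readers$reader)
  if (length(unknown) > 0)
    stop("input error: unknown reader id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(duration_s)) {
    duration_s <- if (nrow(log) > 0)
      ceiling(max(log$time_s) / tick_s) * tick_s else tick_s
  }
  n_ticks <- round(duration_s / tick_s)
  if (abs(n_ticks * tick_s - duration_s) > 1e-6)
    stop("configuration error: duration_s must be an integer multiple of ",
         "tick_s", call. = FALSE)
  if (is.null(tags)) tags <- sort(unique(log$tag))

  rd <- layout$readers
  out <- matrix(NA_integer_, nrow = n_ticks, ncol = length(tags),
                dimnames = list(NULL, tags))
  for (tag in tags) {
    recs <- log[log$tag == tag, , drop = FALSE]
    # simultaneous detections of one tag at two readers: keep the earlier
    # record in file order, drop duplicates at identical timestamps
    dup <- duplicated(recs$time_s)
    if (any(dup)) {
      warning("dropping ", sum(dup), " duplicate-timestamp detection(s) for ",
              tag, call. = FALSE)
      recs <- recs[!dup, , drop = FALSE]
    }
    n <- nrow(recs)
    if (n == 0L) next
    t <- recs$time_s
    ri <- match(recs$reader, rd$reader)
    ival <- integer(0)
    if (n > 1L) {
      same <- ri[-n] == ri[-1L]
      gap <- diff(t)
      ival <- integer(n - 1L)
      ival[same] <- ifelse(gap[same] > redetect_s + 1e-9,
                           rd$end_box[ri[-n][same]], rd$pipe[ri[-n][same]])
      for (i in which(!same))
        ival[i] <- between_cell(layout, recs$reader[i], recs$reader[i + 1L])
    }
    # trailing interval: same-reader rule against the recording end
    tail_cell <- if (duration_s - t[n] > redetect_s + 1e-9)
      rd$end_box[ri[n]] else rd$pipe[ri[n]]
    a <- t
    b <- c(t[-1L], duration_s)
    val <- c(ival, tail_cell)
    k0 <- pmax(tick_index(a, tick_s), 0L)
    k1 <- pmin(tick_index(b, tick_s) - 1L, n_ticks - 1L)
    keep <- k1 >= k0
    if (any(keep)) {
      len <- k1[keep] - k0[keep] + 1L
      idx <- sequence(len, from = k0[keep] + 1L)
      out[cbind(idx, match(tag, tags))] <- rep(val[keep], len)
    }
  }
  location_series(out, tick_s)
}

#' Tracking error rate
#'
#' The pooled fraction of ticks at which the location is unknown, across all
#' individuals of a location series.
#'
#' @param series A [location_series()].
#' @return A fraction in \code{[0, 1]}.
#' @export
compute_error_rate <- function(series) {
  stopifnot(inherits(series, "location_series"), length(series) > 0)
  mean(is.na(series))
}
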