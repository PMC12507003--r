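# Independent brute-force oracles used to cross-check the implementation.

# Naive interval painter: per-tick loop over the detection list of one tag,
# applying the tracking rules directly.
bf_reconstruct_one <- function(recs, layout, tick_s, redetect_s,
                               duration_s) {
  n_ticks <- round(duration_s / tick_s)
  cells <- rep(NA_integer_, n_ticks)
  if (nrow(recs) == 0) return(cells)
  recs <- recs[!duplicated(recs$time_s), , drop = FALSE]
  rd <- layout$readers
  interval_cell <- function(r1, r2, gap) {
    i1 <- match(r1, rd$reader); i2 <- match(r2, rd$reader)
    if (r1 == r2) {
      if (gap > redetect_s) rd$end_box[i1] else rd$pipe[i1]
    } else if (rd$pipe[i1] == rd$pipe[i2]) {
      rd$pipe[i1]
    } else {
      b1 <- layout$adjacency[[rd$pipe[i1]]]
      b2 <- layout$adjacency[[rd$pipe[i2]]]
      shared <- intersect(b1[layout$kind[b1] == "box"],
                          b2[layout$kind[b2] == "box"])
      if (length(shared) == 1) shared else NA_integer_
    }
  }
  bounds <- c(recs$time_s, duration_s)
  vals <- integer(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    gap <- bounds[i + 1] - bounds[i]
    r2 <- if (i < nrow(recs)) recs$reader[i + 1] else recs$reader[i]
    vals[i] <- interval_cell(recs$reader[i], r2, gap)
  }
  for (k in seq_len(n_ticks)) {
    t <- (k - 1) * tick_s
    i <- findInterval(t + 1e-12, bounds)
    if (i >= 1 && i <= nrow(recs)) cells[k] <- vals[i]
  }
  cells
}

bf_count_synchrony <- function(a, b) {
  cnt <- 0L
  for (k in seq_along(a)) {
    if (!is.na(a[k]) && !is.na(b[k]) && a[k] == b[k]) cnt <- cnt + 1L
  }
  cnt
}

bf_count_follows <- function(followee, follower, window_s) {
  cnt <- 0L
  for (i in seq_len(nrow(followee))) {
    hit <- any(follower$time_s > followee$time_s[i] &
                 follower$time_s <= followee$time_s[i] + window_s &
                 follower$from == followee$from[i] &
                 follower$to == followee$to[i])
    if (hit) cnt <- cnt + 1L
  }
  cnt
}

# Gaussian blob sampler for segmentation tests
make_blobs <- function(centers, n_per, sd = 0.3, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(stats::rnorm(n_per, centers[i, 1], sd),
          stats::rnorm(n_per, centers[i, 2], sd))
  }))
  list(x = pts, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# small simulated colony shared across tests (cached per session)
demo_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- colony_config(6, 21600, seed = 101,
                           disturbance_rate_per_day = 2)
      cache <<- c(simulate_colony(cfg), list(config = cfg))
    }
    cache
  }
})
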