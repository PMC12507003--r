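lay <- build_layout()

mk_series <- function(cols, tick_s = 1) {
  location_series(do.call(cbind, cols), tick_s)
}

simple_ann <- function(nest = cell_id(0, 0), toilet = cell_id(0, 4),
                       garbage = cell_id(2, 2)) {
  chamber_annotation(data.frame(time_s = 0, cell = nest), toilet, garbage)
}

test_that("nest annotation follows windowed majority occupancy with the
           lowest-cell tie rule", {
  b1 <- cell_id(0, 0); b2 <- cell_id(2, 2)
  # all individuals in one box all day
  m <- matrix(b2, 8640, 4, dimnames = list(NULL, paste0("i", 1:4)))
  nest <- annotate_nest(mk_series(list(m)), layout = lay)
  expect_true(all(nest$cell == b2))
  # majority switches halfway: the annotated nest switches near where the
  # centered window mean crosses
  m2 <- rbind(matrix(b1, 4320, 4), matrix(b2, 4320, 4))
  colnames(m2) <- paste0("i", 1:4)
  nest2 <- annotate_nest(location_series(m2, 1), layout = lay,
                         window_s = 3600)
  expect_equal(nest2$cell[1], b1)
  expect_equal(nest2$cell[length(nest2$cell)], b2)
  switch_at <- nest2$time_s[which(nest2$cell == b2)[1]]
  expect_lt(abs(switch_at - 4320), 1800 + 10)
  # exact tie between two boxes: lower (row, col) wins
  m3 <- cbind(i1 = rep(b1, 8640), i2 = rep(b2, 8640))
  nest3 <- annotate_nest(location_series(m3, 1), layout = lay)
  expect_true(all(nest3$cell == min(b1, b2)))
})

test_that("stay segmentation emits maximal runs and keeps gaps separate", {
  x <- c(rep(cell_id(0, 0), 5), rep(cell_id(0, 1), 3), rep(cell_id(0, 0), 2))
  ser <- location_series(cbind(a = x), 1)
  ev <- segment_stays(ser)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$end_s - ev$start_s, c(5, 3, 2))
  # constant series -> a single event spanning the recording
  ev1 <- segment_stays(location_series(cbind(a = rep(cell_id(2, 2), 50)), 1))
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$end_s - ev1$start_s, 50)
  # an unknown run splits, and is emitted as a gap record
  x2 <- c(rep(cell_id(0, 0), 4), rep(NA_integer_, 3), rep(cell_id(0, 0), 3))
  ev2 <- segment_stays(location_series(cbind(a = x2), 1))
  expect_equal(nrow(ev2), 3)
  expect_true(is.na(ev2$cell[2]))
})

test_that("event and gap durations sum exactly to the recording length", {
  sim <- demo_sim()
  tls <- truth_location_series(sim$truth, tick_s = 1)
  ev <- segment_stays(tls)
  tot <- tapply(ev$end_s - ev$start_s, ev$individual, sum)
  expect_true(all(abs(tot - sim$config$duration_s) < 1e-9))
})

test_that("the Rest boundary is strict: more than 600 s in the nest", {
  ann <- simple_ann()
  nest <- cell_id(0, 0)
  for (dur in c(599, 600, 600.5, 601, 4000)) {
    ev <- data.frame(individual = "a", start_s = 0, end_s = dur,
                     cell = nest)
    got <- classify_stays(ev, ann)$category
    expect_equal(got, if (dur > 600) "Rest" else "Nest", info = dur)
  }
  # toilet and garbage classify by chamber function regardless of duration
  ev <- data.frame(individual = "a", start_s = c(0, 2), end_s = c(2, 4),
                   cell = c(cell_id(0, 4), cell_id(2, 2)))
  expect_equal(classify_stays(ev, ann)$category, c("Toilet", "Garbage"))
  # pipes and unannotated boxes are Other
  ev <- data.frame(individual = "a", start_s = 0, end_s = 5000,
                   cell = cell_id(0, 1))
  expect_equal(classify_stays(ev, ann)$category, "Other")
  # classification is idempotent
  ev2 <- classify_stays(classify_stays(ev, ann), ann)
  expect_equal(ev2, classify_stays(ev, ann))
})

test_that("disturbance phases need both the sub-25% run and a sub-10% dip", {
  tf <- function(fr) data.frame(time_s = seq_along(fr) * 10 - 10,
                                fraction = fr)
  expect_equal(nrow(detect_disturbances(tf(rep(0.5, 100)))), 0)
  fr <- rep(0.5, 100); fr[40:60] <- 0.2; fr[50] <- 0.05
  d <- detect_disturbances(tf(fr))
  expect_equal(nrow(d), 1)
  expect_equal(unname(d[1, "start"]), 390)
  expect_equal(unname(d[1, "end"]), 600)
  fr2 <- rep(0.5, 100); fr2[40:60] <- 0.15
  expect_equal(nrow(detect_disturbances(tf(fr2))), 0)
})

test_that("corrections reclassify nest-adjacent pipe stays, sub-nests and
           long gaps, and are idempotent", {
  ann <- simple_ann()
  nest <- cell_id(0, 0)
  adj_pipe <- lay$adjacency[[nest]][1]
  # (a) 700-s stay in a pipe adjacent to the nest -> Rest
  ev <- classify_stays(data.frame(individual = "a", start_s = 0,
                                  end_s = 700, cell = adj_pipe), ann)
  got <- apply_corrections(ev, ann, 700, lay)
  expect_equal(got$category, "Rest")
  # same stay in a non-adjacent pipe stays Other
  far_pipe <- cell_id(4, 3)
  ev <- classify_stays(data.frame(individual = "a", start_s = 0,
                                  end_s = 700, cell = far_pipe), ann)
  expect_equal(apply_corrections(ev, ann, 700, lay)$category, "Other")
  # (b) five co-residing individuals make a sub-nest; four do not
  box <- cell_id(4, 4)
  mk <- function(k) classify_stays(
    data.frame(individual = paste0("i", seq_len(k)), start_s = 0,
               end_s = 700, cell = box), ann)
  got5 <- apply_corrections(mk(5), ann, 700, lay)
  expect_true(all(got5$category == "Rest"))
  got4 <- apply_corrections(mk(4), ann, 700, lay)
  expect_true(all(got4$category == "Other"))
  # (c) a 45-minute unknown gap becomes one Rest event at the nest
  ev <- classify_stays(data.frame(individual = "a", start_s = 0,
                                  end_s = 2700, cell = NA_integer_), ann)
  got <- apply_corrections(ev, ann, 2700, lay)
  expect_equal(got$category, "Rest")
  expect_equal(got$cell, nest)
  # a 20-minute gap is left alone
  ev <- classify_stays(data.frame(individual = "a", start_s = 0,
                                  end_s = 1200, cell = NA_integer_), ann)
  expect_true(is.na(apply_corrections(ev, ann, 1200, lay)$category))
  # idempotence on a composite table
  evs <- classify_stays(data.frame(
    individual = c("a", "a", "b"), start_s = c(0, 700, 0),
    end_s = c(700, 3400, 700), cell = c(adj_pipe, NA, far_pipe)), ann)
  once <- apply_corrections(evs, ann, 3400, lay)
  expect_equal(apply_corrections(once, ann, 3400, lay), once)
})

test_that("duration modes recover a planted lognormal mixture valley", {
  set.seed(4)
  dur <- c(stats::rlnorm(2000, log(6), 0.6),
           stats::rlnorm(2000, log(5000), 0.6))
  m <- find_duration_modes(dur)
  expect_gte(length(m$antimodes), 1)
  true_valley <- sqrt(6 * 5000)   # geometric midpoint of the two modes
  best <- m$antimodes[which.min(abs(log(m$antimodes / true_valley)))]
  expect_lt(abs(log(best / true_valley)), log(2))
  # unimodal input has no antimode
  m1 <- find_duration_modes(stats::rlnorm(2000, log(50), 0.5))
  expect_length(m1$antimodes, 0)
  expect_error(find_duration_modes(5), "at least 2")
})

test_that("disturbance detection on simulated colonies covers planted
           episodes and little else", {
  cfg <- colony_config(15, 86400, disturbance_rate_per_day = 3, seed = 7)
  sim <- simulate_colony(cfg)
  ev <- classify_stays(truth_stay_events(sim$truth), simple_ann())
  rf <- rest_fraction_series(ev, 15, 86400)
  det <- detect_disturbances(rf)
  pl <- sim$truth$disturbance_intervals
  t <- rf$time_s
  in_pl <- rowSums(outer(t, pl[, 1], ">=") & outer(t, pl[, 2], "<")) > 0
  in_det <- rowSums(outer(t, det[, 1], ">=") & outer(t, det[, 2], "<")) > 0
  expect_gte(mean(in_det[in_pl]), 0.95)
  expect_lt(mean(in_det[!in_pl]), 0.05)
})
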