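test_that("daily parameters match direct tallies and the Sum = N x Mean
           identity", {
  # one full-day Rest event
  ev <- data.frame(individual = "a", start_s = 0, end_s = 86400,
                   cell = 1L, category = "Rest")
  v <- extract_daily_parameters(ev, "a", 1)
  expect_equal(unname(v["Sum_Rest"]), 86400)
  expect_equal(unname(v["N_Rest"]), 1)
  expect_equal(unname(v["Mean_Rest"]), 86400)
  expect_true(all(v[setdiff(names(v), c("Sum_Rest", "N_Rest",
                                        "Mean_Rest"))] == 0))
  # two toilet events with known active duration
  ev <- data.frame(individual = "a",
                   start_s = c(0, 100, 200), end_s = c(10, 130, 1160),
                   cell = c(5L, 5L, 13L),
                   category = c("Toilet", "Toilet", "Other"))
  v <- extract_daily_parameters(ev, "a", 1)
  expect_equal(unname(v["N_Toilet"]), 2)
  expect_equal(unname(v["Mean_Toilet"]), 20)
  expect_equal(unname(v["Sumrel_Toilet"]), 0.04)  # 40 / 1000
  # simulated day matches a brute-force tally
  sim <- demo_sim()
  ann <- chamber_annotation(data.frame(time_s = 0,
                                       cell = sim$config$nest_cell),
                            sim$config$toilet_cell,
                            sim$config$garbage_cell)
  evs <- classify_stays(truth_stay_events(sim$truth), ann)
  day_s <- sim$config$duration_s
  v <- extract_daily_parameters(evs, "ind02", 1, day_s = day_s)
  one <- evs[evs$individual == "ind02", ]
  for (cc in c("Rest", "Nest", "Toilet", "Garbage", "Other")) {
    expect_equal(unname(v[paste0("Sum_", cc)]),
                 sum((one$end_s - one$start_s)[one$category == cc]))
    expect_equal(unname(v[paste0("N_", cc)]), sum(one$category == cc))
  }
  # Sum = N x Mean for every category with N > 0
  for (cc in c("Rest", "Nest", "Toilet", "Garbage", "Other")) {
    if (v[paste0("N_", cc)] > 0)
      expect_equal(unname(v[paste0("Sum_", cc)]),
                   unname(v[paste0("N_", cc)] * v[paste0("Mean_", cc)]))
  }
  expect_length(v, 23)
})

test_that("zero active duration sets relative terms to 0 with a flag", {
  ev <- data.frame(individual = "a", start_s = 0, end_s = 86400,
                   cell = 1L, category = "Rest")
  v <- extract_daily_parameters(ev, "a", 1)
  expect_true(attr(v, "zero_active"))
  expect_true(all(v[grep("rel", names(v))] == 0))
})

test_that("normalization yields zero mean and unit variance per colony-day
           and recovers a lognormal Box-Cox lambda near 0", {
  set.seed(2)
  mat <- cbind(stats::rlnorm(300, 3, 0.7), stats::rgamma(300, 2, 0.1))
  colony <- rep(c("c1", "c2"), each = 150)
  day <- rep(rep(1:3, each = 50), 2)
  out <- normalize_parameters(mat, colony, day)
  for (g in split(seq_len(300), paste(colony, day))) {
    expect_equal(colMeans(out[g, ]), c(0, 0), tolerance = 1e-8)
    expect_equal(apply(out[g, ], 2, stats::sd), c(1, 1), tolerance = 1e-8)
  }
  lam <- attr(out, "lambda")
  expect_lt(abs(lam[1, 1]), 0.25)       # lognormal column -> lambda ~ 0
  # constant column within a colony-day -> zeros with warning
  mat2 <- cbind(rep(1, 20), stats::rnorm(20))
  expect_warning(out2 <- normalize_parameters(mat2, "c", rep(1, 20)),
                 "constant")
  expect_true(all(out2[, 1] == 0))
})

test_that("watershed segmentation separates planted blobs and collapses
           under infinite suppression", {
  blobs <- make_blobs(rbind(c(0, 0), c(8, 8)), 100, sd = 0.4, seed = 5)
  cm <- embed_and_segment(NULL, embedding = blobs$x)
  expect_equal(cm$K, 2)
  expect_equal(mclust::adjustedRandIndex(cm$labels, blobs$labels), 1)
  # three blobs, 300 points: near-perfect recovery
  b3 <- make_blobs(rbind(c(0, 0), c(8, 0), c(4, 7)), 100, sd = 0.5,
                   seed = 6)
  cm3 <- embed_and_segment(NULL, embedding = b3$x)
  expect_gte(mclust::adjustedRandIndex(cm3$labels, b3$labels), 0.9)
  # labels are renumbered by descending size
  sizes <- as.integer(table(cm3$labels))
  expect_true(all(diff(sizes) <= 0))
  # minima suppression beyond the density maximum -> a single basin
  cm1 <- embed_and_segment(NULL, embedding = b3$x, hmin = 2)
  expect_equal(cm1$K, 1)
  # degenerate embedding -> single cluster with warning
  expect_warning(cmd <- embed_and_segment(NULL,
                                          embedding = cbind(rep(1, 10),
                                                            rep(2, 10))),
                 "degenerate")
  expect_equal(cmd$K, 1)
})

test_that("full pipeline is deterministic given a seed", {
  set.seed(99)
  mat <- matrix(stats::rnorm(60 * 5), 60, 5)
  cm_a <- embed_and_segment(mat, seed = 42)
  cm_b <- embed_and_segment(mat, seed = 42)
  expect_identical(cm_a$labels, cm_b$labels)
  expect_identical(cm_a$embedding, cm_b$embedding)
})

test_that("embedding outliers flag a displaced individual for exclusion", {
  set.seed(3)
  emb <- cbind(stats::rnorm(300), stats::rnorm(300))
  ind <- rep(sprintf("i%02d", 1:10), each = 30)
  none <- detect_embedding_outliers(emb, ind)
  expect_length(none$outliers, 0)
  emb2 <- emb
  shift <- 10 * stats::IQR(sqrt(rowSums(emb^2)))
  emb2[ind == "i04", ] <- emb2[ind == "i04", ] + shift
  out <- detect_embedding_outliers(emb2, ind)
  expect_equal(out$exclude_individuals, "i04")
  expect_equal(out$exclude_samples, which(ind == "i04"))
  # infinite threshold flags nothing
  inf <- detect_embedding_outliers(emb2, ind, k_iqr = Inf)
  expect_length(inf$outliers, 0)
})

test_that("representative cluster is modal with the rare-cluster tie rule", {
  asg <- data.frame(individual = rep("a", 30), day = 1:30,
                    cluster = c(rep(2L, 20), rep(5L, 10)))
  expect_equal(assign_representative_cluster(asg, "a"), 2L)
  # tie between 1 and 4; cluster 4 is globally rarer
  asg2 <- rbind(
    data.frame(individual = "a", day = 1:30,
               cluster = c(rep(1L, 15), rep(4L, 15))),
    data.frame(individual = "b", day = 1:30, cluster = rep(1L, 30)))
  expect_equal(assign_representative_cluster(asg2, "a"), 4L)
  asg3 <- data.frame(individual = "c", day = 1, cluster = 6L)
  expect_equal(assign_representative_cluster(asg3, "c"), 6L)
  expect_true(is.na(assign_representative_cluster(asg3, "zz")))
})
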