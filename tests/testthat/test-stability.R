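test_that("consistency index hits its analytic anchors", {
  # all days in one cluster -> 1
  expect_equal(consistency_index(c(1, 0, 0, 0, 0, 0, 0), 7)$index, 1)
  # uniform over all clusters -> 0
  expect_equal(consistency_index(rep(1 / 7, 7), 7)$index, 0,
               tolerance = 1e-12)
  # counts (29, 1) over 30 days with K = 7 (frozen independent evaluation)
  ci <- consistency_index(c(29, 1, 0, 0, 0, 0, 0) / 30, 7)
  expect_equal(ci$index, 0.9248964572801508, tolerance = 1e-12)
  expect_error(consistency_index(c(1), 1), "K")
  # invariance under cluster relabeling
  p <- c(0.5, 0.3, 0.2, 0, 0, 0, 0)
  expect_equal(consistency_index(p, 7)$index,
               consistency_index(sample(p), 7)$index)
})

test_that("consistency null gives degenerate and extreme p-values
           correctly", {
  # degenerate probabilities -> all simulated indices are 1
  nl <- consistency_null(c(1, 0, 0), n_days = 30, n_sims = 50, seed = 1)
  expect_true(all(nl$sim_indices == 1))
  # observed above all simulations -> smallest add-one p
  nl2 <- consistency_null(rep(1 / 3, 3), n_days = 30, n_sims = 99,
                          seed = 2, observed = 1)
  expect_equal(nl2$p_values, 1 / 100, tolerance = 1e-9)
  # observed below all simulations -> p = 1
  nl3 <- consistency_null(rep(1 / 3, 3), n_days = 30, n_sims = 99,
                          seed = 2, observed = -0.01)
  expect_equal(nl3$p_values, 1)
})

test_that("null p-values are super-uniform: few false positives among null
           individuals", {
  # the realized rate from a single 999-draw null carries Monte-Carlo
  # threshold noise (~0.8 pp), so the rate is averaged over replicate
  # experiments of the stated size
  probs <- c(0.3, 0.25, 0.15, 0.1, 0.1, 0.05, 0.05)
  fpr <- vapply(0:9, function(r) {
    null <- consistency_null(probs, n_days = 30, n_sims = 999,
                             seed = 11 + r)
    set.seed(12 + 100 * r)
    obs_counts <- stats::rmultinom(2000, 30, probs)
    p_obs <- obs_counts / 30
    H <- -colSums(p_obs * ifelse(p_obs > 0, log(p_obs), 0))
    obs <- 1 - H / log(7)
    sorted <- sort(null$sim_indices)
    p <- (1 + 999 - findInterval(obs - 1e-12, sorted)) / 1000
    mean(p < 0.05)
  }, numeric(1))
  expect_lte(mean(fpr), 0.055)
})

test_that("cosine stability matches hand values and centers on its null for
           random memberships", {
  asg <- function(mat) {
    do.call(rbind, lapply(seq_len(ncol(mat)), function(d)
      data.frame(individual = paste0("i", seq_len(nrow(mat))), day = d,
                 cluster = mat[, d])))
  }
  # identical membership across days -> cosine 1
  m <- matrix(rep(c(1L, 1L, 2L, 2L), 3), 4, 3)
  cs <- cluster_stability_cosine(asg(m), cluster = 1, n_shuffles = 5)
  expect_equal(cs$observed, c(1, 1))
  # disjoint membership -> 0
  m2 <- cbind(c(1L, 1L, 2L, 2L), c(2L, 2L, 1L, 1L))
  cs2 <- cluster_stability_cosine(asg(m2), cluster = 1, n_shuffles = 5)
  expect_equal(cs2$observed, 0)
  # random memberships: observed mean close to the null mean
  set.seed(5)
  m3 <- matrix(sample(1:2, 30 * 30, TRUE), 30, 30)
  cs3 <- cluster_stability_cosine(asg(m3), cluster = 1,
                                  n_shuffles = 50, seed = 6)
  expect_lt(abs(mean(cs3$observed) - mean(cs3$null)), 0.1)
})

test_that("co-assignment index is 1 for a pure cluster and matches the
           hand oracle for a 50/50 pair", {
  asg <- data.frame(individual = rep(paste0("i", 1:4), each = 30),
                    day = rep(1:30, 4), cluster = 3L)
  ca <- co_assignment(asg, K = 3)
  expect_equal(ca$index[3, 3], 1)
  # two individuals, each split 15/15 between clusters 1 and 2:
  # C_emp(1,2) = mean(0.5 * 0.5) = 0.25; C_ref = 0.5 * 0.5 -> index 1
  asg2 <- data.frame(individual = rep(c("a", "b"), each = 30),
                     day = rep(1:30, 2),
                     cluster = rep(c(rep(1L, 15), rep(2L, 15)), 2))
  ca2 <- co_assignment(asg2, K = 2)
  expect_equal(ca2$index[1, 2], 1)
  expect_equal(ca2$C_emp[1, 2], 0.25)
  expect_true(isSymmetric(ca2$index))
})

test_that("co-assignment approaches independence for i.i.d. assignments", {
  set.seed(21)
  counts <- stats::rmultinom(200, 30, rep(1 / 7, 7))
  asg <- do.call(rbind, lapply(1:200, function(i)
    data.frame(individual = sprintf("i%03d", i), day = 1:30,
               cluster = rep(1:7, counts[, i]))))
  ca <- co_assignment(asg, K = 7)
  off <- ca$index[upper.tri(ca$index)]
  expect_true(all(abs(off - 1) < 0.1))
})

test_that("leadership ranks order rest onsets, average ties, and apply the
           80% participation rule", {
  tr <- data.frame(time_s = 1000, from = 1L, to = 13L)
  mk_rest <- function(ids, onsets, cell = 13L)
    data.frame(individual = ids, start_s = onsets,
               end_s = onsets + 700, cell = cell, category = "Rest")
  ev <- mk_rest(c("a", "b", "c"), 1000 + c(600, 1200, 1800))
  lr <- leadership_ranks(ev, tr, c("a", "b", "c"))
  expect_equal(lr$rank[match(c("a", "b", "c"), lr$individual)], c(1, 2, 3))
  # simultaneous onsets share averaged ranks
  ev2 <- mk_rest(c("a", "b", "c"), 1000 + c(600, 600, 1800))
  lr2 <- leadership_ranks(ev2, tr, c("a", "b", "c"))
  expect_equal(sort(lr2$rank), c(1.5, 1.5, 3))
  # 7 of 10 participating (70%) -> transition excluded
  ev3 <- mk_rest(paste0("i", 1:7), 1000 + seq(600, by = 60, length.out = 7))
  lr3 <- leadership_ranks(ev3, tr, paste0("i", 1:10))
  expect_equal(nrow(lr3), 0)
  # 9 of 10 (90%) -> included, ranks are a permutation
  ev4 <- mk_rest(paste0("i", 1:9), 1000 + seq(600, by = 60, length.out = 9))
  lr4 <- leadership_ranks(ev4, tr, paste0("i", 1:10))
  expect_equal(sort(lr4$rank), 1:9)
  # rests outside the window or in another chamber do not count
  ev5 <- rbind(mk_rest(c("a", "b", "c"), 1000 + c(600, 1200, 1800)),
               mk_rest("d", 1000 + 50000),
               mk_rest("e", 1100, cell = 25L))
  lr5 <- leadership_ranks(ev5, tr, c("a", "b", "c", "d", "e"))
  expect_equal(nrow(lr5), 0)  # only 3 of 5 participate
  expect_equal(nrow(leadership_ranks(ev5, tr[0, ], letters[1:3])), 0)
})
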