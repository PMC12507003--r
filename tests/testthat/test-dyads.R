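test_that("activity binarization paints Rest, gaps and exclusions
           correctly", {
  ev <- data.frame(individual = "a",
                   start_s = c(0, 43200), end_s = c(43200, 86400),
                   cell = c(1L, 13L), category = c("Rest", "Other"))
  v <- binarize_activity(ev, "a", 86400)
  expect_equal(length(v), 8640)
  expect_true(all(v[1:4320] == 1L))
  expect_true(all(v[4321:8640] == 0L))
  # a gap becomes missing
  ev2 <- data.frame(individual = "a",
                    start_s = c(0, 100), end_s = c(100, 200),
                    cell = c(1L, NA), category = c("Rest", NA))
  v2 <- binarize_activity(ev2, "a", 200)
  expect_true(all(v2[1:10] == 1L) && all(is.na(v2[11:20])))
  # samples inside a disturbance interval are missing
  v3 <- binarize_activity(ev, "a", 86400,
                          exclusions = cbind(1000, 2000))
  expect_true(all(is.na(v3[101:200])))
  expect_true(all(v3[1:100] == 1L))
})

test_that("synchrony counting matches the brute-force loop", {
  expect_equal(count_synchrony(rep(1L, 100), rep(1L, 100)), 100)
  expect_equal(count_synchrony(rep(1L, 50), rep(0L, 50)), 0)
  set.seed(7)
  a <- sample(c(0L, 1L, NA), 500, TRUE)
  b <- sample(c(0L, 1L, NA), 500, TRUE)
  expect_equal(count_synchrony(a, b), bf_count_synchrony(a, b))
  expect_error(count_synchrony(a, b[-1]), "length")
})

test_that("proximity restricts to jointly active samples outside the nest", {
  nest <- 1L
  loc_a <- c(5L, 5L, 1L, 7L, 7L, NA)
  loc_b <- c(5L, 9L, 5L, 7L, 7L, 7L)
  act_a <- c(0L, 0L, 0L, 0L, 1L, 0L)
  act_b <- c(0L, 0L, 0L, 0L, 0L, 0L)
  pr <- count_proximity(loc_a, loc_b, act_a, act_b, nest)
  # kept samples: 1 (same cell 5), 2 (cells differ), 4 (same cell 7)
  expect_equal(pr$idx, c(1L, 2L, 4L))
  expect_equal(pr$count, 2)
  expect_false(pr$undefined)
  # never simultaneously outside the nest -> undefined
  pr2 <- count_proximity(rep(1L, 5), c(1L, 1L, 1L, 1L, 1L),
                         rep(0L, 5), rep(0L, 5), nest)
  expect_true(pr2$undefined)
  # brute-force tally on random vectors
  set.seed(8)
  la <- sample(c(1:9, NA), 300, TRUE); lb <- sample(c(1:9, NA), 300, TRUE)
  aa <- sample(0:1, 300, TRUE); ab <- sample(0:1, 300, TRUE)
  pr3 <- count_proximity(la, lb, aa, ab, nest)
  manual <- sum(!is.na(la) & !is.na(lb) & aa == 0 & ab == 0 &
                  la != nest & lb != nest & la == lb)
  expect_equal(pr3$count, manual)
})

test_that("movement extraction handles static series, round trips and
           integrity", {
  lay <- build_layout()
  expect_equal(nrow(extract_movements(rep(1L, 100), 0.1, lay)), 0)
  x <- c(rep(cell_id(0, 0), 5), rep(cell_id(0, 1), 3), rep(cell_id(0, 0), 2))
  mv <- extract_movements(x, 1, lay)
  expect_equal(nrow(mv), 2)
  expect_equal(mv$from, cell_id(c(0, 0), c(0, 1)))
  expect_equal(mv$to, cell_id(c(0, 0), c(1, 0)))
  # unknown stretches produce no events
  x2 <- c(1L, 1L, NA, 13L, 13L)
  expect_equal(nrow(extract_movements(x2, 1, lay)), 0)
  # teleporting trips the data-integrity check
  expect_error(extract_movements(c(1L, 13L), 1, lay), "non-adjacent")
})

test_that("follow counting is directional with a closed 3-s window", {
  mv_a <- data.frame(time_s = 10, from = 1L, to = 2L)
  mv_b <- data.frame(time_s = 11, from = 1L, to = 2L)
  expect_equal(count_follows(mv_a, mv_b), 1)   # b follows a
  expect_equal(count_follows(mv_b, mv_a), 0)   # not the reverse
  expect_equal(count_follows(mv_a, data.frame(time_s = 13.5, from = 1L,
                                              to = 2L)), 0)
  expect_equal(count_follows(mv_a, data.frame(time_s = 13, from = 1L,
                                              to = 2L)), 1)
  # at most one count per followee event
  mv_c <- data.frame(time_s = c(10.5, 11.5), from = 1L, to = 2L)
  expect_equal(count_follows(mv_a, mv_c), 1)
  # random series match the brute-force loop
  set.seed(9)
  mk <- function(n) data.frame(time_s = sort(stats::runif(n, 0, 500)),
                               from = sample(1:4, n, TRUE),
                               to = sample(5:8, n, TRUE))
  fe <- mk(150); fo <- mk(200)
  expect_equal(count_follows(fe, fo), bf_count_follows(fe, fo, 3))
})

test_that("cyclic surrogate machinery standardizes and classifies", {
  set.seed(10)
  a <- sample(0:1, 400, TRUE)
  b <- sample(0:1, 400, TRUE)
  res <- cyclic_surrogate_index(function(x, y) sum(x == y), a, b,
                                n_surrogates = 199, seed = 3)
  expect_true(is.finite(res$index))
  expect_true(res$p_value > 0 && res$p_value <= 1)
  # constant vector -> sd 0 -> flagged, ns, undefined index
  res0 <- cyclic_surrogate_index(function(x, y) sum(x == y),
                                 rep(1L, 100), rep(1L, 100),
                                 n_surrogates = 19, seed = 1)
  expect_true(res0$flagged)
  expect_true(is.na(res0$index))
  expect_equal(res0$class, "ns")
  expect_error(cyclic_surrogate_index(function(x, y) 0, a, b,
                                      n_surrogates = 5), "19")
})

test_that("joint circular shifts leave synchrony and proximity counts
           unchanged (null exchangeability)", {
  set.seed(11)
  a <- sample(0:1, 300, TRUE); b <- sample(0:1, 300, TRUE)
  la <- sample(2:9, 300, TRUE); lb <- sample(2:9, 300, TRUE)
  shift <- burrowtrack:::circular_shift
  for (k in c(1, 17, 150, 299)) {
    expect_equal(count_synchrony(shift(a, k), shift(b, k)),
                 count_synchrony(a, b))
    expect_equal(sum(shift(la, k) == shift(lb, k)), sum(la == lb))
  }
})

test_that("follow surrogates preserve timing and shift only the path
           labels", {
  set.seed(12)
  fe <- data.frame(time_s = sort(stats::runif(80, 0, 400)),
                   from = sample(1:4, 80, TRUE),
                   to = sample(5:8, 80, TRUE))
  fo <- data.frame(time_s = sort(stats::runif(100, 0, 400)),
                   from = sample(1:4, 100, TRUE),
                   to = sample(5:8, 100, TRUE))
  pairs <- burrowtrack:::follow_candidate_pairs(fe, fo, 3)
  for (k in c(1, 31, 99)) {
    shifted <- fo
    idx <- ((seq_len(100) - 1 + k) %% 100) + 1
    shifted$from <- fo$from[idx]; shifted$to <- fo$to[idx]
    expect_equal(burrowtrack:::count_follows_from_pairs(pairs, k),
                 bf_count_follows(fe, shifted, 3))
  }
})

test_that("Yeo-Johnson standardization has unit moments, preserves order,
           and recovers symmetric input", {
  set.seed(13)
  x <- stats::rnorm(400)
  y <- transform_follow_indices(x)
  expect_equal(mean(y), 0, tolerance = 1e-9)
  expect_equal(stats::sd(y), 1, tolerance = 1e-9)
  expect_lt(abs(attr(y, "lambda") - 1), 0.35)
  expect_true(all(diff(y[order(x)]) >= 0))
  # missing entries propagate
  x2 <- c(x, NA)
  y2 <- transform_follow_indices(x2)
  expect_true(is.na(y2[401]))
  expect_error(transform_follow_indices(rep(2, 10)), "identical")
})

test_that("dyad index tables cover all pairs with derived seeds", {
  set.seed(14)
  act <- matrix(sample(0:1, 500 * 4, TRUE), 500, 4,
                dimnames = list(NULL, paste0("i", 1:4)))
  tbl <- dyad_index_table(act, "synchrony", n_surrogates = 49, seed = 2)
  expect_equal(nrow(tbl), 6)
  expect_false(attr(tbl, "directed"))
  tbl2 <- dyad_index_table(act, "synchrony", n_surrogates = 49, seed = 2)
  expect_identical(tbl, tbl2)
  mv <- lapply(1:3, function(i) data.frame(
    time_s = sort(stats::runif(50, 0, 500)),
    from = sample(1:4, 50, TRUE), to = sample(5:8, 50, TRUE)))
  names(mv) <- paste0("i", 1:3)
  tblf <- dyad_index_table(mv, "follow", n_surrogates = 49, seed = 2)
  expect_equal(nrow(tblf), 6)
  expect_true(attr(tblf, "directed"))
})
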