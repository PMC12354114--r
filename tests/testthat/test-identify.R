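test_that("the slice window reproduces thin- and thick-slice query sizes", {
  # 0.625 mm: +/- 12 slices around the centre -> 25
  w <- slice_window(100, 0.625, 7.5, 200)
  expect_length(w, 25L)
  expect_equal(w, 88:112)
  # 2.5 mm: +/- 3 slices -> 7
  w <- slice_window(50, 2.5, 7.5, 100)
  expect_length(w, 7L)
  expect_equal(w, 47:53)
  # clipping at the stack boundary
  w <- slice_window(5, 0.625, 7.5, 200)
  expect_equal(w, 0:17)
  expect_error(slice_window(10, 0, 7.5, 100), "positive")
  expect_error(slice_window(-1, 2.5, 7.5, 100), "within the stack")
  expect_error(slice_window(100, 2.5, 7.5, 100), "within the stack")
})

test_that("query lists have one scored row per database entry", {
  db <- toy_database(lapply(1:6, function(i) random_feature_set(12, seed = i)),
                     rep(c("I1", "I2", "I3"), each = 2))
  qs <- list(q1 = random_feature_set(10, seed = 50),
             q2 = random_feature_set(10, seed = 51))
  lists <- query_database(qs, db, seed = 4)
  expect_length(lists, 2L)
  for (l in lists) {
    expect_equal(nrow(l), 6L)
    expect_true(all(l$score_percent >= 0 & l$score_percent <= 100))
  }
  # an empty query set is skipped with a warning, recorded as NULL
  expect_warning(
    lists2 <- query_database(list(bad = feature_set(), ok = qs$q1), db),
    "empty")
  expect_null(lists2$bad)
  expect_false(is.null(lists2$ok))
})

test_that("a query identical to an enrolled slice tops its score list", {
  sets <- lapply(1:6, function(i) {
    fs <- random_feature_set(15, seed = 200 + i)
    fs$keypoints$x <- fs$keypoints$x + i   # general position, distinct
    fs
  })
  db <- toy_database(sets, rep(c("I1", "I2", "I3"), each = 2))
  l <- query_database(list(q = sets[[3]]), db, seed = 9)[[1]]
  expect_equal(which.max(l$score_percent), 3L)
  expect_equal(max(l$score_percent), 100)
})

test_that("per-identity filtering takes the maximum over entries", {
  sl <- data.frame(entry_id = c("e1", "e2", "e3"),
                   identity_id = c("I1", "I1", "I2"),
                   score_percent = c(0.5, 0.9, 0.7))
  attr(sl, "query_ref") <- "q"
  fl <- filter_max_per_identity(sl)
  expect_equal(fl[["I1"]], 0.9)
  expect_equal(fl[["I2"]], 0.7)
  expect_length(fl, 2L)
})

test_that("rank tallies use competition ranking with shared rank 1", {
  L1 <- c(I1 = 1.0, I2 = 0.9, I3 = 0.2)
  L2 <- c(I1 = 0.8, I2 = 0.8, I3 = 0.1)
  t <- tally_ranks(list(L1, L2))
  t <- t[order(t$identity_id), ]
  expect_equal(t$rank1_count, c(2L, 1L, 0L))   # L2 tie: I1 and I2 at rank 1
  expect_equal(t$max_score, c(1.0, 0.9, 0.2))
  # with three identities everyone is inside the top 10 of both lists
  expect_equal(t$top10_count, c(2L, 2L, 2L))
})

test_that("consolidation strategies order by their documented keys", {
  t <- tally_ranks(list(c(I1 = 1.0, I2 = 0.9, I3 = 0.2),
                        c(I1 = 0.8, I2 = 0.8, I3 = 0.1)))
  expect_equal(consolidate(t, "rank_based")$identity_id,
               c("I1", "I2", "I3"))
  expect_equal(consolidate(t, "score_based")$identity_id,
               c("I1", "I2", "I3"))

  # identical tallies fall back to identity order (deterministic total order)
  same <- data.frame(identity_id = c("B", "C", "A"),
                     rank1_count = 1L, top10_count = 1L, max_score = 5)
  expect_equal(consolidate(same, "rank_based")$identity_id,
               c("A", "B", "C"))
  expect_error(consolidate(same, "best_based"), "arg")

  # rank-based and score-based can disagree when a high single score
  # competes with consistent rank-1 finishes
  t2 <- data.frame(identity_id = c("A", "B"),
                   rank1_count = c(5L, 1L), top10_count = c(5L, 5L),
                   max_score = c(1.2, 2.4))
  expect_equal(consolidate(t2, "rank_based")$identity_id[1], "A")
  expect_equal(consolidate(t2, "score_based")$identity_id[1], "B")
})

test_that("the sought identity's position is its 1-based list index", {
  cons <- consolidate(data.frame(identity_id = c("A", "B", "C"),
                                 rank1_count = c(3L, 2L, 1L),
                                 top10_count = c(3L, 3L, 3L),
                                 max_score = c(3, 2, 1)), "rank_based")
  expect_equal(evaluate_position(cons, "A"), 1L)
  expect_equal(evaluate_position(cons, "C"), 3L)
  expect_error(evaluate_position(cons, "Z"), "not enrolled")
})

test_that("demographic prefiltering respects unknowns and age windows", {
  fs <- lapply(1:4, function(i) random_feature_set(5, seed = i))
  db <- toy_database(fs, c("I1", "I2", "I3", "I4"),
                     sex = c("male", "female", "unknown", "male"),
                     birth = c("19500101", "19800101", NA, "19300101"),
                     study = rep("20150601", 4))
  kept <- prefilter_candidates(db, sex = "male")
  expect_setequal(names(kept$identity_index), c("I1", "I3", "I4"))

  # birth 1950, study 2015 -> age 65, inside [60, 70]; unknown birth kept
  kept <- prefilter_candidates(db, age_range_years = c(60, 70))
  expect_setequal(names(kept$identity_index), c("I1", "I3"))

  # no filters: identity case
  expect_equal(length(prefilter_candidates(db)$entries), 4L)
  expect_error(prefilter_candidates(db, age_range_years = c(70, 60)),
               "increasing")
})

test_that("CMC rates accumulate over ranks", {
  cmc <- cmc_table(c(1L, 2L, 1L, 7L), max_rank = 7L)
  expect_equal(cmc$identification_rate[1], 0.5)
  expect_equal(cmc$identification_rate[2], 0.75)
  expect_equal(cmc$identification_rate[7], 1)
  expect_true(all(diff(cmc$identification_rate) >= 0))
})
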