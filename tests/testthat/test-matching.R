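test_that("nearest-neighbour candidates follow squared Euclidean distance", {
  A <- rbind(c(0, 0), c(1, 0))
  B <- rbind(c(0, 0.1), c(5, 5), c(1, 0.05))
  out <- nn_candidates(A, B)
  expect_equal(out$ref_idx, c(1L, 3L))
  expect_equal(out$d1_sq, c(0.01, 0.0025))
  expect_equal(out$d2_sq, c(1.0025, 1.01))

  # a query identical to a reference row has zero self distance
  out <- nn_candidates(rbind(c(5, 5)), B)
  expect_equal(out$d1_sq, 0)

  # fewer than two reference rows: ratio test impossible
  expect_equal(nrow(nn_candidates(A, B[1, , drop = FALSE])), 0L)
  expect_equal(nrow(nn_candidates(A[0, , drop = FALSE], B)), 0L)
})

test_that("the ratio test keeps distinctive matches and rejects degenerate ones", {
  cand <- data.frame(query_idx = 1:3, ref_idx = c(1L, 2L, 3L),
                     d1_sq = c(0.04, 0.36, 0), d2_sq = c(0.25, 0.49, 0))
  kept <- lowe_filter(cand, 0.6)
  # 0.04/0.25 = 0.16 keep; 0.36/0.49 = 0.735 reject; 0/0 undefined reject
  expect_equal(kept$query_idx, 1L)
})

test_that("unique assignment keeps the closest claim per reference", {
  p <- data.frame(query_idx = 1:3, ref_idx = c(2L, 2L, 4L),
                  d1_sq = c(0.1, 0.2, 0.05))
  out <- unique_assign(p)
  expect_equal(out$query_idx, c(1L, 3L))
  expect_equal(out$ref_idx, c(2L, 4L))
  expect_false(any(duplicated(out$ref_idx)))

  distinct <- data.frame(query_idx = 1:3, ref_idx = 3:1, d1_sq = c(1, 2, 3))
  expect_equal(unique_assign(distinct)$query_idx, 1:3)
  expect_equal(nrow(unique_assign(p[0, ])), 0L)
})

test_that("RANSAC retains transform-consistent pairs and drops outliers", {
  set.seed(31)
  n <- 10L
  src <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100))
  dst <- data.frame(x = src$x + 5, y = src$y + 3)   # pure translation
  # two gross outliers appended
  src2 <- rbind(src, data.frame(x = c(10, 80), y = c(10, 80)))
  dst2 <- rbind(dst, data.frame(x = c(90, 5), y = c(20, 60)))
  pairs <- data.frame(query_idx = 1:12, ref_idx = 1:12, d1_sq = 0.1)
  kp_q <- data.frame(x = src2$x, y = src2$y)
  kp_r <- data.frame(x = dst2$x, y = dst2$y)
  set.seed(99)
  inl <- ransac_filter(pairs, kp_q, kp_r)
  expect_setequal(inl$query_idx, 1:10)

  # below the homography minimum: no verification possible
  expect_equal(nrow(ransac_filter(pairs[1:3, ], kp_q, kp_r)), 0L)

  # identity transform keeps everything (zero residuals)
  set.seed(99)
  inl <- ransac_filter(pairs[1:10, ], kp_q[1:10, ], kp_q[1:10, ])
  expect_equal(nrow(inl), 10L)
})

test_that("collinear geometry yields no verified matches", {
  kp <- data.frame(x = 1:6, y = 2 * (1:6) + 1)   # all on one line
  pairs <- data.frame(query_idx = 1:6, ref_idx = 1:6, d1_sq = 0.1)
  set.seed(7)
  expect_warning(out <- ransac_filter(pairs, kp, kp), "degenerate")
  expect_equal(nrow(out), 0L)
})

test_that("pipeline stages only ever shrink the match set", {
  for (s in 1:5) {
    A <- random_feature_set(40, seed = s)
    B <- random_feature_set(35, seed = s + 100)
    cand <- nn_candidates(A$descriptors, B$descriptors)
    lo <- lowe_filter(cand, 0.9)    # permissive, to exercise later stages
    un <- unique_assign(lo)
    set.seed(s)
    ra <- ransac_filter(un, A$keypoints, B$keypoints)
    expect_lte(nrow(lo), nrow(cand))
    expect_lte(nrow(un), nrow(lo))
    expect_lte(nrow(ra), nrow(un))
    expect_lte(nrow(cand), A$n)
  }
})

test_that("directional matching equals the brute-force reference", {
  for (s in 1:20) {
    set.seed(s)
    nq <- sample(3:50, 1); nr <- sample(2:50, 1)
    Q <- matrix(rnorm(nq * 64), nq, 64)
    R <- matrix(rnorm(nr * 64), nr, 64)
    # duplicate some rows to exercise tie and d2 = 0 handling
    if (nr > 4) R[2, ] <- R[1, ]
    fast <- unique_assign(lowe_filter(nn_candidates(Q, R), 0.6))
    slow <- brute_force_direction(Q, R, 0.6)
    expect_equal(fast$query_idx, slow$query_idx)
    expect_equal(fast$ref_idx, slow$ref_idx)
    expect_equal(fast$d1_sq, slow$d1_sq)
  }
})

test_that("the bidirectional score is exact for identical sets and bounded", {
  A <- default_slice_features()
  s <- score_pair(A, A, seed = 3)
  expect_equal(s$score_percent, 100)
  expect_equal(s$m_ab, A$n)
  expect_equal(s$m_ba, A$n)

  # no surviving matches in either direction scores 0
  far <- random_feature_set(20, seed = 5)
  far$descriptors <- far$descriptors + 100
  s0 <- score_pair(A, far, seed = 3)
  expect_equal(s0$score_percent, 0)

  # bounds and internal consistency on random pairs
  for (s in 1:5) {
    X <- random_feature_set(sample(5:30, 1), seed = s)
    Y <- random_feature_set(sample(5:30, 1), seed = s + 50)
    sc <- score_pair(X, Y, seed = s)
    expect_gte(sc$score_percent, 0)
    expect_lte(sc$score_percent, 100)
    expect_equal(sc$score_percent,
                 (sc$m_ab + sc$m_ba) / (2 * sc$n_query) * 100)
    expect_lte(sc$m_ab, min(X$n, Y$n))
    expect_lte(sc$m_ba, min(X$n, Y$n))
  }

  expect_error(score_pair(feature_set(), A), "empty")
})

test_that("scores are reproducible for a fixed seed", {
  A <- phantom_features(seed = 21L, z = 2L)
  B <- phantom_features(seed = 22L, z = 2L)
  s1 <- score_pair(A, B, seed = 17)
  s2 <- score_pair(A, B, seed = 17)
  expect_identical(s1, s2)
})
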