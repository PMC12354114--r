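# Descriptor matching between two feature sets and the bidirectional
# similarity score. One direction runs: exhaustive squared-Euclidean nearest
# neighbours -> Lowe's ratio test -> unique (injective) assignment -> RANSAC
# homography verification. The score averages the surviving match counts of
# both directions and normalises by the query set's feature count:
#
#   score = (m_AB + m_BA) / (2 * |A|) * 100   [%]
#
# ranging from 0% (no match) to 100% (identical image).

#' Nearest-neighbour candidates by squared Euclidean distance
#'
#' For each query descriptor, the index of the closest reference descriptor
#' plus the two smallest squared distances (needed for the ratio test).
#' Fewer than two reference rows make the ratio test impossible, so the
#' result is empty.
#'
#' @param query_desc,ref_desc numeric descriptor matrices (rows = features).
#' @return data frame with columns `query_idx`, `ref_idx`, `d1_sq`, `d2_sq`
#'   (1-based indices).
#' @export
nn_candidates <- function(query_desc, ref_desc) {
  empty <- data.frame(query_idx = integer(0), ref_idx = integer(0),
                      d1_sq = numeric(0), d2_sq = numeric(0))
  if (!is.matrix(query_desc) || !is.matrix(ref_desc))
    stop("descriptors must be matrices", call. = FALSE)
  nq <- nrow(query_desc); nr <- nrow(ref_desc)
  if (nq == 0L || nr < 2L) return(empty)
  # ||q - r||^2 = ||q||^2 + ||r||^2 - 2 q.r, clamped at 0 for rounding noise
  d <- outer(rowSums(query_desc^2), rowSums(ref_desc^2), "+") -
    2 * tcrossprod(query_desc, ref_desc)
  d[d < 0] <- 0
  best <- max.col(-d, ties.method = "first")
  d1 <- d[cbind(seq_len(nq), best)]
  d[cbind(seq_len(nq), best)] <- Inf
  d2 <- d[cbind(seq_len(nq), max.col(-d, ties.method = "first"))]
  data.frame(query_idx = seq_len(nq), ref_idx = best, d1_sq = d1, d2_sq = d2)
}

#' Lowe's ratio test
#'
#' Keeps a candidate when `d1_sq / d2_sq < ratio` (thresholding the squared
#' distances, the metric in which neighbours were found). A zero
#' second-nearest distance (duplicate descriptors) is rejected: the ratio is
#' undefined and such matches carry no discriminative information.
#'
#' @param candidates output of [nn_candidates()].
#' @param ratio threshold in (0, 1), default 0.6.
#' @param on_squared apply the threshold to squared distances (TRUE,
#'   default) or to their square roots.
#' @return subset of `candidates` (columns `query_idx`, `ref_idx`, `d1_sq`).
#' @export
lowe_filter <- function(candidates, ratio = 0.6, on_squared = TRUE) {
  d1 <- candidates$d1_sq; d2 <- candidates$d2_sq
  if (!on_squared) { d1 <- sqrt(d1); d2 <- sqrt(d2) }
  keep <- d2 > 0 & (d1 / d2) < ratio
  candidates[keep, c("query_idx", "ref_idx", "d1_sq"), drop = FALSE]
}

#' Unique (injective) assignment
#'
#' When several query descriptors claim the same reference descriptor, only
#' the closest pair survives, making the final correspondence one-to-one.
#'
#' @param pairs data frame with `query_idx`, `ref_idx`, `d1_sq`.
#' @return injective subset, ordered by `query_idx`.
#' @export
unique_assign <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  ord <- order(pairs$d1_sq, pairs$query_idx)
  p <- pairs[ord, , drop = FALSE]
  p <- p[!duplicated(p$ref_idx), , drop = FALSE]
  p <- p[order(p$query_idx), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' RANSAC geometric verification
#'
#' Estimates a planar projective transform (homography) from the matched
#' keypoint coordinates and returns the inlier pairs whose forward-transfer
#' reprojection error is within `params$ransac_reproj_threshold` pixels.
#' Fewer input pairs than `params$min_matches_for_geometry` — or degenerate
#' geometry that supports no homography — yield an empty set: matches that
#' cannot be geometrically verified are not counted.
#'
#' @param pairs injective pairs from [unique_assign()].
#' @param query_keypoints,ref_keypoints keypoint data frames with `x`, `y`.
#' @param params a [match_params()] object.
#' @return inlier subset of `pairs`.
#' @export
ransac_filter <- function(pairs, query_keypoints, ref_keypoints,
                          params = match_params()) {
  empty <- pairs[integer(0), , drop = FALSE]
  n <- nrow(pairs)
  if (n < params$min_matches_for_geometry) return(empty)
  src <- cbind(query_keypoints$x[pairs$query_idx],
               query_keypoints$y[pairs$query_idx])
  dst <- cbind(ref_keypoints$x[pairs$ref_idx],
               ref_keypoints$y[pairs$ref_idx])
  thr <- params$ransac_reproj_threshold
  best_inl <- logical(n)
  best_count <- 0L
  max_iter <- params$ransac_max_iters
  iter <- 0L
  needed <- max_iter
  while (iter < needed && iter < max_iter) {
    iter <- iter + 1L
    idx <- sample.int(n, 4L)
    H <- homography_minimal(src[idx, , drop = FALSE], dst[idx, , drop = FALSE])
    if (is.null(H)) next
    err <- reproj_error(H, src, dst)
    inl <- err <= thr
    cnt <- sum(inl)
    if (cnt > best_count) {
      best_count <- cnt
      best_inl <- inl
      w <- cnt / n
      needed <- if (w >= 1) 0L else
        min(max_iter,
            ceiling(log(1 - params$ransac_confidence) / log(1 - w^4)))
    }
  }
  if (best_count < params$min_matches_for_geometry) {
    if (best_count == 0L && n >= params$min_matches_for_geometry)
      warning("RANSAC found no valid model (degenerate geometry)")
    return(empty)
  }
  # one refit on the consensus set; keep it only if it does not lose inliers
  H <- homography_dlt(src[best_inl, , drop = FALSE],
                      dst[best_inl, , drop = FALSE])
  if (!is.null(H)) {
    inl2 <- reproj_error(H, src, dst) <= thr
    if (sum(inl2) >= best_count) best_inl <- inl2
  }
  out <- pairs[best_inl, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fast minimal solver: exact homography through 4 correspondences via an
# 8x8 linear solve with H[3,3] fixed at 1. Degenerate configurations
# (collinear triples) make the system singular and return NULL. Used only
# for RANSAC hypotheses; the consensus refit uses the normalised DLT.
homography_minimal <- function(src, dst) {
  x <- src[, 1]; y <- src[, 2]; u <- dst[, 1]; v <- dst[, 2]
  A <- matrix(0, 8L, 8L)
  A[1:4, ] <- cbind(x, y, 1, 0, 0, 0, -u * x, -u * y)
  A[5:8, ] <- cbind(0, 0, 0, x, y, 1, -v * x, -v * y)
  h <- tryCatch(solve(A, c(u, v)), error = function(e) NULL)
  if (is.null(h) || anyNA(h)) return(NULL)
  matrix(c(h, 1), 3L, 3L, byrow = TRUE)
}

# Normalised DLT homography from >= 4 correspondences; NULL when the system
# is degenerate (e.g. 3 collinear points in either set).
homography_dlt <- function(src, dst) {
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    md <- mean(d)
    if (md < 1e-12) return(NULL)
    s <- sqrt(2) / md
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1),
                3, 3, byrow = TRUE)
    list(T = T, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  if (is.null(ns) || is.null(nd)) return(NULL)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  n <- length(x)
  A <- matrix(0, 2L * n, 9L)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  sv <- tryCatch(svd(A, nu = 0, nv = 9L), error = function(e) NULL)
  if (is.null(sv)) return(NULL)
  # rank deficiency beyond the 1-d null space => degenerate configuration
  if (sv$d[8] < 1e-10 * sv$d[1]) return(NULL)
  Hn <- matrix(sv$v[, 9L], 3L, 3L, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  if (abs(H[3, 3]) < 1e-12) return(NULL)
  H / H[3, 3]
}

# Euclidean forward-transfer error of H applied to src against dst.
reproj_error <- function(H, src, dst) {
  w <- H[3, 1] * src[, 1] + H[3, 2] * src[, 2] + H[3, 3]
  bad <- abs(w) < 1e-12
  w[bad] <- 1
  px <- (H[1, 1] * src[, 1] + H[1, 2] * src[, 2] + H[1, 3]) / w
  py <- (H[2, 1] * src[, 1] + H[2, 2] * src[, 2] + H[2, 3]) / w
  err <- sqrt((px - dst[, 1])^2 + (py - dst[, 2])^2)
  err[bad] <- Inf
  err
}

# One matching direction: count of geometrically verified matches of A -> B.
match_direction <- function(A, B, params) {
  cand <- nn_candidates(A$descriptors, B$descriptors)
  pairs <- lowe_filter(cand, params$lowe_ratio, params$ratio_on_squared)
  pairs <- unique_assign(pairs)
  inl <- ransac_filter(pairs, A$keypoints, B$keypoints, params)
  nrow(inl)
}

#' Bidirectional similarity score between two feature sets
#'
#' Runs the matching cascade in both directions (A as query against B, then
#' B against A) and combines the verified match counts as
#' `(m_ab + m_ba) / (2 * |A|) * 100`. RANSAC is seeded per direction from
#' `seed` so repeated calls give identical scores.
#'
#' @param A query [feature_set()]; must contain at least one feature.
#' @param B reference [feature_set()].
#' @param params a [match_params()] object.
#' @param seed integer seed for the RANSAC draws.
#' @return object of class `pair_score`: list with `m_ab`, `m_ba`,
#'   `n_query`, `score_percent`.
#' @export
score_pair <- function(A, B, params = match_params(), seed = 1L) {
  stopifnot(inherits(A, "feature_set"), inherits(B, "feature_set"))
  if (A$n == 0L)
    stop("query feature set is empty: the score is undefined", call. = FALSE)
  m_ab <- with_seed(derive_seed(seed, "ab"), match_direction(A, B, params))
  m_ba <- with_seed(derive_seed(seed, "ba"), match_direction(B, A, params))
  structure(list(m_ab = m_ab, m_ba = m_ba, n_query = A$n,
                 score_percent = (m_ab + m_ba) / (2 * A$n) * 100),
            class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf("<pair_score: m_ab=%d m_ba=%d |A|=%d score=%.3f%%>\n",
              x$m_ab, x$m_ba, x$n_query, x$score_percent))
  invisible(x)
}
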