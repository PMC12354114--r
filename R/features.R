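# Keypoint detection on the nonlinear scale space and 64-d real-valued
# descriptors. Detection finds spatial maxima of the scale-normalised
# Hessian determinant per evolution level, merges them across levels by
# non-maximum suppression in base-image coordinates, refines positions to
# sub-pixel accuracy, assigns a dominant gradient orientation and samples an
# M-SURF-style 4 x 4 x (dx, dy, |dx|, |dy|) descriptor from the first
# derivatives of the diffused image at the keypoint's own scale.

#' Construct a feature set
#'
#' @param keypoints data frame with columns `x`, `y` (0-based base-image
#'   pixel coordinates), `scale`, `orientation` (radians), `response`.
#' @param descriptors numeric matrix with one row per keypoint (64 columns
#'   for KAZE-type descriptors).
#' @param source_ref opaque reference to the originating (series,
#'   slice_index), or NULL.
#' @return object of class `feature_set` with element `n`, the keypoint
#'   count.
#' @export
feature_set <- function(keypoints = empty_keypoints(),
                        descriptors = matrix(0, 0L, 64L),
                        source_ref = NULL) {
  stopifnot(is.data.frame(keypoints), is.matrix(descriptors))
  if (nrow(keypoints) != nrow(descriptors))
    stop("keypoints and descriptor rows must correspond 1:1", call. = FALSE)
  structure(list(keypoints = keypoints,
                 descriptors = descriptors,
                 n = nrow(keypoints),
                 source_ref = source_ref),
            class = "feature_set")
}

empty_keypoints <- function() {
  data.frame(x = numeric(0), y = numeric(0), scale = numeric(0),
             orientation = numeric(0), response = numeric(0))
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set: %d keypoints, %d-d descriptors>\n",
              x$n, ncol(x$descriptors)))
  invisible(x)
}

#' Detect keypoints and compute descriptors
#'
#' KAZE-style feature extraction: nonlinear diffusion scale space
#' (`octaves` x `layers_per_octave` evolution levels, conductivity
#' `diffusivity`), scale-normalised Hessian-determinant detection at
#' `detection_threshold`, and 64-dimensional real-valued descriptors
#' matched later by squared Euclidean distance. Deterministic for a fixed
#' input and parameter set.
#'
#' @param image 8-bit single-channel image matrix (values 0..255).
#' @param params an [akaze_params()] object.
#' @param source_ref optional opaque reference stored in the result.
#' @return a [feature_set()].
#' @export
extract_features <- function(image, params = akaze_params(),
                             source_ref = NULL) {
  stopifnot(inherits(params, "akaze_params"))
  if (!is.matrix(image) || length(image) == 0L)
    stop("`image` must be a non-empty matrix", call. = FALSE)
  if (min(dim(image)) < 32L) {
    warning("image smaller than the minimum pyramid size; returning an empty feature set")
    return(feature_set(source_ref = source_ref))
  }
  img <- image / 255
  levels <- build_scale_space(img, params)
  # per-level derivative maps (first and second order, Scharr)
  for (i in seq_along(levels)) {
    lv <- levels[[i]]
    lv$Lx <- scharr_x(lv$L)
    lv$Ly <- scharr_y(lv$L)
    lv$Lxx <- scharr_x(lv$Lx)
    lv$Lyy <- scharr_y(lv$Ly)
    lv$Lxy <- scharr_y(lv$Lx)
    lv$response <- (lv$Lxx * lv$Lyy - lv$Lxy^2) * lv$sigma_loc^4
    levels[[i]] <- lv
  }
  cand <- detect_candidates(levels, params$detection_threshold)
  if (nrow(cand) == 0L) return(feature_set(source_ref = source_ref))
  kp <- nms_across_levels(cand)
  kp <- refine_subpixel(kp, levels)
  if (params$upright) {
    kp$orientation <- 0
  } else {
    kp$orientation <- vapply(seq_len(nrow(kp)), function(i)
      keypoint_orientation(kp[i, ], levels[[kp$level[i]]]), 0)
  }
  desc <- compute_descriptors(kp, levels)
  keep <- rowSums(abs(desc)) > 0     # drop degenerate all-zero descriptors
  kp <- kp[keep, , drop = FALSE]
  desc <- desc[keep, , drop = FALSE]
  rownames(kp) <- NULL
  cols <- c("x", "y", "scale", "orientation", "response")
  feature_set(kp[, cols], desc, source_ref = source_ref)
}

# Spatial 8-neighbour maxima above threshold at every level; coordinates are
# reported in both level-local and base-image frames.
detect_candidates <- function(levels, threshold) {
  out <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    lv <- levels[[i]]
    R <- lv$response
    nr <- nrow(R); nc <- ncol(R)
    if (nr < 3L || nc < 3L) next
    core <- R[2:(nr - 1L), 2:(nc - 1L)]
    is_max <- core > threshold
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      is_max <- is_max & core > R[2:(nr - 1L) + dy, 2:(nc - 1L) + dx]
    }
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    yl <- idx[, 1]         # 1-based row within core => 0-based level row = yl
    xl <- idx[, 2]
    out[[i]] <- data.frame(
      level = i,
      x_loc = xl, y_loc = yl,          # 0-based level coordinates
      x = xl * lv$ratio + lv$offset,
      y = yl * lv$ratio + lv$offset,
      scale = lv$sigma_glob,
      response = core[idx])
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(level = integer(0), x_loc = numeric(0),
                      y_loc = numeric(0), x = numeric(0), y = numeric(0),
                      scale = numeric(0), response = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Greedy non-maximum suppression across all levels in base coordinates:
# strongest first; a candidate is dropped when a kept point lies within the
# larger of the two scales. Ordering ties are broken by (x, y, level) so the
# result is deterministic.
nms_across_levels <- function(cand) {
  ord <- order(-cand$response, cand$x, cand$y, cand$level)
  cand <- cand[ord, , drop = FALSE]
  n <- nrow(cand)
  keep <- logical(n)
  kx <- ky <- ks <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kx)) {
      r <- 0.5 * pmax(ks, cand$scale[i])
      d2 <- (kx - cand$x[i])^2 + (ky - cand$y[i])^2
      if (any(d2 <= r^2)) next
    }
    keep[i] <- TRUE
    kx <- c(kx, cand$x[i]); ky <- c(ky, cand$y[i]); ks <- c(ks, cand$scale[i])
  }
  cand[keep, , drop = FALSE]
}

# Sub-pixel position from a 2-D quadratic fit of the response; offsets with
# magnitude above 1 (unstable fits) are discarded, others clamped to 0.6.
refine_subpixel <- function(kp, levels) {
  for (i in seq_len(nrow(kp))) {
    lv <- levels[[kp$level[i]]]
    R <- lv$response
    x <- kp$x_loc[i]; y <- kp$y_loc[i]      # 0-based, interior by detection
    r <- y + 1L; c <- x + 1L
    gx <- (R[r, c + 1L] - R[r, c - 1L]) / 2
    gy <- (R[r + 1L, c] - R[r - 1L, c]) / 2
    hxx <- R[r, c + 1L] - 2 * R[r, c] + R[r, c - 1L]
    hyy <- R[r + 1L, c] - 2 * R[r, c] + R[r - 1L, c]
    hxy <- (R[r + 1L, c + 1L] + R[r - 1L, c - 1L] -
            R[r + 1L, c - 1L] - R[r - 1L, c + 1L]) / 4
    det <- hxx * hyy - hxy^2
    if (abs(det) < .Machine$double.eps) next
    dx <- -(hyy * gx - hxy * gy) / det
    dy <- -(hxx * gy - hxy * gx) / det
    if (abs(dx) > 1 || abs(dy) > 1) next
    dx <- max(min(dx, 0.6), -0.6)
    dy <- max(min(dy, 0.6), -0.6)
    kp$x_loc[i] <- x + dx
    kp$y_loc[i] <- y + dy
    kp$x[i] <- (x + dx) * lv$ratio + lv$offset
    kp$y[i] <- (y + dy) * lv$ratio + lv$offset
  }
  kp
}

# Dominant orientation: 36-bin gradient-direction histogram over a disc of
# radius 6 sigma, Gaussian weighted (2.5 sigma), circularly smoothed, peak
# refined by parabolic interpolation. First maximal bin wins on ties.
keypoint_orientation <- function(kp, lv) {
  s <- kp$scale / lv$ratio              # sigma in level pixels
  rad <- max(2, 6 * s)
  cx <- kp$x_loc; cy <- kp$y_loc
  nr <- nrow(lv$L); nc <- ncol(lv$L)
  xs <- max(0, floor(cx - rad)):min(nc - 1, ceiling(cx + rad))
  ys <- max(0, floor(cy - rad)):min(nr - 1, ceiling(cy + rad))
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  d2 <- (gx - cx)^2 + (gy - cy)^2
  inside <- d2 <= rad^2
  if (!any(inside)) return(0)
  gx <- gx[inside]; gy <- gy[inside]; d2 <- d2[inside]
  ii <- gy + 1L + gx * nr
  vx <- lv$Lx[ii]; vy <- lv$Ly[ii]
  mag <- sqrt(vx^2 + vy^2)
  w <- exp(-d2 / (2 * (2.5 * s)^2)) * mag
  ang <- atan2(vy, vx)                  # (-pi, pi]
  bin <- floor((ang + pi) / (2 * pi) * 36) %% 36
  hist <- vapply(0:35, function(b) sum(w[bin == b]), 0)
  for (pass in 1:2) {
    hist <- (hist[c(36, 1:35)] + hist + hist[c(2:36, 1)]) / 3
  }
  b <- which.max(hist)
  hl <- hist[if (b == 1L) 36L else b - 1L]
  hr <- hist[if (b == 36L) 1L else b + 1L]
  denom <- hl - 2 * hist[b] + hr
  off <- if (abs(denom) > .Machine$double.eps) 0.5 * (hl - hr) / denom else 0
  theta <- (b - 1 + 0.5 + max(min(off, 0.5), -0.5)) / 36 * 2 * pi - pi
  theta
}

# M-SURF-style descriptor: 20 x 20 samples at sigma spacing, rotated into
# the keypoint frame, 4 x 4 subregions of 5 x 5 samples accumulating
# (sum dx, sum dy, sum |dx|, sum |dy|) with a global Gaussian weight, then
# L2 normalisation. Vectorised over the samples of each keypoint.
compute_descriptors <- function(kp, levels) {
  n <- nrow(kp)
  desc <- matrix(0, n, 64L)
  grid <- seq(-9.5, 9.5, by = 1)                 # sample offsets in sigma units
  gu <- rep(grid, each = 20L)                     # u offsets (keypoint x axis)
  gv <- rep(grid, times = 20L)
  sub <- (floor((gu + 10) / 5)) * 4 + floor((gv + 10) / 5)   # 0..15
  wts <- exp(-(gu^2 + gv^2) / (2 * 6.6^2))
  for (i in seq_len(n)) {
    lv <- levels[[kp$level[i]]]
    s <- kp$scale[i] / lv$ratio
    th <- kp$orientation[i]
    ct <- cos(th); st <- sin(th)
    px <- kp$x_loc[i] + (ct * gu - st * gv) * s
    py <- kp$y_loc[i] + (st * gu + ct * gv) * s
    lx <- bilinear_sample(lv$Lx, px, py)
    ly <- bilinear_sample(lv$Ly, px, py)
    dx <- (ct * lx + st * ly) * wts
    dy <- (-st * lx + ct * ly) * wts
    v <- numeric(64L)
    for (b in 0:15) {
      m <- sub == b
      v[b * 4L + 1L] <- sum(dx[m])
      v[b * 4L + 2L] <- sum(dy[m])
      v[b * 4L + 3L] <- sum(abs(dx[m]))
      v[b * 4L + 4L] <- sum(abs(dy[m]))
    }
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    desc[i, ] <- v
  }
  desc
}
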