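# Shared numeric helpers. Coordinate convention used everywhere in this
# package: 0-based pixel indices, x = column, y = row, origin at top-left.
# Matrices are indexed [row, col] as usual in R, so pixel (x, y) is m[y+1, x+1].

#' Round half away from zero
#'
#' Quantisation convention used whenever images are rounded to 8 bits:
#' 0.5 -> 1, -0.5 -> -1, unlike base [round()] which rounds half to even.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape with rounded values.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Pad a matrix by edge reflection
#'
#' Reflect padding (without repeating the border sample) keeps convolutions
#' from manufacturing spurious edges at the image boundary.
#'
#' @param m numeric matrix.
#' @param k non-negative integer pad width on every side.
#' @return padded matrix of size (nrow + 2k) x (ncol + 2k).
#' @keywords internal
pad_reflect <- function(m, k) {
  if (k == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr > 0L, nc > 0L)
  ridx <- reflect_index(seq_len(nr + 2L * k) - k, nr)
  cidx <- reflect_index(seq_len(nc + 2L * k) - k, nc)
  m[ridx, cidx, drop = FALSE]
}

# Map 1-based indices possibly outside 1..n back inside by mirror reflection
# about the edges (abcb-style: index 0 -> 2, index n+1 -> n-1).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  j + 1L
}

#' 2-D convolution with reflect padding
#'
#' Direct (correlation-style with flipped kernel, i.e. true convolution is
#' not needed here: all kernels used are symmetric or explicitly oriented)
#' sliding-window filter. `kern` is applied as a correlation: the output at
#' pixel p is sum(kern * neighbourhood(p)).
#'
#' @param m numeric matrix.
#' @param kern odd-sized numeric matrix.
#' @return matrix of the same size as `m`.
#' @keywords internal
filter2_reflect <- function(m, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  pr <- (kr - 1L) %/% 2L
  pc <- (kc - 1L) %/% 2L
  p <- max(pr, pc)
  mp <- pad_reflect(m, p)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kern[i, j]
      if (w == 0) next
      out <- out + w * mp[(p - pr + i - 1L) + seq_len(nr),
                          (p - pc + j - 1L) + seq_len(nc)]
    }
  }
  out
}

#' Separable Gaussian blur with reflect padding
#'
#' @param m numeric matrix.
#' @param sigma positive standard deviation in pixels.
#' @return blurred matrix, same size.
#' @keywords internal
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq.int(-half, half)
  g <- exp(-(x^2) / (2 * sigma^2))
  g <- g / sum(g)
  row_k <- matrix(g, nrow = 1L)
  m1 <- filter2_reflect(m, row_k)           # along x (columns)
  filter2_reflect(m1, t(row_k))             # along y (rows)
}

#' Bilinear sampling of a matrix at fractional pixel coordinates
#'
#' Coordinates follow the package convention (x = column, y = row, 0-based).
#' Coordinates outside the image are clamped to the border.
#'
#' @param m numeric matrix.
#' @param x,y numeric vectors of equal length.
#' @return numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * nr
  i10 <- y1 + 1 + x0 * nr
  i01 <- y0 + 1 + x1 * nr
  i11 <- y1 + 1 + x1 * nr
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

#' Inverse-mapped affine warp of an image
#'
#' Computes out(x, y) = img(A^-1 (x, y - c) + c) with bilinear interpolation,
#' where the transform is given in forward form: rotation by `angle_deg`
#' about `center`, scaling by `scale` about `center`, then translation by
#' `tx`, `ty` (pixels). Samples falling outside the source are filled with
#' `fill`.
#'
#' @param img numeric matrix.
#' @param angle_deg rotation in degrees, counter-clockwise in the (x, y)
#'   convention with y pointing down (so visually clockwise).
#' @param scale isotropic scale factor (< 1 shrinks content).
#' @param tx,ty translation in pixels.
#' @param center length-2 (x, y) of the pivot; default image centre.
#' @param fill value for samples outside the source image.
#' @return warped matrix, same size.
#' @keywords internal
warp_affine <- function(img, angle_deg = 0, scale = 1, tx = 0, ty = 0,
                        center = NULL, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(center)) center <- c((nc - 1) / 2, (nr - 1) / 2)
  th <- angle_deg * pi / 180
  # forward: p' = s * R %*% (p - c) + c + t  => inverse mapping below
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, times = nc)
  ux <- xs - center[1] - tx
  uy <- ys - center[2] - ty
  ct <- cos(th); st <- sin(th)
  sx <- (ct * ux + st * uy) / scale + center[1]
  sy <- (-st * ux + ct * uy) / scale + center[2]
  vals <- bilinear_sample(img, sx, sy)
  outside <- sx < 0 | sx > nc - 1 | sy < 0 | sy > nr - 1
  vals[outside] <- fill
  matrix(vals, nr, nc)
}

#' Deterministic 32-bit string hash
#'
#' FNV-1a over UTF-8 bytes, reduced to a non-negative value below 2^31.
#' Used to derive reproducible per-pair RNG seeds from a global seed and
#' identifier strings; not a cryptographic hash.
#'
#' @param ... character or numeric scalars concatenated with ":".
#' @return integer in [0, 2^31 - 1].
#' @keywords internal
hash32 <- function(...) {
  s <- paste(vapply(list(...), as.character, ""), collapse = ":")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

#' Derive a child seed from a parent seed and a label
#' @keywords internal
derive_seed <- function(seed, ...) {
  as.integer((as.numeric(seed) + hash32(...)) %% (2^31 - 1))
}

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
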