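# Slice conditioning before feature detection: 8-bit min-max normalisation,
# Sobel edge enhancement with parameterised centre weight, box smoothing.
# All stages are deterministic, preserve dimensions and keep values in
# [0, 255]; convolutions use reflect padding.

#' Min-max normalisation to 8 bits
#'
#' Linear map of the input range onto \[0, 255\], rounded half away from
#' zero. A constant image maps to all zeros.
#'
#' @param pixels non-empty numeric matrix (HU or raw grayscale).
#' @return integer-valued matrix in \[0, 255\].
#' @export
normalize_8bit <- function(pixels) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  lo <- min(pixels); hi <- max(pixels)
  if (hi == lo) return(matrix(0, nrow(pixels), ncol(pixels)))
  round_half_up((pixels - lo) * (255 / (hi - lo)))
}

#' Sobel edge enhancement
#'
#' Gradient magnitude from the horizontal kernel
#' `[[-1, 0, 1], [-g, 0, g], [-1, 0, 1]]` and its transpose, combined as the
#' Euclidean magnitude, rounded and clipped to \[0, 255\]. The centre weight
#' `g` generalises the classic Sobel kernel (g = 2).
#'
#' @param image 8-bit image matrix.
#' @param g positive centre weight (default 1.8).
#' @return gradient-magnitude image in \[0, 255\].
#' @export
sobel_enhance <- function(image, g = 1.8) {
  pmin(round_half_up(sobel_magnitude(image, g)), 255)
}

# Unrounded, unclipped Euclidean Sobel gradient magnitude.
sobel_magnitude <- function(image, g) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("`image` must be a non-empty matrix", call. = FALSE)
  if (g <= 0) stop("`g` must be positive", call. = FALSE)
  # x = column axis: kernel row i, col j weights neighbour (dy=i-2, dx=j-2)
  kx <- matrix(c(-1, 0, 1,
                 -g, 0, g,
                 -1, 0, 1), nrow = 3L, byrow = TRUE)
  gx <- filter2_reflect(image, kx)
  gy <- filter2_reflect(image, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Box (averaging) filter
#'
#' k x k uniform mean with reflect padding; `k = 1` is the identity.
#'
#' @param image 8-bit image matrix.
#' @param k odd positive integer window size (default 3).
#' @return smoothed image, rounded half away from zero.
#' @export
box_smooth <- function(image, k = 3L) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("`image` must be a non-empty matrix", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L)
    stop("`k` must be an odd positive integer", call. = FALSE)
  if (k == 1L) return(image)
  kern <- matrix(1 / k^2, k, k)
  round_half_up(filter2_reflect(image, kern))
}

#' Full preprocessing of a CT slice
#'
#' Composition of [normalize_8bit()], [sobel_enhance()] (with configurable
#' blending of the gradient magnitude onto the normalised image) and
#' [box_smooth()]. With `stage_order = "normalize_last"` the normalisation
#' is instead applied after enhancement and smoothing.
#'
#' @param slice a [slice_image()] object or a plain numeric matrix.
#' @param params a [preprocess_params()] object.
#' @return 8-bit image matrix of the same dimensions as the input.
#' @export
preprocess_slice <- function(slice, params = preprocess_params()) {
  px <- if (inherits(slice, "slice_image")) slice$pixels else slice
  if (!is.matrix(px) || length(px) == 0L)
    stop("slice pixels must form a non-empty matrix", call. = FALSE)
  stopifnot(inherits(params, "preprocess_params"))

  if (params$stage_order == "normalize_first") {
    img <- normalize_8bit(px)
    mag <- sobel_enhance(img, params$sobel_gradient)
    enh <- if (params$sobel_mode == "magnitude") mag
           else pmin(round_half_up(img + params$sobel_blend * mag), 255)
    box_smooth(enh, params$averaging_size)
  } else {
    # enhancement and smoothing in the source intensity domain, 8-bit last
    mag <- sobel_magnitude(px, params$sobel_gradient)
    enh <- if (params$sobel_mode == "magnitude") mag
           else px + params$sobel_blend * mag
    kern <- matrix(1 / params$averaging_size^2,
                   params$averaging_size, params$averaging_size)
    sm <- if (params$averaging_size == 1L) enh else filter2_reflect(enh, kern)
    normalize_8bit(sm)
  }
}
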