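# Parameter containers. Defaults are the operating point reported as optimal
# for maxillary-sinus CT matching: Sobel gradient 1.8, averaging filter 3,
# octaves 4, layers 4, diffusivity PM_G2, KAZE-type descriptor, detection
# threshold 0.001, Lowe ratio 0.6, RANSAC reprojection threshold 2 px.

#' Preprocessing parameters
#'
#' Controls the slice conditioning applied before feature extraction:
#' 8-bit min-max normalisation, Sobel edge enhancement and box smoothing.
#'
#' @param sobel_gradient positive real; centre weight of the Sobel kernel
#'   (default 1.8).
#' @param averaging_size odd positive integer; side of the box filter
#'   (default 3).
#' @param sobel_blend blend weight lambda for the edge-enhanced image
#'   `clip(original + lambda * gradient_magnitude)`; ignored when
#'   `sobel_mode = "magnitude"`.
#' @param sobel_mode `"blend"` (add the gradient magnitude onto the image)
#'   or `"magnitude"` (replace the image by the gradient magnitude).
#' @param stage_order `"normalize_first"` (normalise, enhance, smooth) or
#'   `"normalize_last"` (enhance, smooth, normalise).
#' @return object of class `preprocess_params`.
#' @export
preprocess_params <- function(sobel_gradient = 1.8,
                              averaging_size = 3L,
                              sobel_blend = 1.0,
                              sobel_mode = c("blend", "magnitude"),
                              stage_order = c("normalize_first", "normalize_last")) {
  sobel_mode <- match.arg(sobel_mode)
  stage_order <- match.arg(stage_order)
  averaging_size <- as.integer(averaging_size)
  if (!is.numeric(sobel_gradient) || length(sobel_gradient) != 1L ||
      sobel_gradient <= 0)
    stop("`sobel_gradient` must be a positive scalar", call. = FALSE)
  if (averaging_size < 1L || averaging_size %% 2L == 0L)
    stop("`averaging_size` must be an odd positive integer", call. = FALSE)
  if (sobel_blend < 0)
    stop("`sobel_blend` must be non-negative", call. = FALSE)
  structure(list(sobel_gradient = sobel_gradient,
                 averaging_size = averaging_size,
                 sobel_blend = sobel_blend,
                 sobel_mode = sobel_mode,
                 stage_order = stage_order,
                 output_depth_bits = 8L),
            class = "preprocess_params")
}

#' Feature-detector parameters
#'
#' Configuration of the KAZE-style nonlinear-scale-space detector and the
#' 64-dimensional real-valued descriptor.
#'
#' @param octaves positive integer, number of octaves (default 4).
#' @param layers_per_octave positive integer, sublevels per octave
#'   (default 4).
#' @param diffusivity conductivity function of the nonlinear diffusion:
#'   one of `"PM_G1"`, `"PM_G2"`, `"WEICKERT"`, `"CHARBONNIER"`.
#' @param descriptor_type descriptor family; `"KAZE"` (64-d real-valued
#'   M-SURF-style) is the only implemented type.
#' @param detection_threshold positive real threshold on the scale-normalised
#'   Hessian response (default 0.001, for input images scaled to \[0, 1\]).
#' @param base_sigma base scale in pixels of the first evolution level.
#' @param upright logical; if TRUE skip orientation assignment (descriptors
#'   are not rotation invariant).
#' @return object of class `akaze_params`.
#' @export
akaze_params <- function(octaves = 4L,
                         layers_per_octave = 4L,
                         diffusivity = c("PM_G2", "PM_G1", "WEICKERT", "CHARBONNIER"),
                         descriptor_type = "KAZE",
                         detection_threshold = 0.001,
                         base_sigma = 1.6,
                         upright = FALSE) {
  diffusivity <- match.arg(diffusivity)
  octaves <- as.integer(octaves)
  layers_per_octave <- as.integer(layers_per_octave)
  if (octaves < 1L || layers_per_octave < 1L)
    stop("`octaves` and `layers_per_octave` must be positive integers",
         call. = FALSE)
  if (!identical(descriptor_type, "KAZE"))
    stop("only the real-valued KAZE descriptor type is implemented",
         call. = FALSE)
  if (detection_threshold <= 0)
    stop("`detection_threshold` must be positive", call. = FALSE)
  structure(list(octaves = octaves,
                 layers_per_octave = layers_per_octave,
                 diffusivity = diffusivity,
                 descriptor_type = descriptor_type,
                 detection_threshold = detection_threshold,
                 base_sigma = base_sigma,
                 upright = isTRUE(upright),
                 descriptor_length = 64L),
            class = "akaze_params")
}

#' Matching parameters
#'
#' @param lowe_ratio ratio-test threshold in (0, 1), applied to squared
#'   nearest-neighbour distances (default 0.6).
#' @param ransac_reproj_threshold inlier reprojection threshold in pixels
#'   (default 2).
#' @param min_matches_for_geometry minimum correspondences required to
#'   attempt geometric verification (default 4, the homography minimum).
#' @param ransac_max_iters cap on RANSAC hypothesis draws (default 500).
#' @param ransac_confidence target confidence for adaptive termination.
#' @param ratio_on_squared logical; apply the Lowe threshold to the squared
#'   distances as computed (TRUE, default) or to their square roots.
#' @return object of class `match_params`.
#' @export
match_params <- function(lowe_ratio = 0.6,
                         ransac_reproj_threshold = 2.0,
                         min_matches_for_geometry = 4L,
                         ransac_max_iters = 500L,
                         ransac_confidence = 0.995,
                         ratio_on_squared = TRUE) {
  if (lowe_ratio <= 0 || lowe_ratio >= 1)
    stop("`lowe_ratio` must lie in (0, 1)", call. = FALSE)
  if (ransac_reproj_threshold <= 0)
    stop("`ransac_reproj_threshold` must be positive", call. = FALSE)
  min_matches_for_geometry <- as.integer(min_matches_for_geometry)
  if (min_matches_for_geometry < 4L)
    stop("`min_matches_for_geometry` must be at least 4 (homography minimum)",
         call. = FALSE)
  structure(list(lowe_ratio = lowe_ratio,
                 ransac_reproj_threshold = ransac_reproj_threshold,
                 min_matches_for_geometry = min_matches_for_geometry,
                 ransac_max_iters = as.integer(ransac_max_iters),
                 ransac_confidence = ransac_confidence,
                 ratio_on_squared = isTRUE(ratio_on_squared)),
            class = "match_params")
}

#' Default pipeline configuration
#'
#' Bundles preprocessing, detector and matching parameters plus the query
#' slice-window span. All values can be overridden from a YAML config file.
#'
#' @param span_mm half-width in mm of the query slice window (default 7.5).
#' @return list with elements `preprocess`, `akaze`, `match`, `span_mm`.
#' @export
default_config <- function(span_mm = 7.5) {
  list(preprocess = preprocess_params(),
       akaze = akaze_params(),
       match = match_params(),
       span_mm = span_mm)
}

#' Read a pipeline configuration from a YAML file
#'
#' Missing keys fall back to the defaults of [default_config()].
#'
#' @param path YAML file with optional top-level sections `preprocess`,
#'   `akaze`, `match` and scalar `span_mm`.
#' @return configuration list as from [default_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- list(
    preprocess = do.call(preprocess_params, as_args(raw$preprocess, preprocess_params)),
    akaze = do.call(akaze_params, as_args(raw$akaze, akaze_params)),
    match = do.call(match_params, as_args(raw$match, match_params)),
    span_mm = if (!is.null(raw$span_mm)) as.numeric(raw$span_mm) else 7.5
  )
  cfg
}

#' Write a pipeline configuration to a YAML file
#'
#' @param config configuration list as from [default_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list(preprocess = unclass(config$preprocess),
              akaze = unclass(config$akaze),
              match = unclass(config$match),
              span_mm = config$span_mm)
  yaml::write_yaml(out, path)
  invisible(path)
}

# Keep only list elements that are formals of `fn`.
as_args <- function(x, fn) {
  if (is.null(x)) return(list())
  x[intersect(names(x), names(formals(fn)))]
}

#' Fingerprint of the feature-extraction configuration
#'
#' Databases record the digest of the preprocessing and detector parameters
#' used at build time; querying with a different configuration is flagged.
#'
#' @param preprocess a `preprocess_params` object.
#' @param akaze an `akaze_params` object.
#' @return character scalar digest.
#' @export
params_fingerprint <- function(preprocess, akaze) {
  digest::digest(list(preprocess = unclass(preprocess),
                      akaze = unclass(akaze)), algo = "sha256")
}
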