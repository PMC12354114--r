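# Synthetic head-CT phantoms: a skull-like elliptical annulus enclosing
# soft tissue with a low-amplitude individual texture field, plus 2-4
# individual-specific air cavities (maxillary-sinus analogues) whose
# outlines are smooth random closed curves with a per-slice area profile,
# so neighbouring slices are similar the way real sinus anatomy is.
# Perturbations emulate postmortem acquisition differences: rotation,
# translation, oversized field of view (head small in frame), noise, an
# injury mask destroying cavity structure, and partial z coverage.
# Everything is deterministic under the seeds.

HU_AIR <- -1000
HU_SOFT <- 40
HU_BONE <- 1300
HU_CAVITY <- -900

#' Perturbation parameters for postmortem-like queries
#'
#' @param rotation_deg in-plane head rotation in degrees.
#' @param translation_px length-2 (x, y) shift in pixels.
#' @param fov_scale >= 1; values above 1 shrink the head in frame,
#'   emulating a whole-body field of view.
#' @param noise_sd additive Gaussian noise standard deviation in HU.
#' @param injury optional injury mask: `TRUE` (disk over the first cavity)
#'   or `list(x =, y =, radius =)` in unperturbed pixel coordinates.
#' @param partial_coverage optional fraction (0, 1\] of the stack's z extent
#'   available to queries (measured from the top).
#' @param seed integer folded into the per-slice noise seeds.
#' @return object of class `perturbation_params`.
#' @export
perturbation_params <- function(rotation_deg = 0, translation_px = c(0, 0),
                                fov_scale = 1, noise_sd = 0, injury = NULL,
                                partial_coverage = NULL, seed = 0L) {
  if (fov_scale < 1) stop("`fov_scale` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (!is.null(partial_coverage) &&
      (partial_coverage <= 0 || partial_coverage > 1))
    stop("`partial_coverage` must be in (0, 1]", call. = FALSE)
  structure(list(rotation_deg = rotation_deg,
                 translation_px = translation_px,
                 fov_scale = fov_scale,
                 noise_sd = noise_sd,
                 injury = injury,
                 partial_coverage = partial_coverage,
                 seed = as.integer(seed)),
            class = "perturbation_params")
}

#' Generate a phantom identity
#'
#' Draws the skull ellipse, the cavity outlines (8 radial control points
#' each, interpolated periodically), per-cavity z profiles and the texture
#' seed from `identity_seed`. Distinct seeds give distinct cavity shapes
#' with probability ~ 1.
#'
#' @param identity_seed integer seed.
#' @param size image side in pixels (square slices).
#' @param n_slices slices in the identity's antemortem stack.
#' @return object of class `phantom_identity`.
#' @export
phantom_identity <- function(identity_seed, size = 160L, n_slices = 7L) {
  size <- as.integer(size); n_slices <- as.integer(n_slices)
  with_seed(derive_seed(identity_seed, "anatomy"), {
    c0 <- (size - 1) / 2
    skull <- list(
      cx = c0 + stats::runif(1, -2, 2),
      cy = c0 + stats::runif(1, -2, 2),
      a = size * stats::runif(1, 0.34, 0.38),   # x semi-axis
      b = size * stats::runif(1, 0.40, 0.44),   # y semi-axis
      rim = size * stats::runif(1, 0.025, 0.04),
      rim_hu = HU_BONE + stats::runif(1, -100, 100))
    n_cav <- sample(2:4, 1L)
    # two principal cavities sit left/right of the midline (sinus pair);
    # extras are smaller and placed above them
    cavs <- vector("list", n_cav)
    for (j in seq_len(n_cav)) {
      side <- if (j <= 2L) c(-1, 1)[j] else stats::runif(1, -0.5, 0.5)
      base_r <- size * (if (j <= 2L) stats::runif(1, 0.09, 0.13)
                        else stats::runif(1, 0.05, 0.08))
      cavs[[j]] <- list(
        cx = skull$cx + side * size * stats::runif(1, 0.12, 0.18),
        cy = skull$cy + size * (if (j <= 2L) stats::runif(1, 0.05, 0.15)
                                else stats::runif(1, -0.2, -0.08)),
        base_r = base_r,
        control = pmax(stats::rnorm(8L, 1, 0.22), 0.45),
        z_center = (n_slices - 1) / 2 + stats::runif(1, -0.15, 0.15) * n_slices,
        z_halfspan = n_slices * stats::runif(1, 0.55, 0.8))
    }
    structure(list(identity_seed = as.integer(identity_seed),
                   texture_seed = derive_seed(identity_seed, "texture"),
                   size = size, n_slices = n_slices,
                   skull = skull, cavities = cavs),
              class = "phantom_identity")
  })
}

# Periodic radial outline: control points at 8 equispaced angles,
# interpolated with a periodic spline, evaluated at `theta`.
cavity_radius <- function(cav, theta) {
  k <- length(cav$control)
  ang <- seq(0, 2 * pi, length.out = k + 1L)
  val <- c(cav$control, cav$control[1L])
  sp <- stats::spline(ang, val, method = "periodic", n = 257L)
  idx <- pmin(pmax((theta %% (2 * pi)) / (2 * pi) * 256 + 1, 1), 257)
  lo <- floor(idx); hi <- pmin(lo + 1, 257); f <- idx - lo
  r <- sp$y[lo] * (1 - f) + sp$y[hi] * f
  cav$base_r * r
}

# Smooth per-slice cavity size in [0, 1]: elliptic-ish profile of z.
cavity_profile <- function(cav, z) {
  u <- (z - cav$z_center) / cav$z_halfspan
  sqrt(pmax(0, 1 - u^2))
}

# Individual texture field (seeded white noise, blurred to ~2 px grain).
# The amplitude is large on the HU scale: it stands in for the
# high-contrast fine structure of the facial skeleton (trabecular bone,
# ethmoid air cells, teeth) that dominates the 8-bit-normalised image the
# way it does in real head CT, where the air-to-bone range compresses soft
# tissue into a few grey levels.
texture_field <- function(identity) {
  with_seed(identity$texture_seed, {
    f <- matrix(stats::rnorm(identity$size^2), identity$size, identity$size)
    gaussian_blur(f, 2) * 800
  })
}

#' Render one phantom slice
#'
#' Deterministic for fixed arguments; calling with a `NULL` perturbation is
#' identical to an all-zero [perturbation_params()].
#'
#' @param identity a [phantom_identity()].
#' @param z 0-based slice index within the identity's stack.
#' @param perturbation optional [perturbation_params()].
#' @return a [slice_image()] with HU pixel values.
#' @export
render_slice <- function(identity, z, perturbation = NULL) {
  stopifnot(inherits(identity, "phantom_identity"))
  if (z < 0 || z >= identity$n_slices)
    stop("slice index out of range for this identity", call. = FALSE)
  if (is.null(perturbation)) perturbation <- perturbation_params()
  size <- identity$size
  sk <- identity$skull
  # column-major fill: y (rows) varies fastest, so matrix(v, size, size)
  # places pixel (x, y) at [y + 1, x + 1]
  xs <- rep(seq_len(size) - 1, each = size)
  ys <- rep(seq_len(size) - 1, times = size)
  ex <- (xs - sk$cx); ey <- (ys - sk$cy)
  q_in <- (ex / sk$a)^2 + (ey / sk$b)^2
  q_out <- (ex / (sk$a + sk$rim))^2 + (ey / (sk$b + sk$rim))^2
  img <- rep(HU_AIR, size * size)
  img[q_out <= 1] <- sk$rim_hu
  inside <- q_in <= 1
  tex <- texture_field(identity)
  img[inside] <- HU_SOFT + as.vector(tex)[inside]
  for (cav in identity$cavities) {
    s <- cavity_profile(cav, z)
    if (s <= 0) next
    dx <- xs - cav$cx; dy <- ys - cav$cy
    r2 <- sqrt(dx^2 + dy^2)
    rb <- cavity_radius(cav, atan2(dy, dx)) * s
    in_cav <- inside & (r2 <= rb)
    img[in_cav] <- HU_CAVITY + 0.2 * as.vector(tex)[in_cav]
  }
  m <- matrix(img, size, size)   # [y+1, x+1] indexing via column-major (ys fast)
  # injury mask in anatomical coordinates, before any acquisition transform
  inj <- perturbation$injury
  if (!is.null(inj) && !identical(inj, FALSE)) {
    if (isTRUE(inj)) {
      cav <- identity$cavities[[1L]]
      inj <- list(x = cav$cx, y = cav$cy, radius = cav$base_r * 1.6)
    }
    d2 <- (xs - inj$x)^2 + (ys - inj$y)^2
    m[matrix(d2 <= inj$radius^2, size, size)] <- HU_SOFT
  }
  if (perturbation$rotation_deg != 0 || perturbation$fov_scale != 1 ||
      any(perturbation$translation_px != 0)) {
    m <- warp_affine(m,
                     angle_deg = perturbation$rotation_deg,
                     scale = 1 / perturbation$fov_scale,
                     tx = perturbation$translation_px[1],
                     ty = perturbation$translation_px[2],
                     fill = HU_AIR)
  }
  if (perturbation$noise_sd > 0) {
    m <- m + with_seed(
      derive_seed(identity$identity_seed, "noise", z, perturbation$seed),
      matrix(stats::rnorm(size^2, 0, perturbation$noise_sd), size, size))
  }
  slice_image(m, pixel_spacing_mm = c(1, 1), slice_thickness_mm = 2.5,
              slice_index = as.integer(z),
              series_id = sprintf("phantom-%d", identity$identity_seed))
}

#' Generate a synthetic antemortem cohort
#'
#' `n_identities` phantom identities, each with one or more antemortem
#' series rendered slice by slice, plus seeded metadata (patient ID, birth
#' date, sex, study date). Optionally written as DICOM stacks.
#'
#' @param n_identities number of identities (>= 1).
#' @param slices_per_series slices per antemortem stack.
#' @param seed global cohort seed.
#' @param size slice side in pixels.
#' @param slice_thickness_mm slice thickness recorded in the output.
#' @param out_dir optional directory; when given, each series is written as
#'   a DICOM stack under `out_dir/<patient>/<series>/`.
#' @return list with `identities` (list of [phantom_identity()]),
#'   `metadata` (data frame: patient_id, birth_date, sex, study_date),
#'   `stacks` (list of lists of [slice_image()]), and `dirs` (series
#'   directories, when written).
#' @export
generate_cohort <- function(n_identities, slices_per_series = 7L, seed = 1L,
                            size = 160L, slice_thickness_mm = 2.5,
                            out_dir = NULL) {
  if (n_identities < 1L) stop("`n_identities` must be >= 1", call. = FALSE)
  ids <- lapply(seq_len(n_identities), function(i)
    phantom_identity(derive_seed(seed, "identity", i),
                     size = size, n_slices = slices_per_series))
  meta <- with_seed(derive_seed(seed, "metadata"), data.frame(
    patient_id = sprintf("PH%03d", seq_len(n_identities)),
    birth_date = sprintf("%04d%02d%02d",
                         sample(1935:1990, n_identities, replace = TRUE),
                         sample(1:12, n_identities, replace = TRUE),
                         sample(1:28, n_identities, replace = TRUE)),
    sex = sample(c("F", "M"), n_identities, replace = TRUE),
    study_date = sprintf("%04d%02d%02d",
                         sample(2012:2020, n_identities, replace = TRUE),
                         sample(1:12, n_identities, replace = TRUE),
                         sample(1:28, n_identities, replace = TRUE))))
  stacks <- lapply(ids, function(id)
    lapply(seq_len(slices_per_series) - 1L, function(z)
      render_slice(id, z)))
  dirs <- NULL
  if (!is.null(out_dir)) {
    dirs <- character(n_identities)
    for (i in seq_len(n_identities)) {
      series_uid <- sprintf("2.25.%d.%d", abs(seed), i)
      d <- file.path(out_dir, meta$patient_id[i], "series1")
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (z in seq_len(slices_per_series) - 1L) {
        dicom_write_slice(
          file.path(d, sprintf("slice%03d.dcm", z)),
          pixels = stacks[[i]][[z + 1L]]$pixels,
          patient_id = meta$patient_id[i],
          study_date = meta$study_date[i],
          birth_date = meta$birth_date[i],
          sex = meta$sex[i],
          series_uid = series_uid,
          sop_uid = sprintf("%s.%d", series_uid, z + 1L),
          instance_number = z + 1L,
          z_position = z * slice_thickness_mm,
          slice_thickness_mm = slice_thickness_mm)
      }
      dirs[i] <- d
    }
  }
  list(identities = ids, metadata = meta, stacks = stacks, dirs = dirs)
}

#' Render a postmortem-like query stack
#'
#' Renders the slice window around `center_z` (span +/- `span_mm`) with the
#' same perturbation applied to every slice. With `partial_coverage` set,
#' indices beyond that fraction of the stack are dropped, emulating an
#' examination that covers only part of the anatomy.
#'
#' @param identity a [phantom_identity()].
#' @param center_z 0-based central slice index.
#' @param perturbation a [perturbation_params()].
#' @param slice_thickness_mm slice thickness of the query acquisition.
#' @param span_mm window half-width in mm (default 7.5).
#' @return list with `slices` (list of [slice_image()]) and `indices`
#'   (their 0-based z positions).
#' @export
generate_query <- function(identity, center_z,
                           perturbation = perturbation_params(),
                           slice_thickness_mm = 2.5, span_mm = 7.5) {
  idx <- slice_window(center_z, slice_thickness_mm, span_mm,
                      identity$n_slices)
  if (!is.null(perturbation$partial_coverage)) {
    zmax <- ceiling(identity$n_slices * perturbation$partial_coverage) - 1L
    idx <- idx[idx <= zmax]
  }
  list(slices = lapply(idx, function(z)
         render_slice(identity, z, perturbation)),
       indices = idx)
}
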