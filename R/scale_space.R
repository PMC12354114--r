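# Nonlinear diffusion scale space.
#
# The evolution L_t = div(g(|grad L_sigma|) grad L) is solved with Fast
# Explicit Diffusion (FED) cycles: a cycle of n explicit steps with varying
# step sizes tau_j covers a total time tau_max * n(n+1)/3 while remaining
# stable, so few steps are needed per scale transition. Octaves are
# downsampled by 2, which keeps the per-octave evolution times identical in
# octave-local units. The conductivity g() suppresses diffusion across
# strong edges, so cavity outlines stay sharp while homogeneous regions
# smooth out -- the property that makes KAZE-family keypoints precise.

# Conductivity functions of squared gradient magnitude, contrast k.
conductivity <- function(grad_sq, k, type) {
  ks <- k * k
  switch(type,
    PM_G1 = exp(-grad_sq / ks),
    PM_G2 = 1 / (1 + grad_sq / ks),
    WEICKERT = {
      r <- (grad_sq / ks)^4          # (|grad|/k)^8
      out <- 1 - exp(-3.315 / pmax(r, .Machine$double.eps))
      out[grad_sq == 0] <- 1
      out
    },
    CHARBONNIER = 1 / sqrt(1 + grad_sq / ks),
    stop("unknown diffusivity: ", type, call. = FALSE)
  )
}

# Contrast factor: the given percentile of the gradient-magnitude histogram
# of the sigma = 1 smoothed image (Scharr gradients, zero responses dropped).
contrast_factor <- function(img, percentile = 0.7) {
  sm <- gaussian_blur(img, 1.0)
  gx <- scharr_x(sm); gy <- scharr_y(sm)
  mag <- sqrt(gx^2 + gy^2)
  mag <- mag[mag > 0]
  if (length(mag) == 0L) return(0.03)
  k <- stats::quantile(mag, percentile, names = FALSE, type = 7)
  if (k <= 0) 0.03 else k
}

# Normalised Scharr derivative kernels: response 1 to a unit-slope ramp.
scharr_x <- function(m) {
  filter2_reflect(m, outer(c(3, 10, 3) / 16, c(-1, 0, 1) / 2))
}
scharr_y <- function(m) {
  filter2_reflect(m, outer(c(-1, 0, 1) / 2, c(3, 10, 3) / 16))
}

# One explicit diffusion step with step size tau and conductivity field c,
# no-flux (Neumann) boundaries. Vectorised over the whole image.
diffusion_step <- function(L, cfield, tau) {
  nr <- nrow(L); nc <- ncol(L)
  # shifted copies (edge replication => zero difference across the border)
  shift <- function(m, dy, dx) {
    ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  flux_xp <- (shift(cfield, 0L, 1L) + cfield) * (shift(L, 0L, 1L) - L)
  flux_xn <- (cfield + shift(cfield, 0L, -1L)) * (L - shift(L, 0L, -1L))
  flux_yp <- (shift(cfield, 1L, 0L) + cfield) * (shift(L, 1L, 0L) - L)
  flux_yn <- (cfield + shift(cfield, -1L, 0L)) * (L - shift(L, -1L, 0L))
  L + (tau / 2) * (flux_xp - flux_xn + flux_yp - flux_yn)
}

# FED step sizes for one cycle of n steps, rescaled so they sum to total_t.
fed_tau <- function(n, total_t, tau_max = 0.25) {
  j <- seq_len(n) - 1
  tau <- tau_max / (2 * cos(pi * (2 * j + 1) / (4 * n + 2))^2)
  tau * (total_t / sum(tau))
}

# Evolve L from time t_from to t_to using one FED cycle; conductivity is
# computed once at t_from from the sigma = 1 smoothed gradient.
evolve <- function(L, t_from, t_to, k, type, tau_max = 0.25) {
  total <- t_to - t_from
  if (total <= 0) return(L)
  sm <- gaussian_blur(L, 1.0)
  gx <- scharr_x(sm); gy <- scharr_y(sm)
  cfield <- conductivity(gx^2 + gy^2, k, type)
  n <- 1L
  while (tau_max * n * (n + 1) / 3 < total) n <- n + 1L
  for (tau in fed_tau(n, total, tau_max)) {
    L <- diffusion_step(L, cfield, tau)
  }
  L
}

# Downsample by 2 via 2x2 block averaging (odd trailing row/col dropped).
# A pixel (row i, col j) of the result sits at (2j + 0.5, 2i + 0.5) in the
# source, 0-based (x, y).
halfsample <- function(m) {
  nr <- 2L * (nrow(m) %/% 2L)
  nc <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  (m[seq(1L, nr, 2L), seq(1L, nc, 2L), drop = FALSE] +
   m[seq(2L, nr, 2L), seq(1L, nc, 2L), drop = FALSE] +
   m[seq(1L, nr, 2L), seq(2L, nc, 2L), drop = FALSE] +
   m[seq(2L, nr, 2L), seq(2L, nc, 2L), drop = FALSE]) / 4
}

#' Build the nonlinear scale space of an image
#'
#' @param img numeric matrix with values in \[0, 1\].
#' @param params an [akaze_params()] object.
#' @return list of evolution levels; each level carries the diffused image
#'   `L`, its octave, octave-local and global scale `sigma_loc` /
#'   `sigma_glob`, and the mapping (`ratio`, `offset`) from level to
#'   base-image pixel coordinates.
#' @keywords internal
build_scale_space <- function(img, params) {
  s0 <- params$base_sigma
  S <- params$layers_per_octave
  kcontrast <- contrast_factor(img)
  L <- gaussian_blur(img, s0)
  t_cur <- s0^2 / 2
  levels <- list()
  for (o in seq_len(params$octaves) - 1L) {
    if (o > 0L) {
      if (min(dim(L)) < 16L) break   # octave would be too small to be useful
      L <- halfsample(L)
      t_cur <- t_cur / 4
    }
    ratio <- 2^o
    offset <- (ratio - 1) / 2
    for (s in seq_len(S) - 1L) {
      sigma_loc <- s0 * 2^(s / S)
      t_target <- sigma_loc^2 / 2
      L <- evolve(L, t_cur, t_target, kcontrast, params$diffusivity)
      t_cur <- t_target
      levels[[length(levels) + 1L]] <- list(
        L = L, octave = o, sublevel = s,
        sigma_loc = sigma_loc, sigma_glob = sigma_loc * ratio,
        ratio = ratio, offset = offset)
    }
    # continue evolution to the start scale of the next octave (2 * s0
    # locally) before downsampling
    t_next <- (s0 * 2)^2 / 2
    L <- evolve(L, t_cur, t_next, kcontrast, params$diffusivity)
    t_cur <- t_next
  }
  levels
}
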