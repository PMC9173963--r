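# Synthetic phantoms realizing the multiplicative image model
# I(x, y) = S(x, y) * R(x, y): piecewise-constant "tissue" reflectance,
# smooth multiplicative illumination/bias field, additive noise.  Every
# enhancement algorithm in the package can be validated against the known
# reflectance layer.

#' Piecewise-constant tissue reflectance
#'
#' A background of constant reflectance carrying `n_structures` randomly
#' placed ellipses with distinct intensity levels.  Default ellipse
#' semi-axes span 0.6--2% of the smaller image dimension: at a typical
#' abdominal MR resolution of about 1.5 mm per pixel on a 256-pixel grid
#' this corresponds to sub-centimeter focal structures, the lesion scale the
#' enhancement pipeline is meant to preserve, and it keeps reflectance
#' detail well below the surround scales of [ssr()]/[msr()].
#'
#' @param height,width image dimensions, each at least 32.
#' @param n_structures number of ellipses (>= 1), default 8.
#' @param seed integer seed; generation is deterministic given the seed.
#' @param background background reflectance, default 0.05.
#' @param axis_range semi-axis range as a fraction of `min(height, width)`.
#' @param level_range range of ellipse reflectance levels; the levels are a
#'   shuffled equispaced grid over this range, so they are pairwise distinct.
#' @return An [rtx_image()] with reflectance values in `(0, 1]` (bit depth 8
#'   declared for display purposes; values are kept on the unit scale).
#' @export
make_reflectance <- function(height, width, n_structures = 8L, seed = 1L,
                             background = 0.05, axis_range = c(0.006, 0.02),
                             level_range = c(0.1, 1.0)) {
  if (height < 32L || width < 32L) stop("phantom must be at least 32 x 32", call. = FALSE)
  if (n_structures < 1L) stop("n_structures must be >= 1", call. = FALSE)
  R <- matrix(background, height, width)
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  msize <- min(height, width)
  withr::with_seed(seed, {
    levels <- seq(level_range[1], level_range[2], length.out = n_structures)
    if (n_structures > 1L) levels <- sample(levels)
    for (k in seq_len(n_structures)) {
      cy <- runif(1, 0.15, 0.85) * height
      cx <- runif(1, 0.15, 0.85) * width
      ay <- max(1.5, runif(1, axis_range[1], axis_range[2]) * msize)
      ax <- max(1.5, runif(1, axis_range[1], axis_range[2]) * msize)
      th <- runif(1, 0, pi)
      dy <- rows - cy; dx <- cols - cx
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      R[(u / ax)^2 + (v / ay)^2 <= 1] <- levels[k]
    }
  })
  rtx_image(R, bit_depth = 8L)
}

#' Smooth multiplicative illumination field
#'
#' Gaussian-filtered white noise rescaled to `[1 - strength, 1 + strength]`
#' and renormalized to mean 1 — a generic smooth bias field whose spatial
#' autocorrelation length is set by a single parameter.  The default
#' smoothness, half the smaller image dimension, makes the field vary over
#' the whole field of view, as coil-sensitivity bias does.
#'
#' @param height,width field dimensions.
#' @param strength modulation depth in `[0, 1)`; 0 gives a constant field.
#' @param smoothness_sigma Gaussian smoothing scale in pixels.
#' @param seed integer seed.
#' @return Matrix of strictly positive reals with mean 1 (within 1e-2).
#' @export
make_illumination <- function(height, width, strength = 0.5,
                              smoothness_sigma = min(height, width) / 2,
                              seed = 1L) {
  if (strength < 0 || strength >= 1) stop("strength must lie in [0, 1)", call. = FALSE)
  if (smoothness_sigma <= 0) stop("smoothness_sigma must be > 0", call. = FALSE)
  if (strength == 0) return(matrix(1, height, width))
  withr::with_seed(seed, {
    z <- matrix(rnorm(height * width), height, width)
  })
  k <- gaussian_surround(smoothness_sigma, ceiling(2 * smoothness_sigma))
  f <- convolve_sep(z, k$k1)
  f <- (f - min(f)) / (max(f) - min(f)) * 2 * strength + (1 - strength)
  f / mean(f)
}

#' Compose a phantom from its layers
#'
#' Forms the observed image `clip(S * R + noise, 0, 1)` and scales it to
#' display units `[0, 2^bit_depth - 1]`.  With `noise_sigma = 0` and no
#' clipping the observed image equals `S * R` exactly (up to the display
#' scale factor).  Gaussian noise is the default so the multiplicative
#' ground-truth algebra stays exact; `noise_model = "rician"` gives the
#' magnitude-image noise typical of MR at the cost of a small positive bias.
#'
#' @param reflectance [rtx_image()] or matrix on the unit scale (true R).
#' @param illumination positive matrix of the same shape (true S).
#' @param noise_sigma additive noise standard deviation on the unit scale.
#' @param bit_depth display bit depth of the observed image.
#' @param seed integer seed for the noise realization.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @return An object of class `rtx_phantom`: list with `reflectance` (matrix,
#'   unit scale), `illumination` (matrix), `observed` ([rtx_image()], display
#'   units), and `params` (including the fraction of clipped pixels).
#' @export
compose_phantom <- function(reflectance, illumination, noise_sigma = 0.005,
                            bit_depth = 8L, seed = 1L,
                            noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  R <- as_pixels(reflectance)
  S <- illumination
  if (!identical(dim(R), dim(S))) stop("layer shapes must match", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  ideal <- S * R
  if (noise_sigma > 0) {
    withr::with_seed(seed, {
      if (noise_model == "gaussian") {
        noisy <- ideal + rnorm(length(ideal), 0, noise_sigma)
      } else {
        noisy <- sqrt((ideal + rnorm(length(ideal), 0, noise_sigma))^2 +
                      rnorm(length(ideal), 0, noise_sigma)^2)
      }
    })
    dim(noisy) <- dim(ideal)
  } else {
    noisy <- ideal
  }
  clipped <- mean(noisy < 0 | noisy > 1)
  observed <- pmin(pmax(noisy, 0), 1) * (2^bit_depth - 1)
  structure(
    list(reflectance = R, illumination = S,
         observed = rtx_image(observed, bit_depth = bit_depth),
         params = list(noise_sigma = noise_sigma, noise_model = noise_model,
                       bit_depth = bit_depth, seed = seed,
                       clipped_fraction = clipped)),
    class = "rtx_phantom"
  )
}

#' One-call phantom generator
#'
#' Convenience wrapper building reflectance, illumination, and observed
#' layers from a single seed (sub-seeds are derived deterministically).
#'
#' @param size image side length (square phantom), default 256.
#' @param n_structures number of ellipses, default 8.
#' @param strength bias-field modulation depth, default 0.5.
#' @param smoothness_sigma bias smoothness in pixels, default `size / 2`.
#' @param noise_sigma additive noise on the unit scale, default 0.005.
#' @param bit_depth display bit depth, default 8.
#' @param seed integer seed.
#' @return An `rtx_phantom`, see [compose_phantom()].
#' @export
make_phantom <- function(size = 256L, n_structures = 8L, strength = 0.5,
                         smoothness_sigma = size / 2, noise_sigma = 0.005,
                         bit_depth = 8L, seed = 1L) {
  R <- make_reflectance(size, size, n_structures, seed = seed)
  S <- make_illumination(size, size, strength, smoothness_sigma, seed = seed + 1000L)
  compose_phantom(R, S, noise_sigma, bit_depth, seed = seed + 2000L)
}

#' @export
print.rtx_phantom <- function(x, ...) {
  cat(sprintf("<rtx_phantom %d x %d, noise %.4g (%s), clipped %.3g%%>\n",
              nrow(x$reflectance), ncol(x$reflectance),
              x$params$noise_sigma, x$params$noise_model,
              100 * x$params$clipped_fraction))
  invisible(x)
}
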