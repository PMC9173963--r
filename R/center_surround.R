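#' Gaussian center-surround kernel
#'
#' Builds the discrete surround function `K * exp(-(x^2 + y^2) / sigma^2)`
#' on a `(2*radius+1)^2` window, with `K` chosen so the discrete weights sum
#' to one (the discrete analogue of a unit-integral surround).  Note the
#' exponent uses `sigma^2`, not `2*sigma^2`: the scale parameter follows the
#' center-surround convention used throughout this package, so the effective
#' Gaussian standard deviation is `sigma / sqrt(2)`.
#'
#' @param sigma positive scale parameter, in pixels.
#' @param radius truncation radius in pixels; defaults to `ceiling(3 * sigma)`.
#'   Normalization is applied after truncation, so the unit-sum property holds
#'   exactly for any radius.
#' @return An object of class `rtx_kernel` with fields `weights`
#'   (the 2-D kernel), `k1` (its 1-D separable factor), `sigma`, `radius`.
#' @export
gaussian_surround <- function(sigma, radius = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  x <- (-radius):radius
  k1 <- exp(-(x^2) / sigma^2)
  k1 <- k1 / sum(k1)
  structure(
    list(weights = outer(k1, k1), k1 = k1, sigma = sigma, radius = radius),
    class = "rtx_kernel"
  )
}

#' Single-scale Retinex (SSR)
#'
#' Estimates log-reflectance as `log I - log(F * I)` where `F` is the
#' Gaussian surround and `*` is 2-D convolution with mirror (reflect)
#' padding.  The surround convolution estimates the illumination component;
#' subtracting it in the log domain discounts smooth shading and bias while
#' retaining local reflectance contrast.
#'
#' @param img single-channel [rtx_image()] or matrix (display units).
#' @param sigma surround scale in pixels; the useful range is roughly
#'   80--120 for images a few hundred pixels across, default 100.
#' @param radius kernel truncation radius, default `ceiling(3 * sigma)`.
#' @param epsilon log guard passed to [safe_log()].
#' @return Matrix of signed log-reflectance values, same shape as the input.
#' @export
ssr <- function(img, sigma = 100, radius = ceiling(3 * sigma), epsilon = 1e-6) {
  px <- as_pixels(img)
  if (length(dim(px)) != 2L) stop("ssr expects a single-channel image", call. = FALSE)
  k <- gaussian_surround(sigma, radius)
  log(px + epsilon) - log(convolve_sep(px, k$k1) + epsilon)
}

#' Multiscale Retinex (MSR)
#'
#' Weighted average of [ssr()] outputs across several surround scales,
#' combining the dynamic-range compression of large surrounds with the edge
#' rendition of small ones.  The defaults use three scales, one below 50,
#' one between 50 and 100, and one above 100 pixels, with equal weights.
#'
#' @param img single-channel [rtx_image()] or matrix.
#' @param sigmas vector of positive surround scales.
#' @param weights nonnegative weights, same length as `sigmas`, summing to 1.
#' @param epsilon log guard passed to [safe_log()].
#' @return Matrix of signed log-reflectance values.
#' @export
msr <- function(img, sigmas = c(25, 75, 150), weights = rep(1 / length(sigmas), length(sigmas)),
                epsilon = 1e-6) {
  if (length(sigmas) != length(weights)) {
    stop("sigmas and weights must have the same length", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  }
  px <- as_pixels(img)
  if (length(dim(px)) != 2L) stop("msr expects a single-channel image", call. = FALSE)
  out <- matrix(0, nrow(px), ncol(px))
  for (n in seq_along(sigmas)) {
    out <- out + weights[n] * ssr(px, sigmas[n], epsilon = epsilon)
  }
  out
}

#' Linear display stretch
#'
#' Affinely maps a log-reflectance grid onto the 8-bit display range:
#' `255 * (R - Rmin) / (Rmax - Rmin)`.  The output attains 0 and 255 exactly.
#'
#' @param R numeric matrix or array with non-degenerate range.
#' @return Grid of the same shape with values in `[0, 255]`.
#' @export
linear_stretch <- function(R) {
  R <- as_pixels(R)
  rmin <- min(R); rmax <- max(R)
  if (!is.finite(rmin) || !is.finite(rmax) || rmax <= rmin) {
    stop("degenerate range: max must exceed min before stretching", call. = FALSE)
  }
  pmin(pmax(255 * (R - rmin) / (rmax - rmin), 0), 255)
}

#' Color restoration factor
#'
#' Per-channel multiplier `C_i = beta * log(alpha_a * I_i / (I_1+I_2+I_3))`
#' that compensates the desaturation of multiscale Retinex on color images.
#' It depends only on each pixel's channel proportions, so it is invariant
#' to rescaling the input intensities.
#'
#' @param img 3-channel [rtx_image()] or array.
#' @param alpha_a gain applied to the channel proportion (default 125).
#' @param beta log gain (default 46).
#' @param epsilon guard added to channel sums and proportions.
#' @return `h x w x 3` array of restoration factors.
#' @export
color_restoration <- function(img, alpha_a = 125, beta = 46, epsilon = 1e-6) {
  if (alpha_a <= 0 || beta <= 0) stop("alpha_a and beta must be > 0", call. = FALSE)
  px <- as_pixels(img)
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) {
    stop("color_restoration expects a 3-channel image", call. = FALSE)
  }
  total <- px[, , 1] + px[, , 2] + px[, , 3] + epsilon
  out <- array(0, dim(px))
  for (i in 1:3) out[, , i] <- beta * log(alpha_a * px[, , i] / total + epsilon)
  out
}

#' Multiscale Retinex with color restoration (MSRCR)
#'
#' Per channel, multiplies the multiscale Retinex log-reflectance by the
#' color restoration factor, then maps each channel to display range with
#' [linear_stretch()].
#'
#' @param img 3-channel [rtx_image()] or array (display units).
#' @param sigmas,weights multiscale parameters as in [msr()].
#' @param alpha_a,beta color restoration parameters as in [color_restoration()].
#' @param color_restore set `FALSE` to force a unit restoration factor, which
#'   reduces the computation to per-channel [msr()] plus stretch.
#' @param epsilon log guard.
#' @return A 3-channel [rtx_image()] with intensities in `[0, 255]`.
#' @export
msrcr <- function(img, sigmas = c(25, 75, 150),
                  weights = rep(1 / length(sigmas), length(sigmas)),
                  alpha_a = 125, beta = 46, color_restore = TRUE, epsilon = 1e-6) {
  px <- as_pixels(img)
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) {
    stop("msrcr expects a 3-channel image", call. = FALSE)
  }
  C <- if (color_restore) color_restoration(px, alpha_a, beta, epsilon) else array(1, dim(px))
  out <- array(0, dim(px))
  for (i in 1:3) {
    Ri <- C[, , i] * msr(px[, , i], sigmas, weights, epsilon)
    out[, , i] <- linear_stretch(Ri)
  }
  rtx_image(out, bit_depth = 8L)
}
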