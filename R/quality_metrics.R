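#' SSIM stabilizing constants
#'
#' The small constants that keep the SSIM component ratios defined when
#' means or variances vanish: `C1 = (K1*L)^2`, `C2 = (K2*L)^2`, `C3 = C2/2`,
#' with the conventional `K1 = 0.01`, `K2 = 0.03` and dynamic range `L = 255`.
#'
#' @param K1,K2 small positive constants.
#' @param L dynamic range of the pixel values.
#' @return List with `K1`, `K2`, `L`, `C1`, `C2`, `C3`.
#' @export
ssim_constants <- function(K1 = 0.01, K2 = 0.03, L = 255) {
  C2 <- (K2 * L)^2
  list(K1 = K1, K2 = K2, L = L, C1 = (K1 * L)^2, C2 = C2, C3 = C2 / 2)
}

check_same_shape <- function(M, N) {
  if (!identical(dim(M), dim(N))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
}

#' Mean squared error
#'
#' `(1 / (e*Q)) * sum((M - N)^2)` over all pixels of two equally shaped
#' images with height `e` and width `Q`.
#'
#' @param M,N images ([rtx_image()] or matrices) of identical shape.
#' @return Nonnegative real.
#' @export
mse <- function(M, N) {
  M <- as_pixels(M); N <- as_pixels(N)
  check_same_shape(M, N)
  mean((M - N)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10((2^n - 1)^2 / MSE)` in dB for bit depth `n`; larger values
#' mean less distortion.  Identical images give `Inf`.
#'
#' @param M,N images of identical shape.
#' @param bit_depth bits per sample defining the peak intensity (default 8).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(M, N, bit_depth = 8L) {
  err <- mse(M, N)
  if (err == 0) return(Inf)
  10 * log10((2^bit_depth - 1)^2 / err)
}

#' Structural similarity (global statistics)
#'
#' Computes the luminance, contrast, and structure components from the
#' image-level means, variances (population convention), and covariance, and
#' returns their product as the SSIM score.  By default the structure term
#' uses the standard denominator `sigma_M * sigma_N + C3`, which guarantees
#' `ssim(M, M) = 1` and keeps the score within `[0, 1]` for nonnegative
#' images; `structure_denom = "as-printed"` switches to the alternative
#' `mu_M * mu_N + C3` denominator for fidelity experiments, at the cost of
#' both properties.
#'
#' A mean-pooled sliding-window variant (uniform window) is available with
#' `windowed = TRUE`; the default is the single global score.
#'
#' @param M,N single-channel images of identical shape.
#' @param consts constants from [ssim_constants()].
#' @param structure_denom `"standard"` (default) or `"as-printed"`.
#' @param windowed mean-pool SSIM over local windows instead of one global
#'   score?
#' @param window_radius half-width of the uniform window (11 x 11 default).
#' @return An object of class `rtx_quality`: list with `mse`, `psnr_db`,
#'   `ssim`, `luminance`, `contrast`, `structure`.
#' @export
ssim <- function(M, N, consts = ssim_constants(),
                 structure_denom = c("standard", "as-printed"),
                 windowed = FALSE, window_radius = 5L) {
  structure_denom <- match.arg(structure_denom)
  M <- as_pixels(M); N <- as_pixels(N)
  if (length(dim(M)) != 2L || length(dim(N)) != 2L) {
    stop("ssim expects single-channel images", call. = FALSE)
  }
  check_same_shape(M, N)
  C1 <- consts$C1; C2 <- consts$C2; C3 <- consts$C3
  if (windowed) {
    muM <- box_mean(M, window_radius); muN <- box_mean(N, window_radius)
    vM <- pmax(box_mean(M * M, window_radius) - muM^2, 0)
    vN <- pmax(box_mean(N * N, window_radius) - muN^2, 0)
    cMN <- box_mean(M * N, window_radius) - muM * muN
  } else {
    muM <- mean(M); muN <- mean(N)
    vM <- mean((M - muM)^2); vN <- mean((N - muN)^2)
    cMN <- mean((M - muM) * (N - muN))
  }
  sM <- sqrt(vM); sN <- sqrt(vN)
  l <- (2 * muM * muN + C1) / (muM^2 + muN^2 + C1)
  cc <- (2 * sM * sN + C2) / (vM + vN + C2)
  denom <- if (structure_denom == "standard") sM * sN + C3 else muM * muN + C3
  s <- (cMN + C3) / denom
  structure(
    list(mse = mse(M, N), psnr_db = psnr(M, N),
         ssim = mean(l * cc * s),
         luminance = mean(l), contrast = mean(cc), structure = mean(s)),
    class = "rtx_quality"
  )
}

#' @export
print.rtx_quality <- function(x, ...) {
  cat(sprintf("MSE %.4f | PSNR %.3f dB | SSIM %.4f (l %.4f, c %.4f, s %.4f)\n",
              x$mse, x$psnr_db, x$ssim, x$luminance, x$contrast, x$structure))
  invisible(x)
}
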