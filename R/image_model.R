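#' @importFrom stats rnorm runif
NULL

#' Image container
#'
#' An `rtx_image` holds a 2-D grid of nonnegative intensities (one matrix for
#' grayscale, an `h x w x 3` array for RGB) together with a declared bit
#' depth.  All processing is done in floating point; intensities live in
#' "display units", i.e. `[0, 2^bit_depth - 1]` for images read from or
#' destined for files.
#'
#' @param pixels numeric matrix (grayscale) or `h x w x 3` array (color).
#' @param bit_depth integer, bits per sample (default 8).
#' @return An object of class `rtx_image` with fields `pixels`, `height`,
#'   `width`, `bit_depth`, `channels`.
#' @export
rtx_image <- function(pixels, bit_depth = 8L) {
  if (is.matrix(pixels)) {
    channels <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    channels <- 3L
  } else {
    stop("pixels must be a matrix or an h x w x 3 array", call. = FALSE)
  }
  if (!all(is.finite(pixels))) stop("intensities must be finite", call. = FALSE)
  if (any(pixels < 0)) stop("intensities must be >= 0", call. = FALSE)
  d <- dim(pixels)
  if (d[1] < 2L || d[2] < 2L) stop("image must be at least 2 x 2", call. = FALSE)
  structure(
    list(pixels = pixels, height = d[1], width = d[2],
         bit_depth = as.integer(bit_depth), channels = channels),
    class = "rtx_image"
  )
}

#' @export
print.rtx_image <- function(x, ...) {
  cat(sprintf("<rtx_image %d x %d, %d channel(s), %d-bit, range [%g, %g]>\n",
              x$height, x$width, x$channels, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept an rtx_image or a bare matrix/array and return the pixel grid.
as_pixels <- function(x) {
  if (inherits(x, "rtx_image")) x$pixels else x
}

# Rec. 601 luma weights for RGB -> grayscale reduction.
rgb_to_gray <- function(arr) {
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

#' Read a raster image
#'
#' Reads PNG or TIFF (and, when the RNifti package is available, a NIfTI
#' volume, of which the middle axial slice is taken).  Samples are returned
#' in display units `[0, 2^bit_depth - 1]` with the bit depth inferred from
#' the file.  Alpha channels are dropped; RGB is kept as 3 channels unless
#' `force_gray` requests reduction to luminance.
#'
#' @param path path to the image file.
#' @param force_gray reduce a color image to luminance (Rec. 601 weights)?
#' @return An [rtx_image()].
#' @export
read_image <- function(path, force_gray = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("unreadable PNG: ", conditionMessage(e), call. = FALSE))
    bit <- attr(raw, "info")$bit.depth
    if (is.null(bit)) bit <- 8L
    px <- round(unclass(raw) * (2^bit - 1))
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) stop("unreadable TIFF: ", conditionMessage(e), call. = FALSE))
    bit <- attr(raw, "bits.per.sample")
    if (is.null(bit)) bit <- 8L
    px <- round(unclass(raw) * (2^bit - 1))
  } else if (ext %in% c("nii", "gz")) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("NIfTI support requires the RNifti package", call. = FALSE)
    }
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 3L) arr <- arr[, , ceiling(dim(arr)[3] / 2)]
    if (length(dim(arr)) != 2L) stop("unsupported NIfTI dimensionality", call. = FALSE)
    arr[arr < 0] <- 0
    bit <- 16L
    px <- arr
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  # strip alpha, keep RGB
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]
    if (dim(px)[3] == 2L) px <- px[, , 1]          # gray + alpha
    if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1]
  }
  if (length(dim(px)) == 3L && force_gray) px <- rgb_to_gray(px)
  if (is.null(dim(px)) || any(dim(px)[1:2] < 2L)) {
    stop("zero-area or degenerate image", call. = FALSE)
  }
  rtx_image(px, bit_depth = bit)
}

#' Write a raster image
#'
#' Writes an [rtx_image()] to PNG (8-bit) or TIFF (8- or 16-bit).  Intensities
#' must already lie within `[0, 2^bit_depth - 1]`; out-of-range values are an
#' error because the display mapping (see [linear_stretch()]) is the caller's
#' responsibility.  Integer-valued images round-trip losslessly.
#'
#' @param img an [rtx_image()].
#' @param path destination path; format chosen by extension (.png/.tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rtx_image"))
  peak <- 2^img$bit_depth - 1
  if (any(img$pixels < 0) || any(img$pixels > peak)) {
    stop(sprintf("intensities outside [0, %d]; stretch before writing", peak),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  scaled <- img$pixels / peak
  if (ext == "png") {
    if (img$bit_depth != 8L) {
      stop("PNG output is 8-bit; use TIFF for 16-bit images", call. = FALSE)
    }
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = img$bit_depth)
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Guarded elementwise logarithm
#'
#' Natural log of `pixels + epsilon`.  The epsilon keeps zero pixels finite;
#' because every enhancement output is a difference (or stretched affinely),
#' the base and the epsilon offset cancel out of all displayed results.
#'
#' @param img an [rtx_image()], matrix, or array.
#' @param epsilon small positive offset, in the same units as the intensities.
#' @return A grid of finite signed reals, same shape as the input.
#' @export
safe_log <- function(img, epsilon = 1e-6) {
  stopifnot(epsilon > 0)
  px <- as_pixels(img)
  log(px + epsilon)
}
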