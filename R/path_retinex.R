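# Path-based Retinex family: random-path, Frankle-McCann spiral, and
# McCann99 pyramid.  All three work on the log image and return
# log-reflectance relative to the image's brightest point (values <= 0 up to
# the threshold's effect), so outputs are invariant to rescaling the input.

#' Ratio threshold function
#'
#' The gate applied to each brightness ratio along a path.  In the
#' `"as-printed"` mode the ratio is kept when it is within `T` of unity and
#' replaced by 1 otherwise, i.e. only gradual transitions contribute.  The
#' `"classic"` mode inverts the branches (ratios near unity are replaced by
#' 1, large jumps are kept), which is the resetting rule used by classic
#' lightness algorithms to discard gradual illumination changes.
#'
#' @param x positive brightness ratio.
#' @param T threshold in (0, 1).
#' @param mode `"as-printed"` (default) or `"classic"`.
#' @return The gated ratio (vectorized over `x`).
#' @export
threshold_ratio <- function(x, T, mode = c("as-printed", "classic")) {
  mode <- match.arg(mode)
  if (any(x <= 0)) stop("ratio must be > 0", call. = FALSE)
  if (T <= 0 || T >= 1) stop("threshold T must lie in (0, 1)", call. = FALSE)
  near <- x >= 1 - T & x <= 1 + T
  if (mode == "as-printed") ifelse(near, x, 1) else ifelse(near, 1, x)
}

# Same gate expressed on log-differences: keep d when the implied ratio
# exp(d) passes, else 0 (log of the replaced unit ratio).
threshold_logdiff <- function(d, T, mode = "as-printed") {
  near <- d >= log(1 - T) & d <= log(1 + T)
  if (mode == "as-printed") ifelse(near, d, 0) else ifelse(near, 0, d)
}

#' Accumulated log-ratio along a pixel path
#'
#' Sums the thresholded log brightness ratios between successive pixels of a
#' path, giving the log-lightness of the path's end pixel relative to its
#' start pixel.
#'
#' @param img single-channel [rtx_image()] or matrix.
#' @param path integer matrix with one `(row, col)` pixel per row, at least 2.
#' @param T ratio threshold in (0, 1), default 0.1.
#' @param mode threshold mode, see [threshold_ratio()].
#' @param epsilon log guard.
#' @return A single signed real.
#' @export
path_log_ratio <- function(img, path, T = 0.1, mode = c("as-printed", "classic"),
                           epsilon = 1e-6) {
  mode <- match.arg(mode)
  px <- as_pixels(img)
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("path needs at least 2 pixels", call. = FALSE)
  if (any(path[, 1] < 1L) || any(path[, 1] > nrow(px)) ||
      any(path[, 2] < 1L) || any(path[, 2] > ncol(px))) {
    stop("path leaves image bounds", call. = FALSE)
  }
  vals <- log(px[cbind(path[, 1], path[, 2])] + epsilon)
  sum(threshold_logdiff(diff(vals), T, mode))
}

# One random monotone staircase path from `from` to `to`: the required unit
# steps in row and column direction are interleaved in random order, so the
# path is a uniformly chosen lattice staircase with fixed endpoints.
random_staircase <- function(from, to) {
  dr <- to[1] - from[1]; dc <- to[2] - from[2]
  steps <- c(rep.int(1L, abs(dr)), rep.int(2L, abs(dc)))
  if (length(steps) == 0L) return(matrix(from, nrow = 1L))
  if (length(steps) > 1L) steps <- sample(steps)
  rows <- from[1] + cumsum(ifelse(steps == 1L, sign(dr), 0L))
  cols <- from[2] + cumsum(ifelse(steps == 2L, sign(dc), 0L))
  rbind(from, cbind(rows, cols))
}

# Keep at most max_len pixels of a path, always retaining both endpoints.
thin_path <- function(path, max_len) {
  if (is.null(max_len) || nrow(path) <= max_len) return(path)
  idx <- unique(round(seq(1L, nrow(path), length.out = max_len)))
  path[idx, , drop = FALSE]
}

#' Random-path Retinex
#'
#' Estimates each pixel's log-lightness relative to the brightest pixel of
#' the image (the "white patch" reference) by averaging [path_log_ratio()]
#' over several random lattice paths from the reference to the pixel.  Paths
#' are random monotone staircases, so every path reaches its target; the
#' estimate is the arithmetic mean of the per-path log-ratios.
#'
#' @param img single-channel [rtx_image()] or matrix.
#' @param threshold_T ratio threshold in (0, 1), default 0.1.
#' @param n_paths number of random paths per pixel, default 8.
#' @param path_length optional cap on pixels retained per path (paths longer
#'   than this are thinned, keeping both endpoints); `NULL` means no cap.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param mode threshold mode, see [threshold_ratio()].
#' @param epsilon log guard.
#' @return Matrix of signed log-reflectance values, same shape as the input.
#' @export
random_path_retinex <- function(img, threshold_T = 0.1, n_paths = 8L,
                                path_length = NULL, seed = 1L,
                                mode = c("as-printed", "classic"), epsilon = 1e-6) {
  mode <- match.arg(mode)
  if (n_paths < 1L) stop("n_paths must be >= 1", call. = FALSE)
  if (!is.null(path_length) && path_length < 2L) {
    stop("path_length must be >= 2", call. = FALSE)
  }
  px <- as_pixels(img)
  if (length(dim(px)) != 2L) {
    stop("random_path_retinex expects a single-channel image", call. = FALSE)
  }
  h <- nrow(px); w <- ncol(px)
  lg <- log(px + epsilon)
  start <- arrayInd(which.max(px), dim(px))[1, ]
  out <- matrix(0, h, w)
  withr::with_seed(seed, {
    for (j in seq_len(w)) {
      for (i in seq_len(h)) {
        acc <- 0
        for (p in seq_len(n_paths)) {
          pt <- thin_path(random_staircase(start, c(i, j)), path_length)
          if (nrow(pt) < 2L) next  # target is the reference pixel itself
          vals <- lg[cbind(pt[, 1], pt[, 2])]
          acc <- acc + sum(threshold_logdiff(diff(vals), threshold_T, mode))
        }
        out[i, j] <- acc / n_paths
      }
    }
  })
  out
}

#' Initial spiral offset
#'
#' The starting comparison distance of the Frankle-McCann spiral:
#' `2^(floor(log2(min(rows, cols))) - 1)`, i.e. half the largest power of two
#' not exceeding the smaller image dimension, so every subsequent halving
#' stays an integer pixel offset.
#'
#' @param rows,cols image dimensions, both at least 2.
#' @return A positive integer offset.
#' @export
conversion_operator <- function(rows, cols) {
  if (rows < 2 || cols < 2) stop("image dimensions must be >= 2", call. = FALSE)
  2^(floor(log2(min(rows, cols))) - 1)
}

# Offset schedule of the spiral: start at (D, 0), rotate 90 degrees
# clockwise and halve the distance after each comparison, stop when the
# distance drops below one pixel.
spiral_offsets <- function(d0) {
  dirs <- matrix(c(1L, 0L, 0L, -1L, -1L, 0L, 0L, 1L), ncol = 2, byrow = TRUE)
  d <- d0; k <- 0L; out <- NULL
  while (abs(d) >= 1) {
    out <- rbind(out, dirs[k %% 4L + 1L, ] * as.integer(round(d)))
    d <- d / 2
    k <- k + 1L
  }
  out
}

# Shift matrix by (dr, dc); cells whose source falls outside the image are NA.
shift_na <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(NA_real_, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  ok_r <- rs >= 1L & rs <= h; ok_c <- cs >= 1L & cs <= w
  out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
  out
}

#' Frankle-McCann spiral Retinex
#'
#' Long-distance lightness propagation along a spiral of comparisons: the
#' estimate is initialized to the log image, then repeatedly updated by the
#' ratio-product / reset / average cycle against a copy of itself shifted by
#' an offset that rotates 90 degrees clockwise and halves after each step,
#' until the offset falls below one pixel.  The reset step clamps candidate
#' estimates at the log of the image maximum.  The returned log-reflectance
#' is expressed relative to that maximum, so constant images map to zero and
#' rescaling the input leaves the output unchanged.
#'
#' @param img single-channel [rtx_image()] or matrix.
#' @param iterations_per_offset comparisons performed at each offset, default 1.
#' @param epsilon log guard.
#' @return Matrix of log-reflectance values (<= 0), same shape as the input.
#' @export
frankle_mccann <- function(img, iterations_per_offset = 1L, epsilon = 1e-6) {
  px <- as_pixels(img)
  if (length(dim(px)) != 2L) {
    stop("frankle_mccann expects a single-channel image", call. = FALSE)
  }
  lg <- log(px + epsilon)
  maxl <- max(lg)
  r <- lg
  offs <- spiral_offsets(conversion_operator(nrow(px), ncol(px)))
  for (k in seq_len(nrow(offs))) {
    for (it in seq_len(iterations_per_offset)) {
      r_sh <- shift_na(r, offs[k, 1], offs[k, 2])
      l_sh <- shift_na(lg, offs[k, 1], offs[k, 2])
      cand <- r_sh + (lg - l_sh)              # ratio/product in log domain
      na <- is.na(cand)
      cand[na] <- r[na]                       # no partner outside the image
      cand <- pmin(cand, maxl)                # reset
      r <- (r + cand) / 2                     # average
    }
  }
  r - maxl
}

# 2x2 block mean; odd dimensions are padded by edge replication first.
pyramid_reduce <- function(x) {
  h <- nrow(x); w <- ncol(x)
  if (h %% 2L == 1L) x <- rbind(x, x[h, , drop = FALSE])
  if (w %% 2L == 1L) x <- cbind(x, x[, ncol(x), drop = FALSE])
  h2 <- nrow(x) / 2L; w2 <- ncol(x) / 2L
  0.25 * (x[2 * seq_len(h2) - 1L, 2 * seq_len(w2) - 1L, drop = FALSE] +
          x[2 * seq_len(h2) - 1L, 2 * seq_len(w2),      drop = FALSE] +
          x[2 * seq_len(h2),      2 * seq_len(w2) - 1L, drop = FALSE] +
          x[2 * seq_len(h2),      2 * seq_len(w2),      drop = FALSE])
}

# Nearest-neighbor duplication to the target size (each coarse pixel becomes
# a 2x2 block, then crop), preserving the clamp invariant exactly.
pyramid_expand <- function(x, target_h, target_w) {
  up <- x %x% matrix(1, 2, 2)
  up[seq_len(target_h), seq_len(target_w), drop = FALSE]
}

#' McCann99 pyramid Retinex
#'
#' Multiresolution lightness estimation: a pyramid of 2x2 block means of the
#' log image is built, and from the coarsest level down the estimate is
#' iteratively updated against all 8 neighbors of each pixel (candidate =
#' neighbor estimate plus the log brightness difference, clamped at the log
#' image maximum, averaged with the current estimate), then duplicated up to
#' the next finer level.  Output is relative to the log maximum, as in
#' [frankle_mccann()].
#'
#' @param img single-channel [rtx_image()] or matrix, at least 4 x 4.
#' @param iterations_per_level update sweeps per pyramid level, default 4.
#' @param n_levels number of pyramid levels, or `"auto"` (halve until the
#'   coarsest level is about 2 pixels across).
#' @param epsilon log guard.
#' @return Matrix of log-reflectance values, same shape as the input.
#' @export
mccann99 <- function(img, iterations_per_level = 4L, n_levels = "auto",
                     epsilon = 1e-6) {
  px <- as_pixels(img)
  if (length(dim(px)) != 2L) stop("mccann99 expects a single-channel image", call. = FALSE)
  if (nrow(px) < 4L || ncol(px) < 4L) stop("image must be at least 4 x 4", call. = FALSE)
  if (iterations_per_level < 1L) stop("iterations_per_level must be >= 1", call. = FALSE)
  lg <- log(px + epsilon)
  maxl <- max(lg)
  if (identical(n_levels, "auto")) {
    n_levels <- max(2L, floor(log2(min(dim(px)))))
  }
  pyr <- list(lg)
  for (lev in seq_len(n_levels - 1L)) pyr[[lev + 1L]] <- pyramid_reduce(pyr[[lev]])
  nbrs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  nbrs <- nbrs[!(nbrs[, 1] == 0L & nbrs[, 2] == 0L), , drop = FALSE]
  r <- pyr[[n_levels]]
  for (lev in rev(seq_len(n_levels))) {
    s <- pyr[[lev]]
    if (lev < n_levels) r <- pyramid_expand(r, nrow(s), ncol(s))
    for (it in seq_len(iterations_per_level)) {
      for (k in seq_len(nrow(nbrs))) {
        r_sh <- shift_na(r, nbrs[k, 1], nbrs[k, 2])
        s_sh <- shift_na(s, nbrs[k, 1], nbrs[k, 2])
        cand <- r_sh + (s - s_sh)
        na <- is.na(cand)
        cand[na] <- r[na]
        cand <- pmin(cand, maxl)
        r <- (r + cand) / 2
      }
    }
  }
  r - maxl
}
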