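# Internal separable convolution with mirror (reflect) boundary handling.
#
# The surround kernel exp(-(x^2+y^2)/sigma^2) factorizes as the outer product
# of two 1-D kernels, and its discrete normalization factorizes with it, so
# ssr/msr convolutions run as two banded matrix products instead of a full
# 2-D convolution.  Tests check this path against a direct O(n^2 k^2)
# spatial convolution.

# Fold arbitrary integer indices into 1..n by boundary reflection
# (period 2n - 2), so padding wider than the image stays well defined.
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  as.integer(ifelse(j < n, j + 1L, p - j + 1L))
}

# Banded convolution matrix mapping a mirror-padded axis of length
# n + 2*radius down to length n with 1-D kernel k1 (length 2*radius + 1).
band_matrix <- function(n, k1) {
  radius <- (length(k1) - 1L) / 2L
  A <- matrix(0, n, n + 2L * radius)
  for (i in seq_len(n)) A[i, i:(i + 2L * radius)] <- k1
  A
}

# Separable convolution of matrix x with the normalized 2-D kernel
# outer(k1, k1), mirror padding.
convolve_sep <- function(x, k1) {
  radius <- (length(k1) - 1L) / 2L
  h <- nrow(x); w <- ncol(x)
  P <- x[mirror_index(seq.int(1L - radius, h + radius), h),
         mirror_index(seq.int(1L - radius, w + radius), w), drop = FALSE]
  band_matrix(h, k1) %*% P %*% t(band_matrix(w, k1))
}

# Uniform box mean over a (2*radius+1)^2 window, mirror padding.
box_mean <- function(x, radius) {
  k1 <- rep(1 / (2 * radius + 1), 2 * radius + 1)
  convolve_sep(x, k1)
}
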