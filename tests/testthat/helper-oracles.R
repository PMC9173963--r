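# Independent oracles used to cross-check production code paths.
# These deliberately use naive algorithms (loops, closed forms, full
# enumeration) and share no code with the package internals.

# Mirror (reflect) index fold, written independently via a lookup table.
oracle_mirror <- function(i, n) {
  period <- c(seq_len(n), rev(seq_len(n))[c(-1, -n)])
  period[(i - 1) %% (2 * n - 2) + 1]
}

# Direct O(n^2 k^2) spatial convolution with a full 2-D kernel and mirror
# boundary handling.
direct_conv2d <- function(x, weights) {
  radius <- (nrow(weights) - 1) / 2
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (u in -radius:radius) {
        for (v in -radius:radius) {
          acc <- acc + weights[u + radius + 1, v + radius + 1] *
            x[oracle_mirror(i + u, h), oracle_mirror(j + v, w)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# The normalized surround kernel recomputed from its definition.
oracle_surround <- function(sigma, radius) {
  g <- outer(-radius:radius, -radius:radius,
             function(x, y) exp(-(x^2 + y^2) / sigma^2))
  g / sum(g)
}

# SSIM components from first principles: explicit sums, population moments.
oracle_ssim <- function(M, N, K1 = 0.01, K2 = 0.03, L = 255) {
  n <- length(M)
  muM <- sum(M) / n; muN <- sum(N) / n
  vM <- sum((M - muM)^2) / n; vN <- sum((N - muN)^2) / n
  cMN <- sum((M - muM) * (N - muN)) / n
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2; C3 <- C2 / 2
  l <- (2 * muM * muN + C1) / (muM^2 + muN^2 + C1)
  cc <- (2 * sqrt(vM) * sqrt(vN) + C2) / (vM + vN + C2)
  s <- (cMN + C3) / (sqrt(vM) * sqrt(vN) + C3)
  list(luminance = l, contrast = cc, structure = s, ssim = l * cc * s)
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration over the feasible top-left cell values.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small random image in display units, reproducible.
rand_img <- function(h, w, seed, peak = 255) {
  withr::with_seed(seed, matrix(runif(h * w, 0, peak), h, w))
}
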