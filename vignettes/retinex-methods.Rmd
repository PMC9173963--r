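---
title: "Retinex enhancement of bias-corrupted images: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinex enhancement of bias-corrupted images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinexmed)
```

## The illumination–reflectance model

All algorithms in this package assume the multiplicative image model

$$I(x,y) = S(x,y) \cdot R(x,y),$$

where $S$ is a slowly varying, strictly positive illumination (for MR, the
bias field) and $R$ is the reflectance that carries tissue structure. The
model's key consequence is that in the log domain the corruption is
*additive and smooth*: $\log I = \log S + \log R$. Every enhancement
operator here works in that log domain and returns a signed
*log-reflectance* grid; conversion to display integers happens only at the
end, through the affine stretch `linear_stretch()` (which maps the observed
range onto $[0,255]$ exactly).

Two conventions apply throughout and are worth stating once:

- **Natural log everywhere.** Only differences of logs reach any output, and
  an affine display stretch follows, so the base is unobservable.
- **Zero pixels** are guarded by a single global epsilon (default `1e-6` in
  display units) inside `safe_log()`; the epsilon is small enough that
  scale-invariance of the operators holds to ~1e-8 for realistic intensity
  ranges.

## Path-based operators

**Random-path** lightness compares each pixel to a bright reference (the
global maximum — the "white patch") through products of brightness ratios
along paths, thresholded so that only ratios within $T$ of unity
contribute (default $T = 0.1$). The default gate keeps *near-unity* ratios
and discards jumps; the `"classic"` switch inverts the branches, which is
the resetting rule of classic lightness estimation (discard gradual
illumination changes, keep edges). Both are exposed because they answer
different questions; the default follows the convention of the rest of the
package's path family.

Where the design was genuinely open was the *path distribution*: a free
lattice random walk truncated at a fixed length almost never terminates at
the target pixel, which the operator's contract requires. We use random
monotone staircase paths — the required row and column unit steps in a
uniformly shuffled order — which are exactly the lattice paths between the
two endpoints of minimal length, sampled uniformly. An optional
`path_length` cap thins long paths while keeping both endpoints; ratios
between non-adjacent retained pixels remain well defined. Estimates from
`n_paths` paths (default 8) are combined by the arithmetic mean of the
per-path log-ratios, and the whole operator is bit-reproducible given its
seed.

**Frankle–McCann** propagates lightness along a spiral: the estimate starts
at the log image, and at each step a shifted copy proposes
`candidate = r(shifted) + (log I − log I(shifted))`, which is clamped at the
log image maximum (the *reset*) and averaged with the current estimate. The
initial offset is $D = 2^{\lfloor \log_2 \min(h,w)\rfloor - 1}$ — the floor
makes $D$ an integer for non-power-of-two images — and after each
comparison the offset rotates 90° clockwise and halves, stopping when it
falls below one pixel (a 256×256 image therefore makes 8 comparisons:
offsets 128, 64, …, 1). Pixels whose comparison partner falls outside the
image keep their current estimate for that step.

**McCann99** replaces the spiral with a pyramid: 2×2 block means of the log
image down to a ~2-pixel coarsest level, then, from coarse to fine, the
same propose/clamp/average cycle against all 8 neighbors of each pixel
(several sweeps per level, default 4), followed by nearest-neighbor
duplication to the next finer level. Duplication (rather than smooth
interpolation) is deliberate: it preserves the clamp invariant exactly.
Odd-sized levels are padded by edge replication before reduction and
cropped after expansion.

Both estimators return log-reflectance **relative to the log image
maximum**. That normalization is what makes two properties exact: constant
images map to constant (zero) output, and scaling the input by any $k > 0$
leaves the output unchanged.

## Center-surround operators

`ssr` computes $\log I - \log(F \ast I)$ with the Gaussian surround

$$F(x,y) = K \exp\!\left(-\frac{x^2+y^2}{\sigma^2}\right),
\qquad \textstyle\sum F = 1 .$$

Note the exponent has no factor 2 — $\sigma$ here equals $\sqrt 2$ times
the usual Gaussian standard deviation. The kernel is truncated at radius
$\lceil 3\sigma \rceil$ and renormalized after truncation, so the unit-sum
property holds exactly at any radius. Convolution uses mirror (reflect)
padding — with zero padding the surround would collapse near borders and
paint dark halos into the log difference. Because the kernel separates into
an outer product of 1-D factors, the production path runs as two banded
matrix products; the test suite checks it against a direct $O(n^2k^2)$
spatial convolution at 1e-8 (observed agreement ~1e-12).

Defaults: $\sigma = 100$ for `ssr` (the middle of the commonly cited
80–120 range for images a few hundred pixels across); `msr` uses
$\sigma = (25, 75, 150)$ with equal weights $1/3$ — one scale below 50, one
between 50 and 100, one above 100 — trading halo suppression (large
surrounds) against local contrast (small ones). `msrcr` multiplies each
RGB channel's `msr` output by the color-restoration factor
$C_i = \beta \log(\alpha I_i / \sum_j I_j)$ with $\alpha = 125$,
$\beta = 46$ (the values in widespread use; both exposed), then stretches
each channel independently. Grayscale enhancement never routes through the
color path.

## Quality metrics

`mse`, `psnr` ($10\log_{10}((2^n-1)^2/\mathrm{MSE})$, bit depth $n$
declared, default 8, `Inf` on identical inputs — larger PSNR always means
*less* distortion), and a **global-moment SSIM**: luminance, contrast, and
structure terms computed from whole-image means, population variances, and
covariance, multiplied together. The structure term's denominator is
$\sigma_M\sigma_N + C_3$; that choice (rather than $\mu_M\mu_N + C_3$) is
what guarantees $\mathrm{SSIM}(M,M) = 1$ and keeps the score in $[0,1]$ for
structurally related images, and an `"as-printed"` switch to the
$\mu$-denominator exists for fidelity experiments. A mean-pooled
11×11-window variant is available behind `windowed = TRUE`; the global
score is the default because the component definitions are written with
image-level moments. One caution the tests encode: for *uncorrelated* image
pairs the sample covariance can be negative, so the product can dip
slightly below 0 — the guaranteed bound is $[-1, 1]$.

## The phantom generator and what it validates

`make_phantom()` realizes the model the algorithms assume:

- **Reflectance**: constant background 0.05 carrying 8 ellipses with
  distinct levels on an equispaced grid over $[0.1, 1]$. Ellipse semi-axes
  default to 0.6–2% of the image side. That scale is chosen to match the
  focal lesions such enhancement pipelines are meant to preserve —
  sub-centimeter structures are a handful of pixels at a typical ~1.5 mm
  in-plane resolution on a 256-pixel abdominal field of view — and it
  respects the center-surround working assumption that reflectance detail
  is *finer* than the surround scale. With organ-scale structures
  (tens of percent of the image) that assumption fails and center-surround
  halos dominate; the generator is deliberately parameterized in the regime
  the method is designed for, and `axis_range` is exposed for studying the
  failure regime.
- **Illumination**: Gaussian-filtered white noise affinely mapped to
  $[1-s, 1+s]$ (default strength $s = 0.5$) and renormalized to mean 1.
  Smoothness is a single parameter (Gaussian scale, default half the image
  side — coil bias varies over the whole field of view).
- **Observed**: $\mathrm{clip}(S\cdot R + \varepsilon, 0, 1)$ scaled to
  display units, with additive Gaussian noise (default SD 0.005) so the
  multiplicative ground-truth algebra stays exact; a Rician option exists
  for magnitude-image realism at the cost of a small positive bias. The
  clipped-pixel fraction is recorded so tests can demand clip-free
  conditions; note that a 1.5× bias peak over a level-1.0 lesion *does*
  saturate, which is realistic and accounted for.

**Recovery scoring.** Retinex returns reflectance up to a multiplicative
constant, so `recovery_scores()` aligns each candidate (the observed image,
and the exponentiated log-reflectance estimate) to the true reflectance by
the least-squares scale factor, clips to display range, and then computes
PSNR and SSIM. On the default phantom conditions (256×256, strength 0.5,
noise 0.005), SSR at $\sigma = 100$ and MSR at the default scales raise
SSIM against the truth in essentially every seeded replicate; the test
suite requires ≥ 90% of 20 replicates and `scripts/acceptance.R` reports
the measured win rates.

What passing these tests does **not** show: the phantom is piecewise
constant with sharp boundaries and a stationary random bias — real MR
slices have texture, partial-volume gradients, anatomy-correlated shading,
and spatially varying noise. The phantom validates that the operators
remove what they model (smooth multiplicative corruption) without
destroying what they must keep (focal structure); it is not evidence about
diagnostic performance on patient images.

## Clinical statistics

The evaluation statistics around such an imaging study are routine and are
delegated to R's own implementations behind a stable interface:
`chi_square_homogeneity()` (Pearson, no continuity correction — none is
conventional for r×c homogeneity), `fisher_exact_2x2()` (exact two-sided,
for the small-count tables where χ² expectations fail), `welch_t()`, and
`diagnostic_performance()` (sensitivity/specificity/accuracy in percent, to
two decimals, rounding half away from zero — the convention of printed
clinical tables, unlike R's default banker rounding).

`counts_from_percentages()` inverts printed percentage tables: it searches
all integer compositions of the group size whose two-decimal rounded
percentages reproduce the printed values and insists the solution is
unique, so a recovered table is exact, not approximate. This is how the
package regenerates analyzable integer tables from published summaries.

## Numerical choices, sizes, and limitations

- Test and acceptance problem sizes: invariants run on 12–32 pixel images
  (path operators are O(pixels × paths × path length) in pure R and are
  meant for small inputs or patch studies); recovery runs on 20 phantoms at
  256×256, a few seconds in total. The whole suite runs in ~20 s.
- Degenerate inputs have defined outcomes: constant images are rejected by
  `linear_stretch` (zero denominator), sub-4×4 inputs by `mccann99`,
  non-positive ratios by the threshold function, empty margins by
  `diagnostic_performance`, zero expected counts by the χ² test.
- Ties and floating point: `linear_stretch` clamps to $[0,255]$ after the
  affine map (bare arithmetic can overshoot by ~3e-14); scale-invariance
  holds to ~1e-8 (epsilon in the log guard), and seeded operators are
  bit-reproducible.
- Known limitations: no 3-D enhancement, no DICOM metadata handling (NIfTI
  slices are read when `RNifti` is installed), no sliding-window SSIM as
  default, and the path operators' R-level loops make them impractical
  above a few thousand pixels.
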