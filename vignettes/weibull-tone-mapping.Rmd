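---
title: "Weibull tone mapping: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weibull tone mapping: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtm)
```

## The problem

Artificially lit seafloor photographs have characteristic brightness
structure: a bright central light cone falling off into a dark periphery.
Their histograms are far from uniform, so plain histogram equalisation (HE)
produces harsh, unnatural renderings, while hand-crafted control-point tone
curves are slow to make at survey scale (thousands of images). Weibull tone
mapping replaces both with a two-parameter adjustment: represent the
brightness histogram by its closest Weibull density, pick a target Weibull,
and apply the monotone curve that maps one onto the other.

## Brightness, tone curves and colour reconstruction

Brightness is the per-pixel channel maximum (the HSV value channel),
`extract_brightness()`. This choice matters: after remapping brightness
from `L_in` to `L_out`, colour is rebuilt by scaling each pixel's RGB
triplet by `L_out / L_in` (`reconstruct_color()`). Because `L_in` is the
channel maximum and `L_out <= 1`, no channel can exceed 1, and chromatic
ratios are preserved exactly. Pixels with `L_in = 0` stay black; the
continuous model assumes brightness in (0, 1], but real 8-bit images contain
true zeros, which we also fold into the first histogram bin rather than
dropping them.

Histograms use `N = 256` half-open bins `((j-1)/N, j/N]` and are normalised
to sum to 1 (`compute_pdf()`). A tone curve is a monotone non-decreasing
vector of 256 output values, entry `j` being the output for input `j/N`.
Between nodes, `apply_tonecurve()` interpolates linearly with an implied
anchor at (0, 0) — the sampled definition says nothing about values between
nodes, and linear interpolation avoids banding without overshoot. The HE
curve is simply the cumulative histogram; its slope at node `j` is exactly
`N * h_j` (`curve_slopes()`), which the tests exploit as an identity.

## The Weibull proxy

The two-parameter Weibull density has scale `lambda` (peak position — a
brightness proxy) and shape `k` (spread — an inverse contrast proxy: lower
`k` means a flatter, wider histogram and a higher-contrast image). On the
natural axis the density extends to infinity, but for the parameter ranges
of interest there is negligible mass beyond 2.55, so the distribution is
truncated there and the axis divided by 2.55 to land on [0, 1]. After
truncation the retained mass `Z = 1 - exp(-(2.55/lambda)^k)` can be
noticeably below 1 for large `lambda`; we renormalise by `Z` so the proxy is
a proper distribution. (Whether to renormalise is a genuinely open choice —
without it the proxy CDF would not reach 1 at `b = 1` and the tone-curve
composition below would be ill-posed, so we renormalise.)

Discrete proxy masses are CDF differences at the bin edges
(`weibull_pdf_discrete()`), not midpoint density evaluations: this makes the
cumulative of the discrete proxy agree with the continuous CDF exactly at
every bin edge, so histogram-space and CDF-space computations never drift
apart.

## Fitting by KL grid search

`fit_weibull()` minimises the Kullback–Leibler divergence
`sum(h * log(h / h_W))` over the exhaustive grid
`lambda in {0.1, ..., 3}`, `k in {0.1, ..., 15}` (step 0.1, 4500 pairs).
Zero is excluded from both ranges because the density is undefined there.
Conventions: observed zero bins contribute nothing (`0 log 0 = 0`); proxy
bins are floored at 1e-12 and renormalised so numerically empty tails cannot
produce infinities; natural log (the argmin is base-invariant). Ties are
broken by the smallest `lambda`, then the smallest `k` — determinism over
elegance. The 4500 log-proxy columns are cached per bin count, so a fit is a
single matrix–vector product (~6 ms) after the first call. No off-grid
refinement is attempted: the grid resolution of 0.1 *is* the parameter
resolution of the method, and "within one grid step" is the accuracy claim
tests assert.

## Composing the tone curve

The WTM curve is `t = t_out^-1(t_in(b))` sampled at the 256 node abscissae.
Algebraically we evaluate it in the Weibull exponent domain: writing
`u = (2.55 b / lambda_in)^k_in` and `s_trunc` for the survival at the
truncation point, matching the renormalised CDFs gives

    exp(-v) = s_out + (Z_out / Z_in) * (exp(-u) - s_in),
    t(b)    = lambda_out * v^(1/k_out) / 2.55.

This is not a numerical nicety but a correctness requirement: for sharply
peaked proxies (say `lambda = 0.1, k = 15`) the CDF saturates to 1 in double
precision long before `b = 1`, so composing through probabilities collapses
the whole upper tone range (the self-map would deviate from the identity by
0.9). In the exponent domain every term of `exp(-v)` is non-negative (no
cancellation), and when the two truncation survivals coincide the self-map
reduces to `v = u` — the identity — for *any* parameters. A `cummax` guard
absorbs last-ulp rounding wobble.

`wtm_enhance()` fits the input proxy and maps it to a user target;
`wtm_approximate()` fits proxies to an input/output image pair and applies
the map between them, which is how arbitrary manual adjustments are reduced
to their closest WTM.

## CLHE baseline

Contrast-limited HE seeks a proxy histogram close to `h` whose cumulative
has slopes in `[m, M]` (defaults 0.5 and 2). "Close" is usually left vague;
the classic implementation iterates clip-and-redistribute, which empirically
behaves like a least-squares fit. We implement the least-squares
characterisation exactly: `clhe_proxy()` is the Euclidean projection of `h`
onto `{h' : m/N <= h'_j <= M/N, sum(h') = 1}`, computed by water-filling —
the projection has the form `clamp(h + tau, m/N, M/N)` for a unique mass
shift `tau` found by bisection, after which the unclamped bins are polished
to restore unit mass exactly. The projection is deterministic, idempotent,
and verified in tests against Dykstra's alternating projections at small N.
Feasibility requires `m <= 1 <= M`; anything else is rejected.

## Control-point curves

Manual adjustments use 6 control points with abscissae fixed at
`{0, 0.2, ..., 1}`; only strictly increasing ordinate configurations are
accepted — non-monotone input is an error, never silently sorted.
`pchip_tonecurve()` interpolates with a monotone piecewise-cubic Hermite
polynomial: interior derivatives are the Fritsch–Carlson-style weighted
harmonic mean of neighbouring secant slopes, endpoint derivatives use the
one-sided three-point formula clamped to preserve shape. PCHIP cannot
overshoot between knots, so the sampled curve inherits monotonicity and
needs no post-hoc sorting. The implementation matches `pracma::pchip` to
machine precision, and an independently coded textbook version serves as the
test oracle.

## Colour difference and session statistics

`mean_delta_e()` converts both images to CIELAB and averages the per-pixel
Euclidean distance; a mean up to 5 is reported as "images appear the same"
(about 1 is a just-noticeable difference). The imagery carries no profile,
so we assume sRGB with D65. The RGB-to-XYZ matrix is derived at load time
from the sRGB primary and white chromaticities rather than hard-coded from
the usual 7-decimal tables — the rounded tables disagree with the definition
by up to ΔE 0.01, which matters at the tolerances our tests assert. (Note
that `grDevices::convertColor` uses a slightly different D65 chromaticity,
(0.3137, 0.3291) rather than (0.3127, 0.3290), so it agrees with a standard
sRGB conversion only on the neutral axis.)

Observer-session tables (CSV: `observer,image,repeat,tool,p1..p6`) support
`agreement()` — the proportion of repeated images on which an observer chose
the same tool — and `mcv()`, the mean across image pairs of the per-parameter
coefficient of variation CV = sigma/mu. The *population* standard deviation
is the default (a `sample = TRUE` flag exists): with two repeats per image
the Bessel-corrected deviation inflates every CV by sqrt(2), and the
definition sigma/mu carries no correction. Observers who never used a tool
are reported as `NA`, mirroring the "-" convention in reporting tables.

## Synthetic scenes

The study imagery that motivates this package is commercially restricted, so
`generate_seafloor_image()` emulates its statistical structure for testing:
i.i.d. truncated-Weibull brightness texture (inverse-CDF sampling,
`sample_weibull_brightness()`), multiplied by a radial Gaussian illumination
profile `1 - gain * (1 - exp(-r^2 / 2 sigma^2))` for the light cone, and
coloured by a fixed low-saturation substrate chromaticity whose maximum
channel is 1 (so constructed brightness is exactly the image's max-channel
brightness). Defaults — texture (λ = 1.2, k = 4), cone gain 0.6, radius 0.35
of the frame, sandy hue at saturation 0.35 — were chosen once as a plausible
cone-lit sandy seafloor. Any smooth unimodal falloff would do for testing;
Gaussian is simply the obvious choice.

What the generator does *not* emulate: spatial correlation of real substrate
texture, wavelength-dependent attenuation and colour casts, scattering/haze,
shadows from 3-D relief, and sensor noise. Passing tests therefore show the
pipeline is correct on images with the right histogram structure and
illumination gradient — not that enhanced real imagery will be preferred by
analysts, which only an observer study can show.

## Numerical choices and degenerate inputs

* Histogram/tone-curve node count 256 throughout (8-bit imagery); images are
  read from 8-bit PNG/JPEG/TIFF by dividing by 255 and written back rounded
  to the nearest 8-bit level.
* Tone-curve evaluation between nodes: linear interpolation, anchor (0, 0).
* Grid-fit tie-break: lexicographic smallest (lambda, k).
* KL proxy floor 1e-12; observed zeros contribute 0.
* A histogram with all mass at zero brightness (an all-black image) yields a
  warning and the best grid fit rather than an error.
* Non-monotone tone curves and non-increasing control-point ordinates are
  rejected, never repaired.
* Problem sizes used by the test-suite and the acceptance script — 96×96 to
  128×128 scenes, 20 seeds per stochastic check, 5·10^5-sample parameter
  recovery, 1000 random curve pairs — keep every check comfortably fast
  while leaving estimator noise well inside the asserted tolerances.

## Limitations

WTM is a global tone adjustment: it cannot fix spatially varying problems
(the light cone itself) the way tiled CLAHE can, and tone curves with
multiple slope regimes — which analysts occasionally craft — lie outside the
two-parameter family, where only the closest-WTM approximation (and its
ΔE*ab score) is available. Fitting is grid-resolution-limited by design; no
continuous optimisation, maximum-likelihood fitting or 3-parameter Weibull
is provided. Colour handling assumes sRGB throughout; there is no colour
management or HDR path.
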