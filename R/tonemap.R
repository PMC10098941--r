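# Tone-curve constructors.
#
# All constructors return length-N (default 256) monotone tone curves on
# [0, 1], applied to images with apply_tonecurve().

as_params_or_fit <- function(p) {
  if (inherits(p, "weibull_fit")) p$params else as_weibull_params(p)
}

#' Histogram-equalisation tone curve
#'
#' The cumulative of the brightness pdf.  Equalising an image whose histogram
#' is already flat is a null operation (identity curve); in general the curve
#' is steep where mass is concentrated and flat where bins are empty.
#'
#' @param h Brightness pdf.
#' @return Tone curve of the same length.
#' @export
he_tonecurve <- function(h) {
  cumulative(h)
}

#' Slope bounds for contrast-limited equalisation
#'
#' @param m Minimum tone-curve slope, `0 < m <= 1` (default 0.5).
#' @param M Maximum tone-curve slope, `M >= 1` (default 2).
#' @return List with elements `m` and `M`.
#' @export
slope_bounds <- function(m = 0.5, M = 2) {
  if (!is.numeric(m) || !is.numeric(M) || length(m) != 1L || length(M) != 1L) {
    stop("slope bounds must be single numbers", call. = FALSE)
  }
  if (!(m > 0 && m <= 1 && M >= 1)) {
    stop("slope bounds require 0 < m <= 1 <= M", call. = FALSE)
  }
  list(m = m, M = M)
}

#' Contrast-limited proxy histogram (CLHE)
#'
#' Finds the histogram closest to `h` in least squares whose cumulative tone
#' curve has all slopes in `[m, M]`; equivalently the Euclidean projection of
#' `h` onto the set `{h' : m/N <= h'_j <= M/N, sum(h') = 1}`.  The projection
#' has the water-filling form `clamp(h + tau, m/N, M/N)` for the unique shift
#' `tau` that restores unit mass; `tau` is located by bisection and the free
#' (unclamped) bins are then polished exactly.
#'
#' @param h Brightness pdf.
#' @param bounds [slope_bounds()] (default m = 0.5, M = 2).
#' @return Proxy pdf: same length, sums to 1, bins within `[m/N, M/N]`.
#' @export
clhe_proxy <- function(h, bounds = slope_bounds()) {
  validate_pdf(h)
  n <- length(h)
  lo <- bounds$m / n
  hi <- bounds$M / n
  # feasibility: the box must intersect the simplex
  if (n * lo > 1 + 1e-12 || n * hi < 1 - 1e-12) {
    stop("infeasible slope bounds: need m <= 1 <= M", call. = FALSE)
  }
  shifted_mass <- function(tau) sum(pmin(pmax(h + tau, lo), hi))
  a <- lo - max(h)
  b <- hi - min(h)
  for (i in 1:100) {
    mid <- (a + b) / 2
    if (shifted_mass(mid) < 1) a <- mid else b <- mid
  }
  tau <- (a + b) / 2
  proxy <- pmin(pmax(h + tau, lo), hi)
  # exact mass on the free set, given the active set found by bisection
  free <- proxy > lo & proxy < hi
  if (any(free)) {
    proxy[free] <- h[free] + (1 - sum(proxy[!free]) - sum(h[free])) / sum(free)
    proxy <- pmin(pmax(proxy, lo), hi)
  }
  proxy / sum(proxy)
}

#' Weibull tone curve
#'
#' The tone map that carries the input Weibull proxy distribution onto a
#' target Weibull proxy: the composition of the input proxy's CDF with the
#' target proxy's inverse CDF, sampled at the 256 node abscissae.
#'
#' @details
#' The composition is evaluated in the Weibull exponent domain
#' `u = (2.55 b / lambda)^k` rather than in probability space: with retained
#' truncation masses `Z = 1 - s` (survival `s` at the truncation point),
#' matching the renormalised CDFs gives
#' `exp(-v) = s_out + (Z_out/Z_in) (exp(-u) - s_in)` and
#' `s = lambda_out v^(1/k_out) / 2.55`.  For sharply peaked proxies the CDF
#' saturates to 1 in double precision long before brightness reaches 1, so a
#' probability-space composition would collapse the upper tone range; the
#' exponent-domain form stays exact there (in particular the self-map is the
#' identity for any parameters).
#'
#' @param fit_in Input-image proxy: [weibull_params()] or a `weibull_fit`.
#' @param target Target proxy parameters.
#' @param n Number of curve samples (default 256).
#' @return Monotone tone curve ending at 1.
#' @export
wtm_tonecurve <- function(fit_in, target, n = 256L) {
  p_in <- as_params_or_fit(fit_in)
  p_out <- as_params_or_fit(target)
  b <- seq_len(n) / n
  u <- (2.55 * b / p_in$lambda)^p_in$k
  s_in <- exp(-(2.55 / p_in$lambda)^p_in$k)    # survival at truncation
  s_out <- exp(-(2.55 / p_out$lambda)^p_out$k)
  if (s_in == s_out) {
    v <- u  # in particular the self-map is exact
  } else {
    # exp(-v) = s_out + (Z_out / Z_in) * (exp(-u) - s_in); every term is
    # non-negative, so the evaluation cannot cancel to a negative argument
    v <- -log(s_out + ((1 - s_out) / (1 - s_in)) * (exp(-u) - s_in))
    v <- pmax(v, 0)
  }
  s <- p_out$lambda * v^(1 / p_out$k) / 2.55
  s <- cummax(pmin(pmax(s, 0), 1))  # guard monotone against rounding
  s[n] <- 1
  s
}

#' Enhance an image with a target Weibull distribution
#'
#' Fits a Weibull proxy to the image's brightness histogram, builds the tone
#' curve mapping that proxy onto `target`, and applies it.  The two target
#' parameters act as intuitive sliders: `lambda` is a brightness control
#' (larger brightens), and `k` is an inverse contrast control (smaller
#' flattens and widens the histogram, increasing contrast).
#'
#' @param image RGB image.
#' @param target Target [weibull_params()].
#' @param n Histogram bin / curve sample count (default 256).
#' @return List: `image` (enhanced), `curve`, and `fit` (the input proxy).
#' @export
wtm_enhance <- function(image, target, n = 256L) {
  validate_image(image)
  target <- as_params_or_fit(target)
  fit <- fit_weibull(compute_pdf(extract_brightness(image), n))
  curve <- wtm_tonecurve(fit$params, target, n)
  list(image = apply_tonecurve(image, curve), curve = curve, fit = fit)
}

#' Approximate an arbitrary enhancement by its closest Weibull tone map
#'
#' Given an input image and some enhanced version of it (for instance a
#' manual control-point adjustment), fits Weibull proxies to both brightness
#' histograms and applies the tone curve mapping one proxy to the other.
#' The result is the Weibull tone map closest (in the KL proxy sense) to the
#' enhancement that produced `output_img`.
#'
#' @param input_img Original RGB image.
#' @param output_img Enhanced RGB image of identical dimensions.
#' @param n Histogram bin / curve sample count (default 256).
#' @return List: `image` (the WTM approximation of `output_img`), `curve`,
#'   `fit_in`, `fit_out`.
#' @export
wtm_approximate <- function(input_img, output_img, n = 256L) {
  validate_image(input_img, "input_img")
  validate_image(output_img, "output_img")
  if (!identical(dim(input_img), dim(output_img))) {
    stop("input and output images must have identical dimensions", call. = FALSE)
  }
  fit_in <- fit_weibull(compute_pdf(extract_brightness(input_img), n))
  fit_out <- fit_weibull(compute_pdf(extract_brightness(output_img), n))
  curve <- wtm_tonecurve(fit_in$params, fit_out$params, n)
  list(image = apply_tonecurve(input_img, curve), curve = curve,
       fit_in = fit_in, fit_out = fit_out)
}

#' Control-point set for manual tone curves
#'
#' Six control points with abscissae fixed at 0, 0.2, ..., 1; only the
#' ordinates move, and only monotonically increasing configurations are
#' accepted.
#'
#' @param ordinates Six strictly increasing output-brightness values in
#'   \[0, 1\].
#' @return A `control_points` list with `x` and `y`.
#' @export
control_points <- function(ordinates) {
  y <- as.numeric(ordinates)
  if (length(y) != 6L || anyNA(y)) stop("need 6 ordinate values", call. = FALSE)
  if (min(y) < 0 || max(y) > 1) stop("ordinates must lie in [0, 1]", call. = FALSE)
  if (any(diff(y) <= 0)) {
    stop("ordinates must be strictly increasing (monotone tone map)", call. = FALSE)
  }
  structure(list(x = seq(0, 1, by = 0.2), y = y), class = "control_points")
}

# Monotone shape-preserving piecewise-cubic Hermite derivative rule:
# weighted harmonic mean of neighbouring secant slopes in the interior,
# one-sided three-point formula with monotonicity clamping at the ends.
pchip_derivs <- function(x, y) {
  n <- length(x)
  hh <- diff(x)
  delta <- diff(y) / hh
  d <- numeric(n)
  for (i in 2:(n - 1)) {
    if (delta[i - 1] * delta[i] > 0) {
      w1 <- 2 * hh[i] + hh[i - 1]
      w2 <- hh[i] + 2 * hh[i - 1]
      d[i] <- (w1 + w2) / (w1 / delta[i - 1] + w2 / delta[i])
    }
  }
  end_deriv <- function(h1, h2, d1, d2) {
    dd <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
    if (sign(dd) != sign(d1)) {
      dd <- 0
    } else if (sign(d1) != sign(d2) && abs(dd) > 3 * abs(d1)) {
      dd <- 3 * d1
    }
    dd
  }
  d[1] <- end_deriv(hh[1], hh[2], delta[1], delta[2])
  d[n] <- end_deriv(hh[n - 1], hh[n - 2], delta[n - 1], delta[n - 2])
  d
}

pchip_eval <- function(x, y, d, xout) {
  idx <- pmin(pmax(findInterval(xout, x), 1L), length(x) - 1L)
  h <- x[idx + 1L] - x[idx]
  t <- (xout - x[idx]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[idx] + h10 * h * d[idx] + h01 * y[idx + 1L] + h11 * h * d[idx + 1L]
}

#' Control-point tone curve via monotone PCHIP interpolation
#'
#' Interpolates the six control points with a piecewise cubic Hermite
#' polynomial whose derivatives are limited (Fritsch-Carlson style) so the
#' interpolant is monotone and passes through every control point without
#' overshoot, then samples it at the `n` node abscissae.
#'
#' @param cps [control_points()] (or a vector of 6 increasing ordinates).
#' @param n Number of curve samples (default 256).
#' @return Monotone tone curve.
#' @export
pchip_tonecurve <- function(cps, n = 256L) {
  if (!inherits(cps, "control_points")) cps <- control_points(cps)
  d <- pchip_derivs(cps$x, cps$y)
  s <- pchip_eval(cps$x, cps$y, d, seq_len(n) / n)
  s <- pmin(pmax(s, 0), 1)
  validate_tonecurve(s)
  s
}
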