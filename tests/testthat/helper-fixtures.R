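# Shared fixtures and independent oracles for the test suite.

# small RGB image with the given brightness matrix and fixed chromatic ratios
image_from_brightness <- function(brightness, ratios = c(1, 0.7, 0.4)) {
  ratios <- ratios / max(ratios)
  img <- array(0, dim = c(dim(brightness), 3))
  for (ch in 1:3) img[, , ch] <- brightness * ratios[ch]
  img
}

random_image <- function(h = 24, w = 24, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

random_pdf <- function(n = 256, seed = 1, concentration = 1) {
  set.seed(seed)
  x <- stats::rgamma(n, shape = concentration)
  x / sum(x)
}

# --- independent oracles ---------------------------------------------------

# Euclidean projection onto {lo <= x <= hi, sum(x) = 1} by Dykstra's
# alternating projections between the box and the hyperplane; independent of
# the water-filling construction used by clhe_proxy().
dykstra_projection <- function(h, lo, hi, iters = 5000) {
  x <- h
  p <- q <- numeric(length(h))
  for (i in seq_len(iters)) {
    y <- pmin(pmax(x + p, lo), hi)        # box
    p <- x + p - y
    x <- y + q - (sum(y + q) - 1) / length(h)  # hyperplane sum = 1
    q <- y + q - x
  }
  x
}

# Scalar textbook monotone piecewise-cubic Hermite interpolation
# (Fritsch-Carlson style limiter, one-sided three-point end derivatives),
# written as plain per-point loops.
pchip_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- numeric(n - 1); delta <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    h[i] <- x[i + 1] - x[i]
    delta[i] <- (y[i + 1] - y[i]) / h[i]
  }
  d <- numeric(n)
  for (i in 2:(n - 1)) {
    if (delta[i - 1] * delta[i] <= 0) {
      d[i] <- 0
    } else {
      w1 <- 2 * h[i] + h[i - 1]
      w2 <- h[i] + 2 * h[i - 1]
      d[i] <- (w1 + w2) / (w1 / delta[i - 1] + w2 / delta[i])
    }
  }
  ends <- function(h1, h2, d1, d2) {
    dd <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
    if (sign(dd) != sign(d1)) return(0)
    if (sign(d1) != sign(d2) && abs(dd) > 3 * abs(d1)) return(3 * d1)
    dd
  }
  d[1] <- ends(h[1], h[2], delta[1], delta[2])
  d[n] <- ends(h[n - 1], h[n - 2], delta[n - 1], delta[n - 2])
  out <- numeric(length(xout))
  for (j in seq_along(xout)) {
    i <- max(1, min(n - 1, findInterval(xout[j], x)))
    t <- (xout[j] - x[i]) / h[i]
    out[j] <- y[i] * (1 + 2 * t) * (1 - t)^2 + h[i] * d[i] * t * (1 - t)^2 +
      y[i + 1] * t^2 * (3 - 2 * t) + h[i] * d[i + 1] * t^2 * (t - 1)
  }
  out
}

# sRGB -> Lab with the RGB->XYZ matrix derived from the sRGB primary and
# white chromaticities (rather than published matrix constants), per pixel.
srgb_to_lab_oracle <- function(rgb) {
  prim <- rbind(r = c(0.64, 0.33), g = c(0.30, 0.60), b = c(0.15, 0.06))
  white <- c(0.3127, 0.3290)
  xyz_from_xy <- function(xy) c(xy[1] / xy[2], 1, (1 - xy[1] - xy[2]) / xy[2])
  P <- sapply(seq_len(3), function(i) xyz_from_xy(prim[i, ]))  # 3x3, cols r,g,b
  wxyz <- xyz_from_xy(white)
  scale <- solve(P, wxyz)
  M <- P %*% diag(scale)
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  out <- matrix(0, nrow(rgb), 3)
  for (i in seq_len(nrow(rgb))) {
    lin <- sapply(rgb[i, ], function(c) {
      if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4
    })
    xyz <- as.numeric(M %*% lin)
    f <- sapply(xyz / wxyz, function(t) {
      if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
    })
    out[i, ] <- c(116 * f[2] - 16, 500 * (f[1] - f[2]), 200 * (f[2] - f[3]))
  }
  out
}

# brute-force double loop over the full (lambda, k) search grid
fit_weibull_bruteforce <- function(h, proxies = NULL) {
  lambdas <- seq(0.1, 3, by = 0.1)
  ks <- seq(0.1, 15, by = 0.1)
  best <- list(kl = Inf)
  for (li in seq_along(lambdas)) {
    for (ki in seq_along(ks)) {
      g <- if (is.null(proxies)) {
        weibull_pdf_discrete(weibull_params(lambdas[li], ks[ki]), length(h))
      } else {
        proxies[[(li - 1) * length(ks) + ki]]
      }
      kl <- kl_divergence(h, g)
      if (kl < best$kl) best <- list(lambda = lambdas[li], k = ks[ki], kl = kl)
    }
  }
  best
}

# all 4500 grid proxies, built once per test run for the brute-force oracle
grid_proxies <- local({
  cache <- NULL
  function(n = 256) {
    if (is.null(cache)) {
      lambdas <- seq(0.1, 3, by = 0.1)
      ks <- seq(0.1, 15, by = 0.1)
      cache <<- vector("list", length(lambdas) * length(ks))
      idx <- 1
      for (l in lambdas) for (k in ks) {
        cache[[idx]] <<- weibull_pdf_discrete(weibull_params(l, k), n)
        idx <- idx + 1
      }
    }
    cache
  }
})
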