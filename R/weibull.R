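# Truncated, rescaled Weibull machinery.
#
# Brightness histograms of artificially lit seafloor images are well
# described by two-parameter Weibull densities.  The density is truncated at
# 2.55 on its natural axis (negligible mass lies beyond that for the
# parameter ranges of interest) and the axis divided by 2.55, so the proxy
# lives on the same [0, 1] brightness interval as the image histograms.
# After truncation the retained mass T(2.55) can be below one (large scale
# lambda), so all truncated quantities are renormalised by T(2.55) to keep
# the proxy a proper distribution.

.wtm_cache <- new.env(parent = emptyenv())

#' Weibull parameter pair
#'
#' @param lambda Scale parameter (> 0); peak position, a brightness proxy.
#' @param k Shape parameter (> 0); spread, an (inverse) contrast proxy --
#'   lower `k` gives a flatter, wider histogram, i.e. more contrast.
#' @return A `weibull_params` list with elements `lambda` and `k`.
#' @export
weibull_params <- function(lambda, k) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda <= 0) {
    stop("lambda must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("k must be a single positive number", call. = FALSE)
  }
  structure(list(lambda = lambda, k = k), class = "weibull_params")
}

as_weibull_params <- function(p) {
  if (inherits(p, "weibull_params")) return(p)
  if (is.list(p) && all(c("lambda", "k") %in% names(p))) {
    return(weibull_params(p$lambda, p$k))
  }
  if (is.numeric(p) && length(p) == 2L) return(weibull_params(p[1], p[2]))
  stop("cannot interpret Weibull parameters", call. = FALSE)
}

#' @export
format.weibull_params <- function(x, ...) {
  sprintf("Weibull(lambda = %g, k = %g)", x$lambda, x$k)
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# retained mass at the truncation point on the raw axis
trunc_mass <- function(p) stats::pweibull(2.55, shape = p$k, scale = p$lambda)

#' Truncated Weibull CDF on the rescaled brightness axis
#'
#' The Weibull CDF `1 - exp(-(x / lambda)^k)` evaluated at `2.55 * b` and
#' renormalised by the retained mass at the truncation point, so it runs from
#' 0 at `b = 0` to 1 at `b = 1`.
#'
#' @param b Brightness in \[0, 1\] (vectorised).
#' @param params [weibull_params()] pair.
#' @return Probabilities in \[0, 1\].
#' @export
weibull_cdf <- function(b, params) {
  params <- as_weibull_params(params)
  b <- as.numeric(b)
  if (anyNA(b) || min(b) < 0 || max(b) > 1) stop("b must lie in [0, 1]", call. = FALSE)
  stats::pweibull(2.55 * b, shape = params$k, scale = params$lambda) / trunc_mass(params)
}

#' Inverse of the truncated Weibull CDF
#'
#' Closed-form inverse: the target probability is scaled back by the retained
#' mass and pushed through the standard Weibull quantile function, then the
#' axis is rescaled to \[0, 1\].  Evaluated through the survival function
#' (`1 - p * Z` assembled as `(1 - p) + p * (1 - Z)`) so quantiles close to 1
#' keep full precision.  Satisfies `weibull_cdf(weibull_icdf(p)) == p` to
#' high precision.
#'
#' @param p Probabilities in \[0, 1\] (vectorised).
#' @param params [weibull_params()] pair.
#' @return Brightness values in \[0, 1\].
#' @export
weibull_icdf <- function(p, params) {
  params <- as_weibull_params(params)
  p <- as.numeric(p)
  if (anyNA(p) || min(p) < 0 || max(p) > 1) stop("p must lie in [0, 1]", call. = FALSE)
  surv_trunc <- stats::pweibull(2.55, shape = params$k, scale = params$lambda,
                                lower.tail = FALSE)
  surv <- (1 - p) + p * surv_trunc  # = 1 - p * trunc_mass, without cancellation
  b <- stats::qweibull(surv, shape = params$k, scale = params$lambda,
                       lower.tail = FALSE) / 2.55
  pmin(pmax(b, 0), 1)
}

#' Discrete truncated Weibull PDF
#'
#' Bin masses are exact CDF differences at the bin edges (not midpoint
#' density evaluations), so the cumulative of this pdf agrees with
#' [weibull_cdf()] at every bin edge by construction.
#'
#' @param params [weibull_params()] pair.
#' @param n Number of bins (default 256).
#' @return Histogram pdf of length `n` summing to 1.
#' @export
weibull_pdf_discrete <- function(params, n = 256L) {
  params <- as_weibull_params(params)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  edges <- stats::pweibull(2.55 * (0:n) / n, shape = params$k, scale = params$lambda)
  diff(edges) / trunc_mass(params)
}

#' Kullback-Leibler divergence between two histogram PDFs
#'
#' `sum(h * log(h / g))` in nats, with the conventions `0 * log(0 / x) = 0`
#' and the reference `g` floored at 1e-12 (then renormalised) so numerically
#' empty proxy bins cannot produce infinities.
#'
#' @param h Observed pdf.
#' @param g Reference (proxy) pdf.
#' @return Non-negative divergence in nats; 0 iff `h == g`.
#' @export
kl_divergence <- function(h, g) {
  if (length(h) != length(g)) stop("pdf length mismatch", call. = FALSE)
  validate_pdf(h)
  validate_pdf(g)
  gf <- pmax(g, 1e-12)
  gf <- gf / sum(gf)
  pos <- h > 0
  sum(h[pos] * (log(h[pos]) - log(gf[pos])))
}

# Pre-tabulated log proxy pdfs over the full search grid, cached per bin
# count.  Rows follow expand-style order: lambda varies slowest (ascending),
# k fastest, so the first minimum found is the lexicographically smallest
# (lambda, k) pair.
weibull_grid <- function(n = 256L) {
  key <- paste0("grid_", n)
  if (!is.null(.wtm_cache[[key]])) return(.wtm_cache[[key]])
  lambda <- seq(0.1, 3, by = 0.1)
  k <- seq(0.1, 15, by = 0.1)
  pairs <- cbind(lambda = rep(lambda, each = length(k)),
                 k = rep(k, times = length(lambda)))
  logg <- matrix(NA_real_, nrow = n, ncol = nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- weibull_pdf_discrete(weibull_params(pairs[i, 1], pairs[i, 2]), n)
    gf <- pmax(g, 1e-12)
    logg[, i] <- log(gf / sum(gf))
  }
  grid <- list(pairs = pairs, logg = logg)
  .wtm_cache[[key]] <- grid
  grid
}

#' Fit a Weibull proxy to a brightness histogram
#'
#' Exhaustive search over the grid `lambda in {0.1, ..., 3}`,
#' `k in {0.1, ..., 15}` (step 0.1; 4500 pairs), minimising the KL divergence
#' of the observed pdf from the discrete truncated Weibull proxy.  Ties are
#' broken deterministically by the smallest `lambda`, then the smallest `k`.
#'
#' @param h Observed brightness pdf (sums to 1).
#' @return A `weibull_fit` list: `params` ([weibull_params()]) and `kl`, the
#'   minimised divergence in nats.
#' @export
fit_weibull <- function(h) {
  validate_pdf(h)
  if (h[1] >= 1 - 1e-12) {
    warning("degenerate histogram (all mass at zero brightness); fit is ill-defined")
  }
  grid <- weibull_grid(length(h))
  pos <- h > 0
  const <- sum(h[pos] * log(h[pos]))
  # KL(h || g_i) = const - sum_j h_j log g_ij, for every grid column at once
  kl <- const - as.numeric(crossprod(grid$logg[pos, , drop = FALSE], h[pos]))
  best <- which.min(kl)
  structure(list(
    params = weibull_params(unname(grid$pairs[best, 1]), unname(grid$pairs[best, 2])),
    kl = max(kl[best], 0)
  ), class = "weibull_fit")
}

#' @export
format.weibull_fit <- function(x, ...) {
  sprintf("%s  [KL = %.6g nats]", format(x$params), x$kl)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Serialise a Weibull fit to JSON
#'
#' @param fit A `weibull_fit` (or `weibull_params`, written with `kl` absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  obj <- if (inherits(fit, "weibull_fit")) {
    list(lambda = fit$params$lambda, k = fit$params$k, kl = fit$kl)
  } else {
    p <- as_weibull_params(fit)
    list(lambda = p$lambda, k = p$k)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
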