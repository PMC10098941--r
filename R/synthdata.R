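# Seeded generators for synthetic seafloor imagery.
#
# Artificially lit benthic survey photographs share a characteristic
# structure: a bright central light cone that falls off radially into a
# darker periphery, brightness texture whose histogram is close to a Weibull
# density, and low-saturation substrate colour.  The generators here emulate
# exactly that structure so the enhancement pipeline can be exercised on
# reproducible scenes.  They do not model underwater light transport,
# scattering or wavelength-dependent attenuation.

#' Sample brightness values from a truncated Weibull distribution
#'
#' Inverse-CDF sampling of the truncated, rescaled Weibull proxy: uniform
#' deviates are pushed through [weibull_icdf()], so the empirical CDF
#' converges to [weibull_cdf()].
#'
#' @param params [weibull_params()].
#' @param n Number of samples.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @return `n` brightness values in (0, 1\].
#' @export
sample_weibull_brightness <- function(params, n, seed = 1L) {
  params <- as_weibull_params(params)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  b <- weibull_icdf(stats::runif(n), params)
  pmax(b, .Machine$double.xmin)  # open at 0: runif lies in (0, 1)
}

#' Scene specification for a synthetic seafloor image
#'
#' @param height,width Image size in pixels (>= 16).
#' @param texture [weibull_params()] for the brightness texture.
#' @param cone_centre Light-cone centre as (row, col) fractions of the frame.
#' @param cone_radius Cone radius (Gaussian sigma) as a fraction of the
#'   frame diagonal.
#' @param cone_gain Cone strength in \[0, 1\]: 0 leaves the texture
#'   unmodulated, 1 darkens the far periphery to black.
#' @param hue,saturation Substrate chromaticity (HSV hue in \[0, 1\],
#'   saturation in \[0, 1\]); defaults give a muted sandy brown.
#' @param seed Integer seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(height = 128L, width = 128L,
                       texture = weibull_params(1.2, 4),
                       cone_centre = c(0.5, 0.5), cone_radius = 0.35,
                       cone_gain = 0.6, hue = 0.09, saturation = 0.35,
                       seed = 1L) {
  if (height < 16L || width < 16L) stop("scene dimensions must be >= 16", call. = FALSE)
  if (cone_gain < 0 || cone_gain > 1) stop("cone_gain must lie in [0, 1]", call. = FALSE)
  if (saturation < 0 || saturation > 1) stop("saturation must lie in [0, 1]", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 texture = as_weibull_params(texture),
                 cone_centre = cone_centre, cone_radius = cone_radius,
                 cone_gain = cone_gain, hue = hue, saturation = saturation,
                 seed = as.integer(seed)), class = "scene_spec")
}

#' Generate a synthetic artificially lit seafloor image
#'
#' Brightness is Weibull-distributed texture multiplied by a radial
#' illumination profile `1 - gain * (1 - exp(-r^2 / (2 sigma^2)))` centred on
#' the light cone, so the centre keeps full texture brightness and the
#' periphery is attenuated.  Colour is the brightness times a fixed
#' low-saturation substrate chromaticity whose maximum channel is 1, so the
#' image's max-channel brightness equals the constructed brightness field
#' exactly.
#'
#' @param spec A [scene_spec()].
#' @return RGB image (height x width x 3), deterministic per seed.
#' @export
generate_seafloor_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  tex <- sample_weibull_brightness(spec$texture, h * w, seed = spec$seed)
  tex <- matrix(tex, nrow = h, ncol = w)
  rows <- (seq_len(h) - 0.5) / h
  cols <- (seq_len(w) - 0.5) / w
  r2 <- outer((rows - spec$cone_centre[1])^2, (cols - spec$cone_centre[2])^2, `+`)
  sigma2 <- (spec$cone_radius * sqrt(2))^2  # radius as fraction of unit frame diagonal sqrt(2)
  illum <- 1 - spec$cone_gain * (1 - exp(-r2 / (2 * sigma2)))
  brightness <- tex * illum
  chroma <- as.numeric(grDevices::col2rgb(
    grDevices::hsv(spec$hue, spec$saturation, 1)
  )) / 255
  chroma <- chroma / max(chroma)  # max channel 1: brightness is preserved exactly
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- brightness * chroma[ch]
  validate_image(img, "generated image")
  img
}

#' Simulate a user tone adjustment
#'
#' Produces an enhanced counterpart of `image` the way an observer session
#' would: either a Weibull tone map towards a target parameter pair, or a
#' monotone control-point curve.
#'
#' @param image RGB image.
#' @param kind `"wtm"` or `"pchip"`.
#' @param params For `"wtm"`, target [weibull_params()]; for `"pchip"`, six
#'   increasing ordinates (or `NULL` to draw a random monotone set).
#' @param seed Seed used when drawing random control points.
#' @return Enhanced RGB image.
#' @export
generate_user_adjustment <- function(image, kind = c("wtm", "pchip"),
                                     params = NULL, seed = 1L) {
  kind <- match.arg(kind)
  validate_image(image)
  if (kind == "wtm") {
    if (is.null(params)) stop("wtm adjustment needs target parameters", call. = FALSE)
    wtm_enhance(image, params)$image
  } else {
    if (is.null(params)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      params <- c(0, sort(stats::runif(4, 0.05, 0.95)), 1)
      while (any(diff(params) <= 0.01)) {
        params <- c(0, sort(stats::runif(4, 0.05, 0.95)), 1)
      }
    }
    apply_tonecurve(image, pchip_tonecurve(control_points(params)))
  }
}
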