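# Image and brightness primitives.
#
# An image is a plain H x W x 3 numeric array with channel values in [0, 1]
# (the layout returned by png::readPNG / tiff::readTIFF).  Brightness is
# defined per pixel as the maximum over R, G and B -- the HSV value channel.
# Using the channel maximum (rather than the mean) guarantees that scaling
# colours by a ratio of brightnesses can never push a channel above 1.

#' Validate an RGB image array
#'
#' Checks that `image` is a finite H x W x 3 numeric array with all values in
#' \[0, 1\].
#'
#' @param image Object to validate.
#' @param arg Name used in error messages.
#' @return The image, invisibly.
#' @export
validate_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop(arg, " must be an H x W x 3 array (RGB)", call. = FALSE)
  }
  if (dim(image)[1] < 1L || dim(image)[2] < 1L) {
    stop(arg, " must have height and width >= 1", call. = FALSE)
  }
  if (!is.numeric(image) || anyNA(image) || any(!is.finite(image))) {
    stop(arg, " must be finite numeric", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 1) {
    stop(arg, " channel values must lie in [0, 1]", call. = FALSE)
  }
  invisible(image)
}

#' Per-pixel maximum-channel brightness
#'
#' Brightness of an RGB pixel is `max(R, G, B)`, i.e. the HSV value channel.
#'
#' @param image H x W x 3 array, values in \[0, 1\].
#' @return H x W matrix of brightness values in \[0, 1\].
#' @examples
#' img <- array(c(0.2, 0.5, 0.3), dim = c(1, 1, 3))
#' extract_brightness(img)  # 0.5
#' @export
extract_brightness <- function(image) {
  validate_image(image)
  L <- pmax(image[, , 1], image[, , 2], image[, , 3])
  dim(L) <- dim(image)[1:2]  # keep matrix shape even for 1-pixel images
  L
}

#' Normalised brightness histogram (PDF)
#'
#' Bins brightness values into `n` equal-width half-open intervals
#' `((j-1)/n, j/n]` and normalises the counts to sum to one.  Exact zeros are
#' assigned to the first bin (real images contain true black, which the
#' half-open convention would otherwise drop).
#'
#' @param brightness Numeric matrix or vector of brightness values in \[0, 1\].
#' @param n Number of bins (default 256).
#' @return Numeric vector of length `n`, non-negative, summing to 1.
#' @export
compute_pdf <- function(brightness, n = 256L) {
  if (length(brightness) == 0L) stop("empty brightness map", call. = FALSE)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  b <- as.numeric(brightness)
  if (anyNA(b) || min(b) < 0 || max(b) > 1) {
    stop("brightness values must lie in [0, 1]", call. = FALSE)
  }
  idx <- pmax(ceiling(b * n), 1L)
  tabulate(idx, nbins = n) / length(b)
}

#' Validate a histogram PDF
#' @param pdf Numeric vector of bin masses.
#' @param tol Tolerance on the unit-sum constraint.
#' @return The pdf, invisibly.
#' @export
validate_pdf <- function(pdf, tol = 1e-9) {
  if (!is.numeric(pdf) || length(pdf) < 2L) stop("pdf must be numeric, length >= 2", call. = FALSE)
  if (anyNA(pdf) || min(pdf) < 0) stop("pdf bins must be non-negative", call. = FALSE)
  if (abs(sum(pdf) - 1) > tol) stop("pdf must sum to 1", call. = FALSE)
  invisible(pdf)
}

#' Cumulative distribution of a histogram PDF
#'
#' The running sum `s_j = sum(h_1..h_j)`.  Applied as a tone curve this is
#' exactly histogram equalisation: the CDF of the input brightness
#' distribution maps it towards a uniform one.
#'
#' @param pdf Histogram PDF (sums to 1).
#' @return Tone curve: monotone non-decreasing vector with final entry 1.
#' @export
cumulative <- function(pdf) {
  validate_pdf(pdf)
  s <- cumsum(pdf)
  s[length(s)] <- 1  # guard accumulated rounding at the top node
  pmin(s, 1)
}

#' Slopes of a tone curve
#'
#' Finite-difference slope at each of the N nodes, `(s_j - s_{j-1}) * N` with
#' `s_0 = 0`.  For a curve that is the cumulative of a pdf `h`, the slopes
#' equal `N * h` exactly.
#'
#' @param curve Tone curve (length-N monotone vector in \[0, 1\]).
#' @return Numeric vector of N slopes.
#' @export
curve_slopes <- function(curve) {
  validate_tonecurve(curve)
  n <- length(curve)
  diff(c(0, curve)) * n
}

#' Validate a tone curve
#'
#' A tone curve is a length-N (default 256) vector giving the output
#' brightness for input `j/N`; it must be monotone non-decreasing with values
#' in \[0, 1\].
#'
#' @param curve Numeric vector.
#' @param tol Tolerance for monotonicity (tiny negative diffs from rounding).
#' @return The curve, invisibly.
#' @export
validate_tonecurve <- function(curve, tol = 1e-12) {
  if (!is.numeric(curve) || length(curve) < 2L) {
    stop("tone curve must be numeric, length >= 2", call. = FALSE)
  }
  if (anyNA(curve) || min(curve) < 0 || max(curve) > 1) {
    stop("tone curve values must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(curve) < -tol)) {
    stop("tone curve must be monotone non-decreasing", call. = FALSE)
  }
  invisible(curve)
}

#' Rebuild a colour image from adjusted brightness
#'
#' Scales each pixel's RGB triplet by `L_out / L_in`, preserving chromatic
#' ratios.  Because `L_in` is the channel maximum and `L_out <= 1`, the output
#' always stays in display range.  Pixels with `L_in = 0` (true black) are
#' returned black.
#'
#' @param image Source RGB image.
#' @param l_in Brightness of `image` (must equal its per-pixel channel max).
#' @param l_out Target brightness, same dimensions, values in \[0, 1\].
#' @return RGB image with per-pixel channel max equal to `l_out`.
#' @export
reconstruct_color <- function(image, l_in, l_out) {
  validate_image(image)
  d <- dim(image)[1:2]
  if (!identical(dim(l_in), d) || !identical(dim(l_out), d)) {
    stop("brightness maps must match image dimensions", call. = FALSE)
  }
  if (max(abs(l_in - extract_brightness(image))) > 1e-12) {
    stop("l_in is not the max-channel brightness of image", call. = FALSE)
  }
  if (min(l_out) < 0 || max(l_out) > 1) {
    stop("l_out must lie in [0, 1]", call. = FALSE)
  }
  ratio <- ifelse(l_in > 0, l_out / l_in, 0)
  out <- image * as.vector(ratio)  # recycles across the 3 channels
  # scaling by l_out/l_in is exact in ratio but can leave 1 + eps
  pmin(pmax(out, 0), 1)
}

#' Apply a tone curve to an image
#'
#' Brightness is remapped through the curve -- evaluated by piecewise-linear
#' interpolation over the nodes `(j/N, s_j)` with an implied anchor at
#' `(0, 0)` -- and colour is rebuilt with [reconstruct_color()] so chromatic
#' ratios are preserved.
#'
#' @param image RGB image.
#' @param curve Tone curve (length N, monotone, values in \[0, 1\]).
#' @return Enhanced RGB image.
#' @export
apply_tonecurve <- function(image, curve) {
  validate_image(image)
  validate_tonecurve(curve)
  l_in <- extract_brightness(image)
  l_out <- evaluate_tonecurve(curve, l_in)
  dim(l_out) <- dim(l_in)
  reconstruct_color(image, l_in, l_out)
}

#' Evaluate a tone curve at arbitrary brightness values
#'
#' Linear interpolation between the N sampled nodes, anchored at (0, 0).
#'
#' @param curve Tone curve.
#' @param b Brightness values in \[0, 1\].
#' @return Output brightness values.
#' @export
evaluate_tonecurve <- function(curve, b) {
  n <- length(curve)
  stats::approx(x = c(0, seq_len(n) / n), y = c(0, curve), xout = as.numeric(b),
                method = "linear", rule = 2, ties = "ordered")$y
}

# ---- tone curve serialisation -------------------------------------------

#' Read / write tone curves
#'
#' JSON files use the schema `{"n": N, "values": [...]}`; CSV files are a
#' single unnamed column of N values.  Round trips are exact to full double
#' precision.
#'
#' @param curve Tone curve.
#' @param path File path; format chosen by extension (`.json` or `.csv`).
#' @return `write_tonecurve` returns `path` invisibly; `read_tonecurve`
#'   returns the curve.
#' @export
write_tonecurve <- function(curve, path) {
  validate_tonecurve(curve)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(n = length(curve), values = curve), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(data.frame(v = sprintf("%.17g", curve)), path,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_tonecurve
#' @export
read_tonecurve <- function(path) {
  curve <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    as.numeric(obj$values)
  } else {
    as.numeric(utils::read.table(path, header = FALSE)[[1]])
  }
  validate_tonecurve(curve)
  curve
}

# ---- image file I/O ------------------------------------------------------

#' Read an 8-bit RGB image
#'
#' PNG, JPEG and TIFF are supported; values are rescaled to \[0, 1\].  Alpha
#' channels are dropped with a warning; greyscale images are replicated to
#' three channels.
#'
#' @param path Image file path.
#' @return H x W x 3 array in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("the 'jpeg' package is required to read JPEG files", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3] == 4L) {
    warning("alpha channel dropped from ", path)
    img <- img[, , 1:3, drop = FALSE]
  }
  validate_image(img, "decoded image")
  img
}

#' Write an RGB image
#'
#' Values are quantised to the nearest 8-bit level on write.
#'
#' @param image RGB image in \[0, 1\].
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  validate_image(image)
  q <- round(image * 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(q, path),
    tif  = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
    stop("unsupported output format: .", ext, call. = FALSE)
  )
  invisible(path)
}
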