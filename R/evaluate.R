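# Quantitative evaluation: CIELAB colour difference and observer-session
# agreement / variability statistics.
#
# Colour conversion assumes the sRGB working space (IEC 61966-2-1 transfer
# function) with the D65 white point; the imagery carries no colour profile
# so this is the conventional choice.

# Linear RGB -> XYZ matrix derived from the sRGB primary and D65 white
# chromaticities (x, y); deriving rather than hard-coding the usual
# 7-decimal matrix keeps the conversion exact to the space's definition.
.srgb_constants <- local({
  xyz_from_xy <- function(x, y) c(x / y, 1, (1 - x - y) / y)
  P <- cbind(r = xyz_from_xy(0.64, 0.33),
             g = xyz_from_xy(0.30, 0.60),
             b = xyz_from_xy(0.15, 0.06))
  white <- xyz_from_xy(0.3127, 0.3290)
  M <- P %*% diag(as.numeric(solve(P, white)))
  list(M = M, Minv = solve(M), white = white)
})
.M_RGB2XYZ <- .srgb_constants$M
.M_XYZ2RGB <- .srgb_constants$Minv
.WHITE_D65 <- .srgb_constants$white

srgb_decode <- function(c) ifelse(c <= 0.04045, c / 12.92, ((c + 0.055) / 1.055)^2.4)
srgb_encode <- function(c) ifelse(c <= 0.0031308, 12.92 * c, 1.055 * c^(1 / 2.4) - 0.055)

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert between sRGB and CIELAB
#'
#' `srgb_to_lab` maps gamma-encoded sRGB triplets in \[0, 1\] to CIE 1976
#' L*a*b* (D65 white); `lab_to_srgb` is its exact inverse.  Both are
#' vectorised over the rows of an n x 3 matrix.
#'
#' @param rgb n x 3 matrix (or length-3 vector) of sRGB values in \[0, 1\].
#' @param lab n x 3 matrix (or length-3 vector) of L*, a*, b* values.
#' @return n x 3 matrix in the destination space.
#' @export
srgb_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  xyz <- srgb_decode(rgb) %*% t(.M_RGB2XYZ)
  fx <- lab_f(xyz[, 1] / .WHITE_D65[1])
  fy <- lab_f(xyz[, 2] / .WHITE_D65[2])
  fz <- lab_f(xyz[, 3] / .WHITE_D65[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' @rdname srgb_to_lab
#' @export
lab_to_srgb <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = 3)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(lab_finv(fx) * .WHITE_D65[1],
               lab_finv(fy) * .WHITE_D65[2],
               lab_finv(fz) * .WHITE_D65[3])
  rgb <- srgb_encode(xyz %*% t(.M_XYZ2RGB))
  pmin(pmax(rgb, 0), 1)
}

#' Mean CIELAB colour difference between two images
#'
#' Converts both images to CIELAB and computes the per-pixel Euclidean
#' distance `Delta E*ab`.  A Delta E near 1 is a just-noticeable difference;
#' an image pair with mean Delta E below `threshold` (default 5) reads as
#' visually the same.
#'
#' @param img_a,img_b RGB images of identical dimensions.
#' @param threshold Similarity threshold on the mean (default 5).
#' @return A `delta_e_report` list: `mean_delta_e`, `map` (H x W per-pixel
#'   distances), `frac_below_1`, `similar` (logical verdict), `threshold`.
#' @export
mean_delta_e <- function(img_a, img_b, threshold = 5) {
  validate_image(img_a, "img_a")
  validate_image(img_b, "img_b")
  if (!identical(dim(img_a), dim(img_b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  d <- dim(img_a)
  lab_a <- srgb_to_lab(matrix(img_a, ncol = 3))
  lab_b <- srgb_to_lab(matrix(img_b, ncol = 3))
  de <- sqrt(rowSums((lab_a - lab_b)^2))
  map <- matrix(de, nrow = d[1], ncol = d[2])
  structure(list(
    mean_delta_e = mean(de),
    map = map,
    frac_below_1 = mean(de < 1),
    similar = mean(de) < threshold,
    threshold = threshold
  ), class = "delta_e_report")
}

#' @export
print.delta_e_report <- function(x, ...) {
  cat(sprintf("mean Delta E*ab = %.4f (%.1f%% of pixels < 1): %s\n",
              x$mean_delta_e, 100 * x$frac_below_1,
              if (x$similar) "images appear the same" else "images differ"))
  invisible(x)
}

# ---- observer-session statistics -----------------------------------------

#' Read an observer-session table
#'
#' CSV with header `observer,image,repeat,tool,p1,...,p6`.  `tool` is `WTM`
#' (parameters `p1` = lambda, `p2` = k) or `control-point` (`p1`..`p6` the
#' six ordinates).  The `repeat` column is renamed `rep` internally.
#'
#' @param path CSV path.
#' @return Data frame with columns observer, image, rep, tool, p1..p6.
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[names(df) == "repeat"] <- "rep"
  need <- c("observer", "image", "rep", "tool")
  if (!all(need %in% names(df))) {
    stop("session table must have columns observer,image,repeat,tool", call. = FALSE)
  }
  df
}

# split a session table into complete (observer, image) repeat pairs
session_pairs <- function(sessions) {
  if (nrow(sessions) == 0L) stop("empty session table", call. = FALSE)
  key <- interaction(sessions$observer, sessions$image, drop = TRUE)
  groups <- split(seq_len(nrow(sessions)), key)
  bad <- vapply(groups, function(i) length(i) != 2L, logical(1))
  if (any(bad)) {
    warning(sum(bad), " (observer, image) group(s) without exactly 2 repeats skipped")
    groups <- groups[!bad]
  }
  if (length(groups) == 0L) stop("no complete repeat pairs in session table", call. = FALSE)
  groups
}

#' Intra-observer tool agreement
#'
#' For each observer, the proportion of repeated images on which the same
#' enhancement tool was chosen both times.
#'
#' @param sessions Session table (see [read_sessions()]); every
#'   (observer, image) pair should appear exactly twice.
#' @return List: `per_observer` (named proportions), `mean`, `sd`.
#' @export
agreement <- function(sessions) {
  groups <- session_pairs(sessions)
  match_tool <- vapply(groups, function(i) {
    sessions$tool[i[1]] == sessions$tool[i[2]]
  }, logical(1))
  obs <- vapply(groups, function(i) as.character(sessions$observer[i[1]]), character(1))
  per <- tapply(match_tool, obs, mean)
  list(per_observer = per, mean = mean(per), sd = stats::sd(per))
}

#' Coefficient of variation
#'
#' The standard deviation divided by the mean.  The population standard
#' deviation (divisor n) is the default; with only two repeats per image the
#' Bessel-corrected sample deviation would inflate every CV by sqrt(2).
#'
#' @param values Non-negative numeric values with non-zero mean.
#' @param sample Use the sample (n - 1) standard deviation instead.
#' @return Non-negative scalar; 0 iff all values are equal.
#' @export
coefficient_of_variation <- function(values, sample = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) stop("values must be non-missing", call. = FALSE)
  mu <- mean(values)
  if (mu == 0) stop("coefficient of variation undefined for zero mean", call. = FALSE)
  sigma <- if (sample) stats::sd(values) else sqrt(mean((values - mu)^2))
  sigma / mu
}

#' Mean coefficient of variation of tool parameters
#'
#' For repeated (observer, image) pairs enhanced with the same tool twice:
#' the CV of each parameter within the pair, averaged across pairs (MCV).
#' WTM pairs yield `mcv_lambda` and `mcv_k`; control-point pairs yield a
#' single `mcv_c`, the across-pair mean of the within-pair average CV over
#' the six ordinates.  Observers who never used the tool get `NA`, matching
#' the "-" convention in reporting.
#'
#' @param sessions Session table.
#' @param tool `"WTM"` or `"control-point"`.
#' @param sample Passed to [coefficient_of_variation()].
#' @return List: `per_observer` data frame and `overall` (MCV pooled over all
#'   pairs of all observers).
#' @export
mcv <- function(sessions, tool = c("WTM", "control-point"), sample = FALSE) {
  tool <- match.arg(tool)
  groups <- session_pairs(sessions)
  use <- vapply(groups, function(i) {
    sessions$tool[i[1]] == tool && sessions$tool[i[2]] == tool
  }, logical(1))
  npar <- if (tool == "WTM") 2L else 6L
  cvs <- lapply(groups[use], function(i) {
    p <- as.matrix(sessions[i, paste0("p", seq_len(npar)), drop = FALSE])
    apply(p, 2, coefficient_of_variation, sample = sample)
  })
  obs <- vapply(groups[use], function(i) as.character(sessions$observer[i[1]]), character(1))
  all_obs <- sort(unique(as.character(sessions$observer)))
  summarise <- function(sel) {
    if (!any(sel)) return(rep(NA_real_, if (tool == "WTM") 2L else 1L))
    m <- do.call(rbind, cvs[sel])
    if (tool == "WTM") colMeans(m) else mean(rowMeans(m))
  }
  per <- t(vapply(all_obs, function(o) summarise(obs == o),
                  numeric(if (tool == "WTM") 2L else 1L)))
  if (tool == "WTM") {
    per_df <- data.frame(observer = all_obs, mcv_lambda = per[, 1], mcv_k = per[, 2],
                         row.names = NULL)
    overall <- stats::setNames(summarise(rep(TRUE, length(cvs))), c("mcv_lambda", "mcv_k"))
  } else {
    per_df <- data.frame(observer = all_obs, mcv_c = per[, 1], row.names = NULL)
    overall <- stats::setNames(summarise(rep(TRUE, length(cvs))), "mcv_c")
  }
  list(per_observer = per_df, overall = overall)
}
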