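test_that("equalisation curve limit cases", {
  expect_equal(he_tonecurve(rep(1 / 256, 256)), (1:256) / 256)
  expect_equal(he_tonecurve(c(1, rep(0, 255))), rep(1, 256))
  h <- random_pdf(seed = 31)
  expect_equal(curve_slopes(he_tonecurve(h)), 256 * h, tolerance = 1e-12)
})

test_that("CLHE proxy respects slope bounds, fixes feasible inputs, and is idempotent", {
  # already-feasible histogram is untouched
  flat <- rep(1 / 256, 256)
  expect_equal(clhe_proxy(flat), flat)

  set.seed(5)
  for (i in 1:100) {
    h <- random_pdf(seed = 300 + i, concentration = 0.3)
    proxy <- clhe_proxy(h)
    slopes <- curve_slopes(cumulative(proxy))
    expect_true(all(slopes >= 0.5 - 1e-9 & slopes <= 2 + 1e-9))
    expect_lt(max(abs(clhe_proxy(proxy) - proxy)), 1e-12)
  }
  expect_error(clhe_proxy(flat, list(m = 1.5, M = 2)), "infeasible")
  expect_error(slope_bounds(0, 2), "0 < m")
})

test_that("CLHE proxy matches an alternating-projection oracle at small N", {
  bounds <- slope_bounds(0.5, 2)
  cases <- list(
    c(1, rep(0, 7)),                       # delta histogram
    rep(1 / 8, 8),                         # already flat
    c(0.4, 0.3, 0.1, 0.1, 0.05, 0.03, 0.01, 0.01)
  )
  set.seed(77)
  for (i in 1:10) cases[[length(cases) + 1]] <- random_pdf(n = 8, seed = 400 + i)
  for (h in cases) {
    mine <- clhe_proxy(h, bounds)
    oracle <- dykstra_projection(h, 0.5 / 8, 2 / 8)
    expect_lt(max(abs(mine - oracle)), 1e-6)
  }
})

test_that("Weibull tone curve: self-map is the identity, brighter targets brighten", {
  for (pp in list(c(0.8, 2), c(1.5, 5), c(2.5, 10))) {
    p <- weibull_params(pp[1], pp[2])
    s <- wtm_tonecurve(p, p)
    expect_lte(max(abs(s - (1:256) / 256)), 2 / 256)
  }
  p_in <- weibull_params(1.0, 4)
  s_up <- wtm_tonecurve(p_in, weibull_params(1.6, 4))
  expect_gte(mean(s_up), mean((1:256) / 256))
  s_down <- wtm_tonecurve(p_in, weibull_params(0.6, 4))
  expect_lte(mean(s_down), mean((1:256) / 256))
})

test_that("Weibull tone curve matches a CDF-bisection inversion oracle", {
  bisect_curve <- function(p_in, p_out, n = 256) {
    q <- weibull_cdf((1:n) / n, p_in)
    lo <- rep(0, n); hi <- rep(1, n)
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      below <- weibull_cdf(mid, p_out) < q
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    (lo + hi) / 2
  }
  for (pair in list(list(c(1.2, 4), c(0.9, 2.5)), list(c(0.5, 1.5), c(2, 8)))) {
    p_in <- weibull_params(pair[[1]][1], pair[[1]][2])
    p_out <- weibull_params(pair[[2]][1], pair[[2]][2])
    expect_lt(max(abs(wtm_tonecurve(p_in, p_out) - bisect_curve(p_in, p_out))), 1e-7)
  }
})

test_that("Weibull tone curves are monotone over random parameter pairs and compose", {
  set.seed(19)
  for (i in 1:200) {
    p1 <- weibull_params(runif(1, 0.1, 3), runif(1, 0.1, 15))
    p2 <- weibull_params(runif(1, 0.1, 3), runif(1, 0.1, 15))
    s <- wtm_tonecurve(p1, p2)
    expect_true(all(diff(s) >= 0) && all(s >= 0 & s <= 1))
  }
  # A->B then B->C agrees with A->C; the middle map is sampled densely so the
  # check measures composition consistency, not 256-node interpolation error
  a <- weibull_params(1.2, 4); b <- weibull_params(0.8, 2); cc <- weibull_params(2, 7)
  ab <- wtm_tonecurve(a, b)
  bc_fine <- wtm_tonecurve(b, cc, n = 65536L)
  ac <- wtm_tonecurve(a, cc)
  composed <- evaluate_tonecurve(bc_fine, ab)
  expect_lte(max(abs(composed - ac)), 2 / 256)
})

test_that("enhancement towards the input's own fit changes almost nothing", {
  img <- generate_seafloor_image(scene_spec(height = 64, width = 64, seed = 3))
  fit <- fit_weibull(compute_pdf(extract_brightness(img)))
  res <- wtm_enhance(img, fit$params)
  change <- abs(extract_brightness(res$image) - extract_brightness(img))
  expect_lte(mean(change), 2 / 256)
})

test_that("lowering target k increases brightness spread (contrast)", {
  img <- generate_seafloor_image(scene_spec(height = 64, width = 64,
                                            texture = weibull_params(1.2, 6),
                                            cone_gain = 0, seed = 4))
  fit <- fit_weibull(compute_pdf(extract_brightness(img)))
  res <- wtm_enhance(img, weibull_params(fit$params$lambda, fit$params$k - 3))
  expect_gt(sd(extract_brightness(res$image)), sd(extract_brightness(img)))
})

test_that("enhanced images fit back to the requested target within one grid step", {
  img <- generate_seafloor_image(scene_spec(height = 96, width = 96, cone_gain = 0, seed = 5))
  target <- weibull_params(0.9, 2.5)
  res <- wtm_enhance(img, target)
  refit <- fit_weibull(compute_pdf(extract_brightness(res$image)))
  expect_lte(abs(refit$params$lambda - target$lambda), 0.1 + 1e-12)
  expect_lte(abs(refit$params$k - target$k), 0.1 + 1e-12)
})

test_that("approximating an identical pair reproduces the input", {
  img <- generate_seafloor_image(scene_spec(height = 48, width = 48, seed = 6))
  res <- wtm_approximate(img, img)
  expect_lte(mean_delta_e(res$image, img)$mean_delta_e, 1)
  expect_error(wtm_approximate(img, img[1:32, 1:32, ]), "identical dimensions")
})

test_that("WTM-produced enhancements are recovered almost exactly", {
  img <- generate_seafloor_image(scene_spec(height = 96, width = 96, seed = 7))
  target <- weibull_params(1.4, 2.2)
  enhanced <- wtm_enhance(img, target)$image
  res <- wtm_approximate(img, enhanced)
  expect_lte(abs(res$fit_out$params$lambda - target$lambda), 0.1 + 1e-12)
  expect_lte(abs(res$fit_out$params$k - target$k), 0.1 + 1e-12)
  expect_lte(mean_delta_e(res$image, enhanced)$mean_delta_e, 5)
})

test_that("gentle control-point adjustments are approximated below the similarity threshold", {
  img <- generate_seafloor_image(scene_spec(height = 96, width = 96, seed = 8))
  adjusted <- generate_user_adjustment(img, "pchip",
                                       params = c(0, 0.15, 0.35, 0.55, 0.8, 1))
  res <- wtm_approximate(img, adjusted)
  expect_lt(mean_delta_e(res$image, adjusted)$mean_delta_e, 5)
})

test_that("PCHIP tone curves reproduce the identity, stay monotone, match the oracle", {
  ident <- pchip_tonecurve(control_points(seq(0, 1, by = 0.2)))
  expect_lt(max(abs(ident - (1:256) / 256)), 1e-12)

  y <- c(0, 0.1, 0.5, 0.7, 0.9, 1.0)
  curve <- pchip_tonecurve(control_points(y))
  oracle <- pchip_oracle(seq(0, 1, by = 0.2), y, (1:256) / 256)
  expect_lt(max(abs(curve - oracle)), 1e-9)
  # the interpolant passes through every control point
  expect_lt(max(abs(pchip_oracle(seq(0, 1, by = 0.2), y, seq(0, 1, by = 0.2)) - y)), 1e-12)
  expect_equal(evaluate_tonecurve(curve, 0.2), 0.1, tolerance = 1e-3)

  # matches the reference implementation in pracma too
  if (requireNamespace("pracma", quietly = TRUE)) {
    ref <- pracma::pchip(seq(0, 1, by = 0.2), y, (1:256) / 256)
    expect_lt(max(abs(curve - ref)), 1e-9)
  }

  set.seed(29)
  for (i in 1:50) {
    ords <- c(0, sort(runif(4, 0.02, 0.98)), 1)
    if (any(diff(ords) <= 0)) next
    s <- pchip_tonecurve(control_points(ords))
    expect_true(all(diff(s) >= -1e-12))
  }
  expect_error(control_points(c(0, 0.5, 0.4, 0.6, 0.8, 1)), "strictly increasing")
  expect_error(control_points(c(0, 0.2, 0.4, 0.6, 0.8)), "6 ordinate")
})
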