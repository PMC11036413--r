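test_that("the sigmoid strain factor passes through its anchors and bounds", {
  p <- strain_cv_params()
  expect_equal(g_strain(p$eps_ref, p), 1, tolerance = 1e-12)
  expect_equal(cvt_field(0.1665, 1, p), 0.30, tolerance = 1e-12)
  # analytic asymptotes of the law at unit density
  expect_equal(cvt_field(100, 1, p), p$cvt_ref + p$cvt_var / 2,
               tolerance = 1e-9)
  expect_equal(p$cvt_ref * g_strain(0, p),
               0.3 + 0.22 * tanh(-20.6 * 0.1665), tolerance = 1e-12)
  # strict monotonicity and bounds over a dense grid
  eps <- seq(0, 1, length.out = 400)
  g <- g_strain(eps, p)
  expect_true(all(diff(g) > 0))
  lo <- 1 - p$cvt_var / (2 * p$cvt_ref); hi <- 1 + p$cvt_var / (2 * p$cvt_ref)
  expect_true(all(g > lo & g < hi))
  expect_error(strain_cv_params(cvt_ref = 0.1, cvt_var = 0.44), "negative")
})

test_that("the CV_T field is annihilated by zero infarct density and linear in it", {
  p <- strain_cv_params()
  expect_identical(cvt_field(c(0.1, 0.2, 0.3), c(0, 0, 0), p), c(0, 0, 0))
  expect_equal(cvt_field(0.1665, 0.5, p), 0.15, tolerance = 1e-12)
  expect_error(cvt_field(c(0.1, 0.2), c(1, 1, 1), p), "length")
  expect_error(cvt_field(-0.1, 1, p), "nonnegative")
})

test_that("fitting recovers the generating parameters", {
  p0 <- strain_cv_params()
  eps <- seq(0.05, 0.28, length.out = 50)
  cv <- cvt_field(eps, rep(1, 50), p0)
  f <- fit_strain_cv(eps, cv, objective = "points")
  expect_equal(f$alpha, p0$alpha, tolerance = 0.01)
  expect_equal(f$eps_ref, p0$eps_ref, tolerance = 0.01)
  expect_gt(attr(f, "fit")$r_squared, 0.8)
  # recovery under additive noise (sd = 5% of the CV range) within 10%
  set.seed(42)
  cvn <- cv + rnorm(50, sd = 0.05 * diff(range(cv)))
  fn <- fit_strain_cv(eps, cvn, objective = "points")
  expect_lt(abs(fn$alpha / p0$alpha - 1), 0.10)
  expect_lt(abs(fn$eps_ref / p0$eps_ref - 1), 0.10)
  # two noiseless mid-range anchor points are interpolated by the line fit
  e2 <- c(0.15, 0.18); c2 <- cvt_field(e2, c(1, 1), p0)
  f2 <- fit_strain_cv(c(e2, mean(e2)), c(c2, cvt_field(mean(e2), 1, p0)),
                      objective = "line")
  pred <- cvt_field(e2, c(1, 1),
                    strain_cv_params(alpha = f2$alpha, eps_ref = f2$eps_ref))
  expect_equal(pred, c2, tolerance = 0.01)
  expect_error(fit_strain_cv(rep(0.1, 5), rep(0.3, 5)), "variance")
  expect_error(fit_strain_cv(c(0.1, 0.2), c(0.1, 0.3)), "3 paired samples")
})

test_that("CV_T discretization assigns bin centers and preserves zeros", {
  out <- discretize_cvt(c(0, 0.1, 0.5), n_levels = 2)
  expect_equal(as.numeric(out), c(0, 0.2, 0.4))
  # a uniform field is unchanged
  u <- discretize_cvt(rep(0.3, 10), n_levels = 9)
  expect_equal(as.numeric(u), rep(0.3, 10))
  # discretization error bounded by half a bin width
  set.seed(7)
  f <- runif(200, 0.05, 0.5)
  d <- discretize_cvt(f, n_levels = 9)
  bw <- diff(attr(d, "levels"))[1]
  expect_true(all(abs(d - f) <= bw / 2 + 1e-12))
  expect_warning(z <- discretize_cvt(c(0, 0, 0)), "all-zero")
  expect_equal(as.numeric(z), c(0, 0, 0))
})

test_that("field interpolation reproduces linear fields and respects bounds", {
  mc <- build_fixture("cable", 10, 1)
  mf <- build_fixture("cable", 10, 0.25)
  v <- 3 * mc$nodes[, 1] + 1
  vi <- interpolate_field(mc, v, mf)
  expect_equal(vi, 3 * mf$nodes[, 1] + 1, tolerance = 1e-9)
  expect_equal(interpolate_field(mc, rep(2.5, nrow(mc$nodes)), mf),
               rep(2.5, nrow(mf$nodes)), tolerance = 1e-12)
  # convexity: interpolated values bounded by the source field range
  set.seed(1)
  w <- runif(nrow(mc$nodes))
  wi <- interpolate_field(mc, w, mf)
  expect_true(all(wi >= min(w) - 1e-12 & wi <= max(w) + 1e-12))
  expect_error(interpolate_field(mc, v, matrix(c(50, 0, 0), 1)),
               "projection error")
  # 2D: coarse sheet onto a fine sheet (interior nodes, away from the
  # ragged lattice boundary)
  sc <- build_fixture("sheet", c(10, 10), 2)
  sf <- build_fixture("sheet", c(8, 8), 1)
  g <- sc$nodes[, 1] - 2 * sc$nodes[, 2]
  gi <- interpolate_field(sc, g, sf)
  sel <- sf$nodes[, 1] > 2 & sf$nodes[, 1] < 7 &
         sf$nodes[, 2] > 2 & sf$nodes[, 2] < 7
  expect_equal(gi[sel], (sf$nodes[, 1] - 2 * sf$nodes[, 2])[sel],
               tolerance = 1e-9)
})
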