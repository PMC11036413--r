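test_that("layer and border-zone conductance scalings compose as specified", {
  expect_equal(make_cell_params("endo", "remote")$gks_scale, 2.10)
  expect_equal(make_cell_params("sub_endo", "remote")$gks_scale, 0.95)
  expect_equal(make_cell_params("mid", "remote")$gks_scale, 1.30)
  p <- make_cell_params("epi", "structural_bz")
  expect_equal(p$gna_scale, 0.38)
  expect_equal(p$gcal_scale, 0.31)
  expect_equal(p$gkr_scale, 0.30)
  expect_equal(p$gks_scale, 2.45 * 0.20)
  # single border-zone phenotype switch drops the layer gradient
  q <- make_cell_params("epi", "structural_bz", bz_layer_gradient = FALSE)
  expect_equal(q$gks_scale, 0.20)
  expect_error(make_cell_params("outer", "remote"), "unknown layer")
  expect_error(make_cell_params("epi", "elsewhere"), "unknown region")
})

test_that("an unstimulated cell stays at rest", {
  tr <- pace_cell(make_cell_params("mid", "remote"),
                  pacing_spec(1, 1000, amplitude = 0), trace_stride = 10L)
  expect_lt(max(abs(tr$trace$vm - tr$trace$vm[1])), 1)
})

test_that("APD measurement recovers an analytic square pulse", {
  t <- seq(0, 400, by = 0.1)
  v <- ifelse(t >= 100 & t < 300, 0, -85)
  expect_equal(measure_apd(data.frame(t = t, vm = v), -70), 200,
               tolerance = 0.005)
  expect_error(measure_apd(data.frame(t = t, vm = rep(-85, length(t)))),
               "no upstroke")
  expect_error(measure_apd(data.frame(t = t, vm = ifelse(t >= 100, 0, -85))),
               "no repolarization")
})

test_that("steady pacing is converged and intrinsic APDs order with Gks", {
  trs <- lapply(c(endo = "endo", sub_endo = "sub_endo", mid = "mid",
                  epi = "epi"), steady_trace)
  apd75 <- vapply(trs, function(tr) measure_apd(tr, -75), numeric(1))
  # beat-to-beat convergence on the final two beats
  for (tr in trs) expect_lt(abs(diff(tail(tr$apd, 2))), 1)
  # monotonic: higher Gks scaling -> shorter APD
  gks <- c(endo = 2.10, sub_endo = 0.95, mid = 1.30, epi = 2.45)
  ord <- order(gks)
  expect_true(all(diff(apd75[ord]) < 0))
})

test_that("border-zone remodeling depresses upstroke velocity and peak voltage", {
  rem <- pace_cell(make_cell_params("mid", "remote"), pacing_spec(50, 600),
                   trace_stride = 1L)
  bz <- pace_cell(make_cell_params("mid", "structural_bz"),
                  pacing_spec(50, 600), trace_stride = 1L)
  up <- function(tr) max(diff(tr$trace$vm) / diff(tr$trace$t))
  # compare after the 2 ms stimulus artifact
  pk <- function(tr) max(tr$trace$vm[tr$trace$t > 3])
  expect_lt(up(bz), up(rem))
  expect_lt(pk(bz), pk(rem))
  # border-zone remodeling prolongs the action potential
  expect_gt(tail(bz$apd, 1), tail(rem$apd, 1))
})

test_that("steady-state checkpoints round-trip through CSV", {
  st <- cell_steady_state("mid", "remote", n_beats = 5, bcl = 600)
  f <- tempfile(fileext = ".csv")
  write_cell_checkpoints(f)
  df <- utils::read.csv(f)
  row <- df[df$layer == "mid" & df$region == "remote" & df$n_beats == 5, ]
  expect_equal(as.numeric(row[1, -(1:4)]), unname(st), tolerance = 1e-9)
})
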