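test_that("an unstimulated warm-started domain stays quiescent", {
  m <- build_fixture("cable", 10, 0.5)
  s6 <- tensor_rows_export(m$fibers, 0.2, 0.2)
  rec <- solve_monodomain(m, s6, cells = make_cell_params("mid", "remote"),
                          stimuli = list(), duration = 100,
                          early_stop = FALSE)
  expect_true(all(rec$n_act == 0))
  expect_lt(diff(range(rec$Vm)), 0.5)
})

test_that("a mid-cable stimulus produces symmetric activation times", {
  m <- build_fixture("cable", 20, 0.5)
  s6 <- tensor_rows_export(m$fibers, 0.2, 0.2)
  rec <- solve_monodomain(m, s6, cells = make_cell_params("mid", "remote"),
                          stimuli = list(stimulus_spec(c(10, 0, 0),
                                                       diameter = 2)),
                          duration = 120, early_stop = TRUE)
  at <- rec$act[, 1]
  expect_true(all(!is.na(at)))
  expect_equal(at, rev(at), tolerance = 1e-6)
})

test_that("conduction velocity scales as the square root of conductivity", {
  m <- build_fixture("cable", 20, 0.125)
  cvof <- function(sig) {
    s6 <- tensor_rows_export(m$fibers, sig, sig)
    rec <- solve_monodomain(m, s6, cells = make_cell_params("mid", "remote"),
                            stimuli = list(stimulus_spec(c(0, 0, 0),
                                                         diameter = 2.1)),
                            duration = 120, early_stop = TRUE)
    measure_cv(rec, m, c(6, 0, 0), c(14, 0, 0))
  }
  ratio <- cvof(0.4) / cvof(0.1)
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("CV measurement is exact on an analytic record and symmetric", {
  m <- build_fixture("cable", 20, 0.5)
  rec <- fake_record(m$nodes[, 1] / 0.6)  # t = x / v with v in mm/ms
  expect_equal(measure_cv(rec, m, c(4, 0, 0), c(16, 0, 0)), 0.6,
               tolerance = 1e-9)
  expect_equal(measure_cv(rec, m, c(16, 0, 0), c(4, 0, 0)), 0.6,
               tolerance = 1e-9)
  rec$act[m$nodes[, 1] > 15] <- NA
  expect_error(measure_cv(rec, m, c(4, 0, 0), c(18, 0, 0)), "unactivated")
})

test_that("conductivity calibration hits its targets and caches by resolution", {
  sig <- calibrate_conductivity(0.6, "longitudinal", resolution = 0.5)
  expect_equal(attr(sig, "measured"), 0.6, tolerance = 0.01)
  sig_t <- calibrate_conductivity(0.3, "transverse", resolution = 0.5)
  expect_equal(attr(sig_t, "measured"), 0.3, tolerance = 0.01)
  expect_lt(as.numeric(sig_t), as.numeric(sig))
  expect_error(calibrate_conductivity(0, resolution = 0.5), "positive")
  # lookup covers multiple levels; targets below the propagation limit of
  # the mesh spacing are extrapolated via the CV ~ sqrt(sigma) law
  lk <- conductivity_lookup(c(1e-4, 0.3, 0.6), resolution = 0.5,
                            length_mm = 10)
  expect_equal(length(lk), 3L)
  expect_true(attr(lk, "extrapolated")[1])
  expect_false(any(attr(lk, "extrapolated")[2:3]))
  expect_true(all(diff(lk) > 0))
})

test_that("assembled tensors respect fibers, cores, and isotropy", {
  m <- build_fixture("cable", 10, 0.5)
  lk <- c(0.05, 0.2); names(lk) <- c(sprintf("%.6f", 0.3), sprintf("%.6f", 0.6))
  n <- nrow(m$nodes)
  cvt <- rep(0.3, n); attr(cvt, "levels") <- 0.3
  s6 <- assemble_conductivity(m, 0.6, cvt, lk)
  # fibers along x: sigma_xx = sigma_L, sigma_yy = sigma_T
  expect_equal(unique(s6[, 1]), 0.2)
  expect_equal(unique(s6[, 2]), 0.05)
  expect_equal(unique(s6[, 4]), 0)
  # anisotropy ratio matches the calibrated ratio
  expect_equal(unique(s6[, 1] / s6[, 2]), 0.2 / 0.05)
  # core nodes produce exactly zero tensors
  cvt0 <- c(rep(0, 6), rep(0.3, n - 6)); attr(cvt0, "levels") <- 0.3
  s60 <- assemble_conductivity(m, 0.6, cvt0, lk)
  all_core <- rowSums(matrix(cvt0[m$elems] == 0, ncol = 2)) == 2
  expect_true(all(s60[all_core, ] == 0))
  expect_true(all(s60[!all_core, 1] > 0))
  # isotropic request gives a tensor proportional to the identity
  cvt_iso <- rep(0.6, n); attr(cvt_iso, "levels") <- 0.6
  s6i <- assemble_conductivity(m, 0.6, cvt_iso, lk)
  expect_equal(unique(s6i[, 1]), unique(s6i[, 2]))
  expect_equal(unique(s6i[, 6]), 0)
  # missing level -> informative error
  cvt_bad <- rep(0.45, n); attr(cvt_bad, "levels") <- 0.45
  expect_error(assemble_conductivity(m, 0.6, cvt_bad, lk), "missing")
})

test_that("temporal refinement changes the measured CV by less than 2%", {
  cw <- cable_wave()
  cvat <- function(dtus) {
    s6 <- tensor_rows_export(cw$mesh$fibers, cw$sigma, cw$sigma)
    rec <- solve_monodomain(cw$mesh, s6,
                            cells = make_cell_params("mid", "remote"),
                            stimuli = list(stimulus_spec(c(0, 0, 0),
                                                         diameter = 2.1)),
                            duration = 80, params = tissue_params(dt = dtus))
    measure_cv(rec, cw$mesh, c(6, 0, 0), c(14, 0, 0))
  }
  expect_equal(cvat(10) / cvat(20), 1, tolerance = 0.02)
})

test_that("electrotonic coupling narrows the transmural APD range", {
  fx <- transmural_cable()
  apd <- fx$record$rep[, 6] - fx$record$act[, 6]
  manifested <- diff(range(apd, na.rm = TRUE))
  intrinsic <- measure_apd(steady_trace("sub_endo"), -70) -
    measure_apd(steady_trace("epi"), -70)
  expect_lt(manifested, intrinsic)
  # manifested map increases monotonically from epi to endo end on average
  expect_gt(mean(apd[fx$mesh$transmural < 0.2]),
            mean(apd[fx$mesh$transmural > 0.8]))
})
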