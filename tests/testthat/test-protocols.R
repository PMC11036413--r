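test_that("VT detection reads sustained activity from activation records", {
  # no activations after S2
  rec <- fake_record(c(10, 20, 30), duration = 2000)
  expect_false(detect_vt(rec, 100, sustain = 800))
  # a single passage that extinguishes
  rec2 <- fake_record(cbind(c(10, 20, 30), c(150, 160, 170)),
                      duration = 2000)
  expect_false(detect_vt(rec2, 100, sustain = 800))
  # ongoing activity covering every 100 ms sub-window
  acts <- t(vapply(1:3, function(i) seq(150 + i * 10, 950, by = 90),
                   numeric(9)))
  expect_true(detect_vt(fake_record(acts, duration = 2000), 100,
                        sustain = 800))
  expect_error(detect_vt(rec, 1500, sustain = 800), "shorter")
})

test_that("the exit point is the earliest second post-S2 activation, ties to lowest index", {
  act <- rbind(c(110, 400), c(110, 350), c(110, 380))
  expect_equal(as.integer(locate_exit_point(fake_record(act), 100)), 2L)
  act_tie <- rbind(c(110, 400), c(110, 350), c(110, 350))
  expect_equal(as.integer(locate_exit_point(fake_record(act_tie), 100)), 2L)
  expect_error(locate_exit_point(fake_record(c(110, 120, 130)), 100),
               "second activation")
})

test_that("default pacing sites sit on the endocardium around the border zone", {
  lv <- assign_layers(build_lv_mesh(136, 44, resolution = 2.5))
  lv <- assign_infarct(lv, infarct_spec(angular_extent = 0.8))
  sites <- default_pacing_sites(lv, 6)
  expect_equal(length(unique(unlist(sites))), 6L)
  for (s in sites) {
    expect_lte(lv$transmural[s], 0.05)
    expect_true(lv$region[s] != "core")
  }
})

test_that("an empty site list yields an empty vulnerable window", {
  fx <- ring_fixture()
  s6 <- assemble_conductivity(fx$mesh, 0.6, fx$cvt_ref, fx$lk)
  vw <- scan_vulnerable_window(stress_test_spec(pacing_sites = list()),
                               build_model(fx$mesh, s6))
  expect_s3_class(vw, "sw_vulnerable_window")
  expect_equal(nrow(vw), 0L)
})

test_that("a homogeneous healthy sheet captures but induces no VT", {
  vw <- healthy_scan()
  expect_true(all(vw$outcome != "VT"))
  # refractoriness: the earliest scanned interval fails to capture
  expect_equal(vw$outcome[1], "no_capture")
  # bounds exist: a capturing interval was found, upper bound is the cap
  expect_true(any(vw$outcome == "no_VT"))
  expect_equal(unique(vw$upper), 310)
  expect_equal(attr(vw, "window_width_ms"), c(`1` = 0))
})

test_that("capture is monotone in the S2 interval on the annulus fixture", {
  for (v in c("reference", "extended")) {
    vw <- ring_scan(v)
    captured <- vw$outcome != "no_capture"
    if (any(captured)) {
      first <- min(which(captured))
      expect_true(all(captured[first:length(captured)]),
                  label = paste("monotone capture,", v))
    }
  }
})

test_that("sustained reentry on the annulus fixture is detected as VT with a located exit", {
  rec <- ring_vt_record()
  expect_true(detect_vt(rec, 0, sustain = 800))
  fx <- ring_fixture()
  ex <- locate_exit_point(rec, 0)
  # the exit point lies in the surviving annulus tissue on the slowed
  # region around the scar, not in the core and not in far-field tissue
  expect_false(fx$mesh$region[ex] == "core")
  expect_lt(fx$mesh$core_dist[ex], 4 + 6 + 2)
})

test_that("identical configuration reproduces the identical vulnerable window", {
  fx <- ring_fixture()
  s6 <- assemble_conductivity(fx$mesh, 0.6, fx$cvt_ref, fx$lk)
  spec <- ring_spec(fx)
  spec$s2_min <- 310; spec$s2_max <- 310
  a <- scan_vulnerable_window(spec, build_model(fx$mesh, s6))
  b <- scan_vulnerable_window(spec, build_model(fx$mesh, s6))
  expect_identical(as.data.frame(a), as.data.frame(b))
})
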