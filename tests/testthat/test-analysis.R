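test_that("repolarization maps select the requested beat and flag missing nodes", {
  cw <- cable_wave()
  rt <- repolarization_map(cw$record, c(0, 400))
  x <- cw$mesh$nodes[, 1]
  # a planar wave: repolarization times increase along the cable
  expect_true(all(diff(rt[order(x)]) > 0))
  # nodes that never activated are missing
  rec <- cw$record
  rec$act[1:3, ] <- NA; rec$rep[1:3, ] <- NA
  rt2 <- repolarization_map(rec, c(0, 400))
  expect_true(all(is.na(rt2[1:3])))
  expect_error(repolarization_map(cw$record, c(2000, 2400)), "no beat")
})

test_that("gradient recovery matches analytic and finite-difference values", {
  sl <- build_fixture("slab", c(10, 4, 4), 0.5)
  # uniform field: all magnitudes zero
  m0 <- rtg_map(rep(7, nrow(sl$nodes)), sl)
  expect_true(all(abs(m0$magnitude) < 1e-10))
  # linear field 12 ms/mm
  m1 <- rtg_map(12 * sl$nodes[, 1], sl)
  expect_equal(unique(round(m1$magnitude, 9)), 12)
  # smooth nonlinear field vs the analytic gradient on interior nodes
  f <- sl$nodes[, 1]^2 + 0.5 * sl$nodes[, 2]^2
  gan <- sqrt((2 * sl$nodes[, 1])^2 + sl$nodes[, 2]^2)
  m2 <- rtg_map(f, sl)
  inner <- sl$nodes[, 1] > 1 & sl$nodes[, 1] < 9 &
           sl$nodes[, 2] > 1 & sl$nodes[, 2] < 3 &
           sl$nodes[, 3] > 1 & sl$nodes[, 3] < 3
  err <- abs(m2$magnitude[inner] - gan[inner]) / gan[inner]
  expect_lt(max(err), 0.01)
  # a step concentrates gradient magnitude on the nodes flanking the jump
  step <- ifelse(sl$nodes[, 1] < 5, 0, 30)
  m3 <- rtg_map(step, sl)
  flank <- sl$nodes[, 1] %in% c(4.5, 5)   # elements spanning the jump
  expect_gt(min(m3$magnitude[flank]), 10)
  expect_lt(max(m3$magnitude[!flank]), 1e-9)
  # elements touching missing nodes are excluded
  fna <- f; fna[1] <- NA
  m4 <- rtg_map(fna, sl)
  expect_true(is.na(m4$magnitude[1]))
})

test_that("substrate metrics integrate volumes analytically", {
  sl <- build_fixture("slab", c(10, 10, 20), 1)  # 2 mL
  map <- rtg_map(12 * sl$nodes[, 1], sl)
  met <- rtg_metrics(map, threshold = 10)
  expect_equal(met$rtg_vol, 2, tolerance = 1e-9)
  expect_equal(met$rtg_mean, 12, tolerance = 1e-9)
  low <- rtg_metrics(rtg_map(5 * sl$nodes[, 1], sl), threshold = 10)
  expect_equal(low$rtg_vol, 0)
  expect_false(low$any_above)
  # analytic half/half gradient-magnitude map: half the volume above
  # threshold, mean exactly the high value
  half <- structure(list(
    magnitude = ifelse(sl$nodes[, 3] < 10, 15, 5),
    node_vol = sl$node_vol), class = "sw_rtg_map")
  mm <- rtg_metrics(half, threshold = 10)
  expect_equal(mm$rtg_vol,
               sum(sl$node_vol[sl$nodes[, 3] < 10]) / 1000,
               tolerance = 1e-9)
  expect_equal(mm$rtg_mean, 15, tolerance = 1e-12)
  # conservation: rtg_vol bounded by the domain volume; mean >= threshold
  expect_lte(mm$rtg_vol, mesh_volume(sl))
  expect_gte(mm$rtg_mean, 10)
  expect_error(rtg_metrics(map, threshold = -1), "nonnegative")
})

test_that("slow-conduction volume counts core and sub-threshold tissue", {
  sl <- build_fixture("slab", c(10, 10, 20), 1)
  n <- nrow(sl$nodes)
  expect_equal(slow_cv_volume(rep(0.3, n), sl), 0)
  cvt <- rep(0.3, n)
  sel <- sl$nodes[, 3] < 10
  cvt[sel] <- 0.08
  expect_equal(slow_cv_volume(cvt, sl), sum(sl$node_vol[sel]) / 1000,
               tolerance = 1e-9)
  cvt[sel] <- 0
  expect_equal(slow_cv_volume(cvt, sl, include_core = FALSE), 0)
  expect_gt(slow_cv_volume(cvt, sl, include_core = TRUE), 0.9)
})

test_that("the strain law extends the severely slowed volume beyond the scar", {
  # a functional border zone appears once border-zone strain amplitudes sit
  # below the 0.1 m/s iso-strain of the law (eps ~ 0.092 at defaults); the
  # reference model confines slow conduction to the structural zones
  sh <- build_fixture("sheet", c(30, 30), 0.6)
  sh$transmural <- rep(0.5, nrow(sh$nodes))
  sh <- assign_disc_infarct(sh, c(15, 15, 0), core_radius = 5,
                            bz_thickness = 4)
  eps <- generate_strain_field(sh, strain_profile_spec(
    eps_epi = 0.1665, eps_endo = 0.1665, bz_amplitude = 0.08,
    core_amplitude = 0.2, transition_width = 6))
  cvt_ref <- ifelse(sh$region == "core", 0,
                    ifelse(sh$region == "structural_bz", 0.08, 0.3))
  cvt_ext <- discretize_cvt(cvt_field(eps, sh$fact), 9)
  expect_gte(slow_cv_volume(as.numeric(cvt_ext), sh),
             slow_cv_volume(cvt_ref, sh))
})

test_that("CV_T histograms are volume-conserving", {
  sl <- build_fixture("slab", c(10, 10, 20), 1)
  n <- nrow(sl$nodes)
  h1 <- cvt_histogram(rep(0.3, n), sl)
  expect_equal(sum(h1$volume_ml), mesh_volume(sl), tolerance = 1e-9)
  expect_equal(sum(h1$volume_ml > 0), 1L)
  set.seed(3)
  cvt <- runif(n, 0.05, 0.5)
  d <- discretize_cvt(cvt, 9)
  h2 <- cvt_histogram(d, sl)
  expect_equal(sum(h2$volume_ml), mesh_volume(sl), tolerance = 1e-9)
  # healthy synthetic field: no volume below the healthy minimum
  sh <- build_fixture("sheet", c(10, 10), 1)
  eps <- generate_strain_field(sh, strain_profile_spec())
  cvt_h <- cvt_field(eps, sh$fact)
  h3 <- cvt_histogram(cvt_h, sh)
  lo <- cvt_field(strain_profile_spec()$eps_epi, 1)
  expect_equal(sum(h3$volume_ml[h3$upper < lo - 1e-9]), 0)
})
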