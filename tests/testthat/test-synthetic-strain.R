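test_that("healthy strain fields follow the transmural profile", {
  sh <- build_fixture("sheet", c(10, 10), 1)  # transmural along y
  spec <- strain_profile_spec(eps_epi = 0.12, eps_endo = 0.21)
  eps <- generate_strain_field(sh, spec)
  expect_equal(unique(eps[sh$transmural == 0]), 0.21, tolerance = 1e-12)
  expect_equal(unique(eps[sh$transmural == 1]), 0.12, tolerance = 1e-12)
  # monotone decrease endo -> epi
  expect_true(all(diff(tapply(eps, sh$transmural, mean)) < 1e-12))
})

test_that("border-zone strain plateaus at the depressed amplitude", {
  sh <- build_fixture("sheet", c(40, 20), 1)
  sh$transmural <- rep(0, nrow(sh$nodes))  # flat remote profile
  sh <- assign_disc_infarct(sh, c(20, 10, 0), core_radius = 4,
                            bz_thickness = 9)
  spec <- strain_profile_spec(eps_epi = 0.21, eps_endo = 0.21,
                              bz_amplitude = 0.15, core_amplitude = 0.25,
                              transition_width = 5)
  eps <- generate_strain_field(sh, spec)
  # mid-border-zone nodes (past the core blend, before the outer blend)
  mid_bz <- sh$core_dist > 3 & sh$core_dist < 8.9
  expect_true(all(abs(eps[mid_bz] - 0.15) < 1e-9))
  expect_true(all(abs(eps[sh$region == "core"] - 0.25) < 1e-9))
  # far remote unaffected
  far <- sh$core_dist > 9 + 5 + 1e-9
  expect_true(all(abs(eps[far] - 0.21) < 1e-9))
  # the functional border zone: depressed amplitudes just outside the
  # structural border zone
  halo <- sh$core_dist > 9 & sh$core_dist < 11
  expect_true(all(eps[halo] < 0.21 - 1e-6))
})

test_that("strain noise is seed-reproducible and smooth", {
  sh <- build_fixture("sheet", c(15, 15), 1)
  spec <- strain_profile_spec(noise_sd = 0.02, seed = 11)
  a <- generate_strain_field(sh, spec)
  b <- generate_strain_field(sh, spec)
  expect_identical(a, b)
  spec2 <- strain_profile_spec(noise_sd = 0.02, seed = 12)
  expect_false(identical(a, generate_strain_field(sh, spec2)))
  expect_true(all(a >= 0))
})

test_that("induced CV_T reproduces the transmural and infarct orderings", {
  # remote tissue: higher CV_T toward the endocardium
  sh <- build_fixture("sheet", c(10, 10), 0.5)
  eps <- generate_strain_field(sh, strain_profile_spec())
  cvt <- cvt_field(eps, sh$fact)
  endo <- cvt[sh$transmural < 0.1]; epi <- cvt[sh$transmural > 0.9]
  expect_gt(min(endo), max(epi))
  # healthy field never drops below the healthy transmural minimum
  expect_gte(min(cvt), cvt_field(strain_profile_spec()$eps_epi, 1) - 1e-12)
  # infarcted: depressed CV_T in the border zone and in the halo around it
  fx <- ring_fixture()
  cvt2 <- cvt_field(fx$eps, fx$mesh$fact)
  bz <- fx$mesh$region == "structural_bz"
  halo <- fx$mesh$region == "remote" & fx$mesh$core_dist < 4 + 4
  far <- fx$mesh$core_dist > 4 + 6 + 1
  expect_lt(max(cvt2[bz]), min(cvt2[far]))
  expect_lt(mean(cvt2[halo]), mean(cvt2[far]))
  expect_true(all(cvt2[fx$mesh$region == "core"] == 0))
})

test_that("invalid strain specifications are rejected", {
  expect_error(strain_profile_spec(eps_epi = 0.3, eps_endo = 0.2), ">=")
  expect_error(strain_profile_spec(core_amplitude = 0.1), "exceed")
  expect_error(strain_profile_spec(noise_sd = -1), "nonnegative")
})
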