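test_that("fixture meshes have the documented node counts and volumes", {
  cab <- build_fixture("cable", 20, 0.25)
  expect_equal(nrow(cab$nodes), 81L)
  expect_equal(mesh_volume(build_fixture("slab", c(20, 5, 5), 1)), 0.5,
               tolerance = 1e-12)
  sh <- build_fixture("sheet", c(20, 10), 0.5, cross_section = 2)
  # hexagonal lattice: realized height is rounded to whole rows
  expect_equal(mesh_volume(sh), 20 * max(sh$nodes[, 2]) * 2 / 1000,
               tolerance = 1e-9)
  for (m in list(cab, sh)) {
    expect_true(all(m$elem_vol > 0))
    expect_true(all(abs(sqrt(rowSums(m$fibers^2)) - 1) < 1e-9))
    expect_true(all(m$fact == 1))
  }
})

test_that("truncated-ellipsoid wall volume matches the requested volumes and converges", {
  lv <- build_lv_mesh(136, 44, resolution = 2.5)
  expect_equal(mesh_volume(lv), 136, tolerance = 0.01)
  e_coarse <- abs(mesh_volume(lv) - 136)
  e_fine <- abs(mesh_volume(build_lv_mesh(136, 44, resolution = 1.5)) - 136)
  expect_lt(e_fine, e_coarse)
  expect_true(all(lv$transmural >= 0 & lv$transmural <= 1))
  expect_true(all(lv$height >= -1e-9 & lv$height <= 1 + 1e-9))
})

test_that("degenerate volume requests raise geometric-infeasibility errors", {
  expect_error(build_lv_mesh(136, 0), "infeasibility")
  expect_error(build_lv_mesh(-1, 44), "infeasibility")
})

test_that("rule-based fibers are unit vectors with a linear transmural helix", {
  lv <- assign_fibers(build_lv_mesh(136, 44, resolution = 2.5), 60, -60)
  expect_true(all(abs(sqrt(rowSums(lv$fibers^2)) - 1) < 1e-9))
  # mid-wall elements have helix ~0: nearly circumferential fibers
  u_el <- rowMeans(matrix(lv$transmural[lv$elems], ncol = 4))
  mid <- which(abs(u_el - 0.5) < 0.02)
  ec <- lv$e_c[lv$elems[mid, 1], ]
  ang <- acos(pmin(abs(rowSums(lv$fibers[mid, ] * ec)), 1)) * 180 / pi
  expect_lt(median(ang), 8)
  # flat fixture with zero helix: fibers along the first axis
  sl <- build_fixture("slab", c(10, 4, 4), 1)
  expect_true(all(abs(sl$fibers[, 1] - 1) < 1e-12))
})

test_that("layer assignment bins the transmural coordinate and partitions volume", {
  cab <- build_fixture("cable", 10, 0.5)  # transmural = x/L
  cab <- assign_layers(cab, c(0.25, 0.25, 0.25, 0.25))
  expect_equal(cab$layer[cab$transmural == 0.1], "endo")
  expect_equal(cab$layer[cab$transmural == 0.9], "epi")
  all_endo <- assign_layers(cab, c(1, 0, 0, 0))
  expect_true(all(all_endo$layer == "endo"))
  expect_error(assign_layers(cab, c(0.5, 0.5, 0.5, -0.5)), "summing to 1|sum")
  lv <- assign_layers(build_lv_mesh(136, 44, resolution = 2.5))
  vols <- tapply(lv$node_vol, lv$layer, sum)
  expect_equal(sum(vols) / 1000, mesh_volume(lv), tolerance = 1e-9)
})

test_that("infarct labeling produces the distance-linear density ramp", {
  sh <- build_fixture("sheet", c(30, 30), 0.5)
  sh <- assign_disc_infarct(sh, c(15, 15, 0), core_radius = 5,
                            bz_thickness = 8)
  expect_true(all(sh$fact[sh$region == "core"] == 0))
  expect_true(all(sh$fact[sh$region == "remote"] == 1))
  # linear ramp: fact equals distance/thickness inside the border zone
  bz <- sh$region == "structural_bz"
  expect_equal(sh$fact[bz], sh$core_dist[bz] / 8, tolerance = 1e-12)
  expect_true(all(sh$fpas[sh$region == "core"] == 10))
  # regions partition the node set
  expect_equal(sort(unique(sh$region)),
               c("core", "remote", "structural_bz"))
  expect_equal(length(sh$region), nrow(sh$nodes))
  # monotone in the distance coordinate
  ord <- order(sh$core_dist)
  expect_true(all(diff(sh$fact[ord]) >= -1e-12))
})

test_that("LV infarct respects height/angular/transmural extents", {
  lv <- assign_layers(build_lv_mesh(136, 44, resolution = 2.5))
  m <- assign_infarct(lv, infarct_spec(height_extent = c(0.14, 0.51),
                                       transmurality = 1,
                                       angular_extent = 0.8))
  core <- m$region == "core"
  expect_true(any(core))
  expect_true(all(m$height[core] >= 0.14 - 1e-9 &
                  m$height[core] <= 0.51 + 1e-9))
  expect_true(all(m$fact[core] == 0))
  out <- m$region == "structural_bz"
  expect_true(all(m$core_dist[out] <= 9 + 1e-9))
  # a spec missing the mesh warns and leaves everything remote
  expect_warning(m2 <- assign_infarct(lv, infarct_spec(
    height_extent = c(0.98, 0.99), transmurality = 0.001,
    angular_extent = 1e-4)), "empty core")
  expect_true(all(m2$region == "remote"))
})
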