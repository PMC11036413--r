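# Shared, session-memoized fixtures. The heavier objects (conditioned cell
# trains, conductivity calibrations, the annulus reentry scans) are computed
# once and reused across test files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- expr
  .fx[[key]]
}

# steady-paced single-cell trace per layer (500 beats at BCL 600)
steady_trace <- function(layer, region = "remote") {
  memo(paste("trace", layer, region), {
    pace_cell(make_cell_params(layer, region), pacing_spec(500, 600),
              trace_stride = 1L)
  })
}

# annulus reentry fixture: a sheet with a central transmural scar disc and
# border zone; the extended variant carries the strain-derived CV_T halo
ring_fixture <- function() {
  memo("ring", {
    res <- 0.6
    sh <- build_fixture("sheet", c(34, 34), res)
    sh$layer <- rep("epi", nrow(sh$nodes))
    sh <- assign_disc_infarct(sh, c(17, 17, 0), core_radius = 7.5,
                              bz_thickness = 4)
    eps <- generate_strain_field(sh, strain_profile_spec(
      eps_epi = 0.1665, eps_endo = 0.1665, bz_amplitude = 0.12,
      core_amplitude = 0.25, transition_width = 6))
    cvt_ref <- ifelse(sh$region == "core", 0,
                      ifelse(sh$region == "structural_bz", 0.08, 0.3))
    attr(cvt_ref, "levels") <- c(0.08, 0.3)
    cvt_ext <- discretize_cvt(cvt_field(eps, sh$fact), 9)
    lk <- conductivity_lookup(
      sort(unique(c(0.08, 0.3, 0.6, attr(cvt_ext, "levels")))),
      resolution = res)
    list(mesh = sh, eps = eps, cvt_ref = cvt_ref, cvt_ext = cvt_ext,
         lk = lk, bottom = which(sh$nodes[, 2] <= 0.61),
         s2_site = c(3, 17, 0), res = res)
  })
}

ring_spec <- function(fx) {
  stress_test_spec(pacing_sites = list(fx$s2_site), n_s1 = 2, s1_bcl = 600,
                   s2_step = 15, s2_min = 310, s2_max = 370,
                   stim_diameter = 5, s1_nodes = fx$bottom)
}

ring_scan <- function(variant) {
  memo(paste("scan", variant), {
    fx <- ring_fixture()
    cvt <- if (variant == "reference") fx$cvt_ref else fx$cvt_ext
    s6 <- assemble_conductivity(fx$mesh, 0.6, cvt, fx$lk)
    scan_vulnerable_window(ring_spec(fx), build_model(fx$mesh, s6))
  })
}

# one sustained-reentry record on the extended annulus (S2 at 340 ms),
# for the VT-detection and exit-point checks
ring_vt_record <- function() {
  memo("vt_record", {
    fx <- ring_fixture()
    s6 <- assemble_conductivity(fx$mesh, 0.6, fx$cvt_ext, fx$lk)
    base <- solve_monodomain(fx$mesh, s6,
                             stimuli = list(stimulus_spec(nodes = fx$bottom)),
                             duration = 600, early_stop = FALSE)
    iv <- 340
    seg1 <- solve_monodomain(fx$mesh, s6,
                             stimuli = list(stimulus_spec(nodes = fx$bottom)),
                             duration = iv,
                             warm_start = list(Vm = base$Vm,
                                               states = base$states),
                             early_stop = FALSE)
    solve_monodomain(fx$mesh, s6,
                     stimuli = list(stimulus_spec(fx$s2_site, diameter = 5)),
                     duration = 900,
                     warm_start = list(Vm = seg1$Vm, states = seg1$states),
                     early_stop = TRUE)
  })
}

# healthy negative-control scan (uniform CV_T, no infarct)
healthy_scan <- function() {
  memo("healthy", {
    fx <- ring_fixture()
    sh <- build_fixture("sheet", c(22, 22), fx$res)
    sh$layer <- rep("epi", nrow(sh$nodes))
    s6 <- assemble_conductivity(sh, 0.6, rep(0.3, nrow(sh$nodes)), fx$lk)
    spec <- stress_test_spec(pacing_sites = list(c(2, 11, 0)), n_s1 = 2,
                             s1_bcl = 600, s2_step = 30, s2_min = 250,
                             s2_max = 310, stim_diameter = 5)
    scan_vulnerable_window(spec, build_model(sh, s6))
  })
}

# transmural cable with the four layer phenotypes coupled at CV_T = 0.3
transmural_cable <- function() {
  memo("cable44", {
    lv <- build_lv_mesh(136, 44, resolution = 2.5)
    wall <- attr(lv, "geometry")$wall_offset
    res <- 0.25
    cab <- assign_layers(build_fixture("cable", wall, res))
    sig <- as.numeric(calibrate_conductivity(0.3, "transverse",
                                             resolution = res))
    s6 <- tensor_rows_export(cab$fibers, sig, sig)
    stims <- lapply(0:5 * 600, function(on)
      stimulus_spec(c(0, 0, 0), diameter = 2.1, onset = on))
    rec <- solve_monodomain(cab, s6, stimuli = stims, duration = 4000,
                            early_stop = TRUE)
    list(mesh = cab, record = rec)
  })
}

# package-internal tensor helper, re-exported for fixtures
tensor_rows_export <- function(fibers, sl, st)
  getFromNamespace("tensor_rows", "strainwave")(fibers, sl, st)

# a simple propagated cable record with the mid-remote phenotype
cable_wave <- function() {
  memo("cable_wave", {
    m <- build_fixture("cable", 20, 0.5)
    sig <- as.numeric(calibrate_conductivity(0.6, resolution = 0.5))
    s6 <- tensor_rows_export(m$fibers, sig, sig)
    rec <- solve_monodomain(m, s6, cells = make_cell_params("mid", "remote"),
                            stimuli = list(stimulus_spec(c(0, 0, 0),
                                                         diameter = 2.1)),
                            duration = 400, early_stop = TRUE)
    list(mesh = m, record = rec, sigma = sig)
  })
}

# synthetic solution record with prescribed activation/repolarization times;
# act may be a vector (one beat) or an n x K matrix
fake_record <- function(act, rep = NULL, duration = 2000) {
  if (!is.matrix(act)) act <- matrix(act, ncol = 1)
  if (is.null(rep)) rep <- act + 200
  if (!is.matrix(rep)) rep <- matrix(rep, ncol = 1)
  n <- nrow(act)
  structure(list(act = act, rep = rep,
                 n_act = as.integer(rowSums(!is.na(act))), Vm = numeric(n),
                 states = matrix(0, n, 18), t_end = duration,
                 duration = duration, mesh_n = n),
            class = "sw_record")
}
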