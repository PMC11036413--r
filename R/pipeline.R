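#' Run configuration
#'
#' Builds the single nested configuration driving
#' \code{\link{run_pipeline}}. The reference model variant imposes the
#' piecewise-constant transverse conduction velocity (0.3 m/s remote,
#' 0.08 m/s structural border zone, 0 core); the extended variant derives
#' CV_T from the strain-CV law and discretizes it into level center values.
#'
#' @param geometry list: either \code{list(kind = "lv", wall_volume,
#'   cavity_volume, resolution, ...)} or \code{list(kind = "sheet"|"cable"|
#'   "slab", lengths, resolution)}.
#' @param infarct NULL or the arguments of \code{\link{infarct_spec}}.
#' @param strain arguments of \code{\link{strain_profile_spec}}.
#' @param strain_cv arguments of \code{\link{strain_cv_params}}.
#' @param model_variant "extended" or "reference".
#' @param cv_long longitudinal CV target (m/s).
#' @param n_levels CV_T discretization levels.
#' @param layers layer thickness fractions.
#' @param fibers list(helix_endo, helix_epi).
#' @param tissue arguments of \code{\link{tissue_params}}.
#' @param warm list(n_beats, bcl): single-cell conditioning train.
#' @param s1 list(site, n_s1, bcl): baseline-rhythm pacing used for the
#'   repolarization-gradient metrics.
#' @param stress NULL or arguments of \code{\link{stress_test_spec}}.
#' @param seed integer seed for every stochastic component.
#' @return object of class \code{sw_config} (a nested list).
#' @export
run_config <- function(geometry = list(kind = "sheet", lengths = c(20, 20),
                                       resolution = 0.5),
                       infarct = NULL,
                       strain = list(),
                       strain_cv = list(),
                       model_variant = c("extended", "reference"),
                       cv_long = 0.6, n_levels = 9,
                       layers = c(0.25, 0.25, 0.25, 0.25),
                       fibers = list(helix_endo = 60, helix_epi = -60),
                       tissue = list(),
                       warm = list(n_beats = 500, bcl = 600),
                       s1 = list(site = NULL, n_s1 = 2, bcl = 600),
                       stress = NULL,
                       seed = 1L) {
  model_variant <- match.arg(model_variant)
  cfg <- list(geometry = geometry, infarct = infarct, strain = strain,
              strain_cv = strain_cv, model_variant = model_variant,
              cv_long = cv_long, n_levels = n_levels, layers = layers,
              fibers = fibers, tissue = tissue, warm = warm, s1 = s1,
              stress = stress, seed = as.integer(seed))
  class(cfg) <- c("sw_config", "list")
  cfg
}

#' Serialize / parse a run configuration as YAML
#' @param config an \code{sw_config}.
#' @param file optional path; when NULL the YAML text is returned.
#' @export
write_config <- function(config, file = NULL) {
  txt <- yaml::as.yaml(unclass(config))
  if (!is.null(file)) { writeLines(txt, file); return(invisible(file)) }
  txt
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- yaml::yaml.load_file(file)
  do.call(run_config, x)
}

config_hash <- function(config) {
  f <- tempfile()
  writeLines(write_config(config), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

build_geometry_stage <- function(config) {
  g <- config$geometry
  if (identical(g$kind, "lv")) {
    mesh <- do.call(build_lv_mesh, g[setdiff(names(g), "kind")])
  } else {
    mesh <- build_fixture(g$kind, lengths = unlist(g$lengths),
                          resolution = g$resolution)
  }
  mesh <- assign_layers(mesh, unlist(config$layers))
  mesh <- assign_fibers(mesh, config$fibers$helix_endo,
                        config$fibers$helix_epi)
  if (!is.null(config$infarct))
    mesh <- assign_infarct(mesh, do.call(infarct_spec, config$infarct))
  mesh
}

cvt_stage <- function(mesh, config, strain) {
  if (config$model_variant == "reference") {
    cvt <- ifelse(mesh$region == "core", 0,
                  ifelse(mesh$region == "structural_bz", 0.08, 0.3))
    attr(cvt, "levels") <- sort(unique(cvt[cvt > 0]))
    cvt
  } else {
    params <- do.call(strain_cv_params, config$strain_cv)
    discretize_cvt(cvt_field(strain, mesh$fact, params),
                   n_levels = config$n_levels)
  }
}

#' Run the full simulation pipeline
#'
#' Executes the stages in order — geometry, synthetic strain, CV_T field,
#' conductivity calibration, monodomain baseline (S1) simulation,
#' substrate metrics, optional S1-S2 stress test — writing every
#' intermediate field plus a metrics CSV/JSON and a run log to
#' \code{outdir}. Deterministic given identical config and seed.
#'
#' @param config an \code{\link{run_config}}.
#' @param outdir output directory (created if needed); NULL writes nothing.
#' @return list with the mesh, strain and CV_T fields, the S1 record, the
#'   metrics, and (when enabled) the vulnerable window.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sw_config"))
  t0 <- Sys.time()
  hash <- config_hash(config)
  log <- c(sprintf("run %s", hash),
           sprintf("package strainwave %s",
                   as.character(utils::packageVersion("strainwave"))),
           sprintf("seed %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed (config %s): %s", name, hash,
                   conditionMessage(e)), call. = FALSE))
  }
  mesh <- stage("geometry", build_geometry_stage(config))
  sspec <- stage("strain", do.call(strain_profile_spec,
                                   c(config$strain,
                                     list(seed = config$seed))))
  strain <- stage("strain", generate_strain_field(mesh, sspec))
  cvt <- stage("cvt", cvt_stage(mesh, config, strain))
  res <- stage("calibration", {
    cell <- make_cell_params("mid", "remote")
    levels <- sort(unique(c(attr(cvt, "levels"), config$cv_long)))
    conductivity_lookup(levels, resolution = mesh$resolution, cell = cell)
  })
  sigma6 <- stage("assembly",
                  assemble_conductivity(mesh, config$cv_long, cvt, res))
  tp <- do.call(tissue_params, config$tissue)
  model <- build_model(mesh, sigma6, tp,
                       n_beats_warm = config$warm$n_beats,
                       bcl_warm = config$warm$bcl)
  # baseline rhythm: S1 train at one site, repolarization metrics of the
  # last beat
  site <- config$s1$site
  if (is.null(site)) {
    site <- if (!is.null(mesh$core_dist)) default_pacing_sites(mesh, 1)[[1]]
            else 1L
  }
  n_s1 <- config$s1$n_s1
  bcl <- config$s1$bcl
  stims <- lapply(seq_len(n_s1) - 1, function(b)
    stimulus_spec(site, onset = b * bcl))
  rec <- stage("simulate", solve_monodomain(
    mesh, sigma6, stimuli = stims,
    duration = n_s1 * bcl, params = tp, warm_start = TRUE,
    n_beats_warm = config$warm$n_beats, bcl_warm = config$warm$bcl))
  last_onset <- (n_s1 - 1) * bcl
  rt <- stage("metrics", repolarization_map(rec,
                                            c(last_onset, last_onset + bcl)))
  map <- rtg_map(rt, mesh)
  met <- rtg_metrics(map)
  metrics <- data.frame(
    run = hash, variant = config$model_variant, site = site[1],
    rtg_vol = met$rtg_vol, rtg_mean = met$rtg_mean,
    slow_volume = slow_cv_volume(cvt, mesh))
  out <- list(mesh = mesh, strain = strain, cvt = cvt, record = rec,
              rt = rt, rtg = map, metrics = metrics,
              calibration = res, config = config, hash = hash)
  if (!is.null(config$stress)) {
    sargs <- config$stress
    if (is.null(sargs$pacing_sites))
      sargs$pacing_sites <- default_pacing_sites(mesh)
    spec <- do.call(stress_test_spec, sargs)
    out$vulnerable_window <- stage("stresstest",
                                   scan_vulnerable_window(spec, model))
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_vtu(mesh, file.path(outdir, "mesh.vtu"),
              point_data = list(strain_amplitude = strain,
                                cvt = as.numeric(cvt), repol_time = rt,
                                rtg = map$magnitude))
    write_field_csv(as.numeric(cvt), file.path(outdir, "cvt.csv"))
    write_field_csv(strain, file.path(outdir, "strain.csv"))
    utils::write.csv(metrics, file.path(outdir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(as.list(metrics),
                           list(config_hash = hash)),
                         file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(out$vulnerable_window))
      utils::write.csv(as.data.frame(out$vulnerable_window),
                       file.path(outdir, "vulnerable_window.csv"),
                       row.names = FALSE)
    log <- c(log, sprintf("elapsed %.1f s",
                          as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    writeLines(log, file.path(outdir, "run.log"))
  }
  out
}

#' Sensitivity sweep over the strain-CV parameters
#'
#' Re-runs the baseline-rhythm substrate metrics for one-at-a-time
#' variations of the sensitivity constant alpha and the reference strain
#' amplitude, each expressed as a factor of its default. The baseline
#' setting is counted once. Optionally adds paired settings in which
#' larger reference strains combine with smaller alpha (overlapping-curve
#' settings).
#'
#' @param config base \code{\link{run_config}} (extended variant).
#' @param alpha_factors,eps_ref_factors multiplicative factors.
#' @param paired also run zip(largest eps factor, smallest alpha factor)
#'   combinations.
#' @return data.frame: one row per distinct setting with the metrics.
#' @export
sweep_sensitivity <- function(config,
                              alpha_factors = c(0.5, 0.7, 1, 1.5, 2.5),
                              eps_ref_factors = c(1.22, 1.11, 1, 0.89, 0.78),
                              paired = FALSE) {
  base <- do.call(strain_cv_params, config$strain_cv)
  settings <- unique(rbind(
    data.frame(fa = alpha_factors, fe = 1),
    data.frame(fa = 1, fe = eps_ref_factors),
    if (paired) data.frame(fa = sort(alpha_factors),
                           fe = sort(eps_ref_factors, decreasing = TRUE))))
  rows <- lapply(seq_len(nrow(settings)), function(i) {
    cfg <- config
    cfg$strain_cv <- list(cvt_ref = base$cvt_ref, cvt_var = base$cvt_var,
                          alpha = base$alpha * settings$fa[i],
                          eps_ref = base$eps_ref * settings$fe[i])
    res <- run_pipeline(cfg, outdir = NULL)
    cbind(alpha_factor = settings$fa[i], eps_ref_factor = settings$fe[i],
          res$metrics)
  })
  do.call(rbind, rows)
}
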