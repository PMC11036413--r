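#' Tissue-level parameters of the monodomain model
#'
#' @param beta membrane surface-to-volume ratio (um^-1).
#' @param cm membrane capacitance (uF/cm^2).
#' @param dt time step (us).
#' @return object of class \code{sw_tissue_params}.
#' @export
tissue_params <- function(beta = 0.14, cm = 1, dt = 20) {
  if (beta <= 0 || cm <= 0 || dt <= 0)
    stop("beta, cm and dt must be positive")
  structure(list(beta = beta, cm = cm, dt = dt),
            class = "sw_tissue_params")
}

#' Stimulus specification
#'
#' @param center stimulus center: a node index (integer) or a coordinate
#'   (numeric length 3); alternatively supply \code{nodes} directly.
#' @param diameter stimulated-area diameter (mm).
#' @param amplitude stimulus amplitude (uA/cm^2).
#' @param duration stimulus duration (ms).
#' @param onset stimulus onset time (ms).
#' @param nodes optional explicit node-index set (overrides center/diameter),
#'   e.g. for planar stimuli.
#' @return object of class \code{sw_stimulus}.
#' @export
stimulus_spec <- function(center = NULL, diameter = 3, amplitude = 40,
                          duration = 2, onset = 0, nodes = NULL) {
  if (diameter <= 0 || duration <= 0)
    stop("diameter and duration must be positive")
  if (is.null(center) && is.null(nodes))
    stop("either center or nodes must be given")
  structure(list(center = center, diameter = diameter,
                 amplitude = amplitude, duration = duration, onset = onset,
                 nodes = nodes),
            class = "sw_stimulus")
}

stimulus_nodes <- function(mesh, stim) {
  if (!is.null(stim$nodes)) return(as.integer(stim$nodes))
  if (is.integer(stim$center) || (is.numeric(stim$center) &&
                                  length(stim$center) == 1)) {
    ctr <- mesh$nodes[as.integer(stim$center), ]
  } else {
    ctr <- rep_len(as.numeric(stim$center), 3)
  }
  d <- sqrt(colSums((t(mesh$nodes) - ctr)^2))
  idx <- which(d <= stim$diameter / 2)
  if (!length(idx)) idx <- which.min(d)
  as.integer(idx)
}

# per-element transversely isotropic tensor rows (xx,yy,zz,xy,xz,yz)
tensor_rows <- function(fibers, sigma_l, sigma_t) {
  f <- fibers
  cbind(sigma_t + (sigma_l - sigma_t) * f[, 1]^2,
        sigma_t + (sigma_l - sigma_t) * f[, 2]^2,
        sigma_t + (sigma_l - sigma_t) * f[, 3]^2,
        (sigma_l - sigma_t) * f[, 1] * f[, 2],
        (sigma_l - sigma_t) * f[, 1] * f[, 3],
        (sigma_l - sigma_t) * f[, 2] * f[, 3])
}

#' Solve the monodomain equation
#'
#' Operator-split integration of the monodomain reaction-diffusion
#' equation: explicit (lumped-mass finite-element) diffusion and
#' Rush-Larsen/forward-Euler membrane kinetics, both at the tissue time
#' step, with the zero-flux boundary condition implied by the FEM
#' assembly. Records per-node activation times (time of maximum upstroke
#' velocity per beat) and repolarization times (-70 mV downward crossing).
#'
#' @param mesh an \code{sw_mesh} with fibers.
#' @param sigma6 per-element conductivity tensors (m x 6 upper-triangle
#'   rows, mS/mm), e.g. from \code{\link{assemble_conductivity}}.
#' @param cells either a single \code{sw_cell_params} or NULL to derive
#'   per-node phenotypes from the mesh's layer/region labels.
#' @param stimuli list of \code{\link{stimulus_spec}}.
#' @param duration simulation duration (ms).
#' @param params \code{\link{tissue_params}}.
#' @param warm_start use steady-paced cell states (default) rather than
#'   resting initial conditions; may also be a list with elements
#'   \code{Vm} (n) and \code{states} (n x 18) to continue a previous run.
#' @param n_beats_warm,bcl_warm conditioning-train protocol behind the
#'   warm start.
#' @param snapshot_stride record Vm snapshots every this many steps
#'   (0 = none).
#' @param t_offset time offset added to all recorded times (for chained
#'   runs).
#' @param early_stop stop once the tissue is quiescent and no stimulus is
#'   pending.
#' @return an \code{sw_record}: list with \code{act}/\code{rep} (n x K
#'   matrices of per-beat activation/repolarization times, ms),
#'   \code{n_act} counts, final \code{Vm}/\code{states}, \code{t_end},
#'   \code{duration} and optional snapshots.
#' @export
solve_monodomain <- function(mesh, sigma6, cells = NULL, stimuli = list(),
                             duration = 500, params = tissue_params(),
                             warm_start = TRUE, n_beats_warm = 500,
                             bcl_warm = 600, snapshot_stride = 0L,
                             t_offset = 0, early_stop = TRUE) {
  validate_mesh(mesh)
  n <- nrow(mesh$nodes)
  # per-node conductance scalings
  if (inherits(cells, "sw_cell_params")) {
    sc <- matrix(rep(scales_vector(cells), each = n), n, 4)
    pheno <- data.frame(layer = cells$layer, region = cells$region)[rep(1, n), ]
  } else {
    if (is.null(mesh$layer) || is.null(mesh$region))
      stop("mesh lacks layer/region labels and no cell params given")
    pheno <- data.frame(layer = mesh$layer, region = mesh$region)
    sc <- matrix(0, n, 4)
    for (key in unique(paste(pheno$layer, pheno$region))) {
      parts <- strsplit(key, " ")[[1]]
      idx <- pheno$layer == parts[1] & pheno$region == parts[2]
      reg <- if (parts[2] == "core") "remote" else parts[2]
      sc[idx, ] <- matrix(rep(scales_vector(make_cell_params(parts[1], reg)),
                              each = sum(idx)), sum(idx), 4)
    }
  }
  # initial state
  if (is.list(warm_start) && !is.null(warm_start$states)) {
    V0 <- warm_start$Vm; S0 <- warm_start$states
  } else {
    V0 <- numeric(n); S0 <- matrix(0, n, 18)
    if (isTRUE(warm_start)) {
      for (key in unique(paste(pheno$layer, pheno$region))) {
        parts <- strsplit(key, " ")[[1]]
        idx <- paste(pheno$layer, pheno$region) == key
        reg <- if (parts[2] == "core") "remote" else parts[2]
        st <- cell_steady_state(parts[1], reg, n_beats_warm, bcl_warm)
        V0[idx] <- st[1]
        S0[idx, ] <- matrix(rep(st[-1], each = sum(idx)), sum(idx), 18)
      }
    } else {
      st <- cell_initial_state()
      V0[] <- st[1]
      S0 <- matrix(rep(st[-1], each = n), n, 18)
    }
  }
  lap <- diffusion_operator(mesh, sigma6, beta = params$beta, cm = params$cm)
  stim_nodes <- lapply(stimuli, function(s) stimulus_nodes(mesh, s))
  res <- monodomain_cpp(
    V0, S0, sc, lap$p, lap$j, lap$x,
    stim_nodes,
    vapply(stimuli, `[[`, numeric(1), "amplitude"),
    vapply(stimuli, `[[`, numeric(1), "onset"),
    vapply(stimuli, `[[`, numeric(1), "duration"),
    params$dt / 1000, duration, 32L, as.integer(snapshot_stride),
    -60, -70, early_stop)
  rec <- list(act = res$act + t_offset, rep = res$rep + t_offset,
              n_act = res$n_act, Vm = res$Vm, states = res$states,
              t_end = res$t_end + t_offset,
              duration = duration + t_offset, mesh_n = n)
  if (!is.null(res$snapshots)) {
    rec$snapshots <- res$snapshots
    rec$snapshot_times <- res$snapshot_times + t_offset
  }
  class(rec) <- "sw_record"
  rec
}

#' @export
print.sw_record <- function(x, ...) {
  cat(sprintf("sw_record: %d nodes, t_end %.1f ms, %d/%d nodes activated\n",
              x$mesh_n, x$t_end, sum(x$n_act > 0), x$mesh_n))
  invisible(x)
}

# merge two chained records (b continues a)
merge_records <- function(a, b) {
  n <- a$mesh_n
  K <- ncol(a$act)
  act <- matrix(NA_real_, n, K); rep_ <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    ta <- c(a$act[i, !is.na(a$act[i, ])], b$act[i, !is.na(b$act[i, ])])
    tr <- c(a$rep[i, !is.na(a$rep[i, ])], b$rep[i, !is.na(b$rep[i, ])])
    act[i, seq_len(min(K, length(ta)))] <- ta[seq_len(min(K, length(ta)))]
    rep_[i, seq_len(min(K, length(tr)))] <- tr[seq_len(min(K, length(tr)))]
  }
  structure(list(act = act, rep = rep_, n_act = a$n_act + b$n_act,
                 Vm = b$Vm, states = b$states, t_end = b$t_end,
                 duration = b$duration, mesh_n = n), class = "sw_record")
}

#' Measure planar conduction velocity between two probes
#'
#' CV = distance / activation-time difference, with activation times
#' linearly interpolated from the nodes surrounding each probe.
#'
#' @param record an \code{sw_record}.
#' @param mesh the mesh the record was computed on.
#' @param probe_a,probe_b probe coordinates (numeric length <= 3).
#' @param beat which activation to use (default first).
#' @return conduction velocity in m/s (mm/ms).
#' @export
measure_cv <- function(record, mesh, probe_a, probe_b, beat = 1L) {
  at <- record$act[, beat]
  miss <- is.na(at)
  if (all(miss)) stop("measurement error: no activated nodes")
  # interpolate activation times at the probes (nodes with NA excluded by
  # erroring if the enclosing element is unactivated)
  pts <- rbind(rep_len(as.numeric(probe_a), 3),
               rep_len(as.numeric(probe_b), 3))
  bc <- barycentric_coords(mesh, pts)
  tt <- numeric(2)
  for (q in 1:2) {
    vids <- mesh$elems[bc$elem[q], ]
    if (any(is.na(at[vids])))
      stop("measurement error: probe ", q, " in unactivated tissue")
    lam <- pmax(bc$lambda[q, ], 0); lam <- lam / sum(lam)
    tt[q] <- sum(at[vids] * lam)
  }
  dist <- sqrt(sum((pts[1, ] - pts[2, ])^2))
  dtv <- abs(tt[2] - tt[1])
  if (dtv <= 0) stop("measurement error: zero activation-time difference")
  dist / dtv
}

# session cache for conductivity calibration
.calib_cache <- new.env(parent = emptyenv())

#' Calibrate a conductivity eigenvalue against a conduction-velocity target
#'
#' Bisection on the monodomain conductivity, each iterate measured by a
#' planar-wave simulation on a thin cable fixture at the stated resolution,
#' until the measured CV is within the relative tolerance of the target.
#' Because the numerically manifested CV depends on the mesh spacing, the
#' calibration (and its session cache) is keyed by resolution.
#'
#' @param target_cv target conduction velocity (m/s).
#' @param direction "longitudinal" or "transverse" (cache key only; the
#'   planar-wave calibration itself is direction-agnostic).
#' @param resolution mesh spacing of the fixture (mm).
#' @param cell \code{sw_cell_params} phenotype carried by the fixture.
#' @param tol relative CV tolerance.
#' @param length_mm fixture length.
#' @param params \code{\link{tissue_params}}.
#' @return calibrated conductivity (mS/mm), with attribute \code{measured}.
#' @export
calibrate_conductivity <- function(target_cv,
                                   direction = c("longitudinal",
                                                 "transverse"),
                                   resolution = 0.5,
                                   cell = make_cell_params("mid", "remote"),
                                   tol = 0.005, length_mm = 20,
                                   params = tissue_params()) {
  direction <- match.arg(direction)
  if (target_cv <= 0)
    stop("calibration failure: target CV must be positive")
  key <- paste(signif(target_cv, 8), resolution, cell$layer, cell$region,
               sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])

  measure <- function(sig) {
    mesh <- build_fixture("cable", length_mm, resolution)
    s6 <- tensor_rows(mesh$fibers, sig, sig)
    dur <- min(0.75 * length_mm / (0.3 * target_cv) + 50, 2500)
    rec <- tryCatch(solve_monodomain(
      mesh, s6, cells = cell,
      stimuli = list(stimulus_spec(c(0, 0, 0), diameter = 2.1)),
      duration = dur, params = params, early_stop = TRUE),
      error = function(e) NULL)
    if (is.null(rec)) return(Inf)   # diffusion blow-up: sigma far too large
    # excitation failure (stimulus charge diffused away): also sigma-too-large
    if (all(rec$n_act == 0)) return(Inf)
    pa <- c(0.3 * length_mm, 0, 0); pb <- c(0.7 * length_mm, 0, 0)
    tryCatch(measure_cv(rec, mesh, pa, pb), error = function(e) 0)
  }
  # explicit-diffusion stability cap for the bracket (D < h^2 / (2 dt))
  beta_cm <- (params$beta * 1000) * (params$cm / 100)
  sig_cap <- 0.35 * resolution^2 / (params$dt / 1000) * beta_cm

  # initial guess from the CV ~ sqrt(sigma) scaling of a reference point
  sig0 <- 0.1
  cv0 <- measure(sig0)
  if (cv0 <= 0 || !is.finite(cv0)) { sig0 <- 0.02; cv0 <- measure(sig0) }
  if (cv0 <= 0 || !is.finite(cv0))
    stop("calibration failure: no propagation in bracket probe")
  sig <- sig0 * (target_cv / cv0)^2
  lo <- sig / 16; hi <- min(sig * 8, sig_cap)
  cv_lo <- measure(lo); cv_hi <- measure(hi)
  tries <- 0
  while (cv_lo > target_cv && tries < 6) { lo <- lo / 8; cv_lo <- measure(lo); tries <- tries + 1 }
  while (cv_hi < target_cv && hi < sig_cap && tries < 12) {
    hi <- min(hi * 8, sig_cap); cv_hi <- measure(hi); tries <- tries + 1
  }
  if (cv_lo > target_cv || cv_hi < target_cv)
    stop(sprintf(
      "calibration failure: target %.3f m/s outside bracket [%g, %g] mS/mm (measured %.3f..%.3f m/s)",
      target_cv, lo, hi, cv_lo, cv_hi))
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    cv <- measure(mid)
    if (is.finite(cv) && cv > 0 &&
        abs(cv - target_cv) / target_cv < tol) {
      out <- structure(mid, measured = cv, resolution = resolution)
      .calib_cache[[key]] <- out
      return(out)
    }
    if (cv < target_cv) lo <- mid else hi <- mid
  }
  stop("calibration failure: bisection did not converge; bracket [",
       lo, ", ", hi, "]")
}

#' Calibration lookup for a set of CV levels
#'
#' @param targets CV targets (m/s); zeros are skipped (zero conductivity).
#' @inheritParams calibrate_conductivity
#' @return named numeric vector, conductivity (mS/mm) per target level.
#' @export
conductivity_lookup <- function(targets, resolution = 0.5,
                                cell = make_cell_params("mid", "remote"),
                                ...) {
  targets <- sort(unique(targets[targets > 0]), decreasing = TRUE)
  out <- numeric(length(targets))
  extrap <- logical(length(targets))
  anchor <- NULL
  for (i in seq_along(targets)) {
    tg <- targets[i]
    if (is.null(anchor)) {
      sig <- tryCatch(calibrate_conductivity(tg, resolution = resolution,
                                             cell = cell, ...),
                      error = function(e) NULL)
      if (!is.null(sig)) { out[i] <- as.numeric(sig); next }
      # below the propagation limit of this mesh spacing: extrapolate all
      # remaining (slower) levels from the slowest calibrated level via
      # the CV ~ sqrt(sigma) law
      if (i == 1)
        stop("calibration failure: no target level propagates at ",
             resolution, " mm")
      anchor <- c(sigma = out[i - 1], cv = targets[i - 1])
    }
    out[i] <- anchor[["sigma"]] * (tg / anchor[["cv"]])^2
    extrap[i] <- TRUE
  }
  ord <- order(targets)
  out <- out[ord]; extrap <- extrap[ord]
  names(out) <- format_cv(targets[ord])
  attr(out, "extrapolated") <- extrap
  out
}

format_cv <- function(x) sprintf("%.6f", x)

#' Assemble per-element anisotropic conductivity tensors
#'
#' Builds the transversely isotropic tensor
#' sigma = sigma_L f f' + sigma_T (I - f f') per element from the
#' longitudinal CV target and a per-node transverse CV field, using a
#' calibration lookup. Elements whose nodes are all in the infarct core
#' (CV_T = 0) receive an exactly zero tensor; other elements take the mean
#' of their nodes' positive CV_T snapped to the nearest calibrated level.
#'
#' @param mesh \code{sw_mesh} with fibers.
#' @param cv_long longitudinal CV (m/s), scalar.
#' @param cvt per-node transverse CV field (m/s), e.g. a discretized field
#'   from \code{\link{discretize_cvt}}.
#' @param calibration named conductivity lookup from
#'   \code{\link{conductivity_lookup}}; must cover \code{cv_long} and all
#'   positive CV_T levels.
#' @return m x 6 tensor rows (mS/mm).
#' @export
assemble_conductivity <- function(mesh, cv_long, cvt, calibration) {
  if (is.null(mesh$fibers)) stop("mesh has no fibers")
  if (length(cvt) != nrow(mesh$nodes))
    stop("cvt field length does not match mesh")
  # snap element values to the field's own discretization levels when
  # present (a calibration lookup may cover a superset of levels)
  levels <- attr(cvt, "levels")
  if (is.null(levels)) levels <- as.numeric(names(calibration))
  need <- format_cv(cv_long)
  if (!need %in% names(calibration))
    stop("calibration missing longitudinal level ", cv_long)
  el <- mesh$elems; k <- ncol(el)
  cvt_el <- matrix(cvt[el], ncol = k)
  pos_mean <- apply(cvt_el, 1, function(z) {
    p <- z[z > 0]
    if (!length(p)) 0 else mean(p)
  })
  sigma_t <- numeric(nrow(el))
  nz <- pos_mean > 0
  if (any(nz)) {
    snap <- levels[pmax(1, apply(abs(outer(pos_mean[nz], levels, "-")), 1,
                                 which.min))]
    missing <- setdiff(format_cv(snap), names(calibration))
    if (length(missing))
      stop("calibration missing CV_T levels: ",
           paste(missing, collapse = ", "))
    sigma_t[nz] <- calibration[format_cv(snap)]
  }
  sigma_l <- ifelse(nz, calibration[[need]], 0)
  s6 <- tensor_rows(mesh$fibers, sigma_l, sigma_t)
  s6[!nz, ] <- 0
  s6
}
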