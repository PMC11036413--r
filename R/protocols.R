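#' Bundle a configured electrophysiology model
#'
#' Packages everything the stimulation protocols need: the mesh, the
#' assembled per-element conductivity tensors, tissue parameters and the
#' warm-start conditioning protocol.
#'
#' @param mesh \code{sw_mesh} with fibers and labels.
#' @param sigma6 per-element conductivity tensor rows (mS/mm).
#' @param params \code{\link{tissue_params}}.
#' @param n_beats_warm,bcl_warm single-cell conditioning train used to
#'   warm-start tissue runs.
#' @return object of class \code{sw_model}.
#' @export
build_model <- function(mesh, sigma6, params = tissue_params(),
                        n_beats_warm = 500, bcl_warm = 600) {
  validate_mesh(mesh)
  structure(list(mesh = mesh, sigma6 = sigma6, params = params,
                 n_beats_warm = n_beats_warm, bcl_warm = bcl_warm),
            class = "sw_model")
}

#' Virtual stress-test specification
#'
#' @param pacing_sites list of stimulus centers (node indices or
#'   coordinates).
#' @param n_s1 number of S1 drive-train stimuli.
#' @param s1_bcl S1 cycle length (ms).
#' @param s2_step S2 interval scan increment (ms).
#' @param vt_sustain minimum duration of post-S2 electrical activity that
#'   qualifies as ventricular tachycardia (ms).
#' @param s2_min,s2_max scanned S2-interval range (ms); the effective lower
#'   bound is the earliest capturing interval, the upper bound the latest
#'   VT-inducing interval + 15 ms (or \code{s2_max} when no VT occurs).
#' @param stim_diameter,stim_amplitude,stim_duration stimulus geometry.
#' @param s1_nodes optional explicit node set for the S1 drive train (e.g. a
#'   planar edge drive); by default S1 is delivered at the pacing site.
#' @return object of class \code{sw_stress_spec}.
#' @export
stress_test_spec <- function(pacing_sites = list(), n_s1 = 6, s1_bcl = 600,
                             s2_step = 5, vt_sustain = 800,
                             s2_min = 150, s2_max = 450,
                             stim_diameter = 3, stim_amplitude = 40,
                             stim_duration = 2, s1_nodes = NULL) {
  if (n_s1 < 1) stop("n_s1 must be >= 1")
  if (s2_step <= 0) stop("s2_step must be positive")
  structure(list(pacing_sites = pacing_sites, n_s1 = as.integer(n_s1),
                 s1_bcl = s1_bcl, s2_step = s2_step,
                 vt_sustain = vt_sustain, s2_min = s2_min, s2_max = s2_max,
                 stim_diameter = stim_diameter,
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration, s1_nodes = s1_nodes),
            class = "sw_stress_spec")
}

#' Default endocardial pacing sites around the border zone
#'
#' Places \code{n} sites equally spaced circumferentially on the
#' endocardial surface, each at the node closest to the border-zone outer
#' boundary.
#'
#' @param mesh an infarcted LV \code{sw_mesh}.
#' @param n number of sites.
#' @return list of node indices.
#' @export
default_pacing_sites <- function(mesh, n = 6) {
  if (is.null(mesh$core_dist)) stop("mesh has no infarct")
  endo <- which(mesh$transmural <= 0.05 + 1e-9)
  phi <- atan2(mesh$nodes[endo, 2], mesh$nodes[endo, 1])
  bz <- max(mesh$core_dist[mesh$region == "structural_bz"], 1)
  targets <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  lapply(targets, function(ph) {
    dphi <- abs(((phi - ph + pi) %% (2 * pi)) - pi)
    score <- dphi * 10 + abs(mesh$core_dist[endo] - 1.2 * bz)
    endo[which.min(score)]
  })
}

stim_for_site <- function(spec, site, onset) {
  stimulus_spec(site, diameter = spec$stim_diameter,
                amplitude = spec$stim_amplitude,
                duration = spec$stim_duration, onset = onset)
}

s1_stim <- function(spec, site, onset) {
  if (!is.null(spec$s1_nodes))
    stimulus_spec(nodes = spec$s1_nodes, amplitude = spec$stim_amplitude,
                  duration = spec$stim_duration, onset = onset)
  else stim_for_site(spec, site, onset)
}

# Run the S1 drive train up to the onset of the last S1 beat and return the
# state checkpoint (the last beat itself is simulated by the callers).
run_s1_train <- function(model, site, spec) {
  t_last <- (spec$n_s1 - 1) * spec$s1_bcl
  if (t_last == 0) {
    # single S1: branch directly off the conditioned cell states
    return(list(checkpoint = TRUE, t_last = 0, record = NULL))
  }
  stims <- lapply(seq_len(spec$n_s1 - 1) - 1,
                  function(b) s1_stim(spec, site, b * spec$s1_bcl))
  rec <- solve_monodomain(model$mesh, model$sigma6, stimuli = stims,
                          duration = t_last, params = model$params,
                          warm_start = TRUE,
                          n_beats_warm = model$n_beats_warm,
                          bcl_warm = model$bcl_warm,
                          early_stop = FALSE)  # checkpoint at exactly t_last
  if (all(rec$n_act == 0))
    stop("protocol error: S1 failed to capture")
  list(checkpoint = list(Vm = rec$Vm, states = rec$states),
       t_last = t_last, record = rec)
}

#' Detect sustained post-S2 electrical activity (VT)
#'
#' VT is electrical activity sustained for at least \code{sustain} ms after
#' the premature stimulus, operationalized as new activations (upstrokes)
#' occurring somewhere in the domain throughout every \code{window}-ms
#' sub-window of [s2_onset, s2_onset + sustain].
#'
#' @param record an \code{sw_record} covering at least
#'   \code{s2_onset + sustain} (runs that terminated early because the
#'   tissue went quiescent count as covering the remainder with no
#'   activity).
#' @param s2_onset S2 onset time (ms, record time base).
#' @param sustain sustained-activity requirement (ms).
#' @param window sub-window length (ms).
#' @return logical.
#' @export
detect_vt <- function(record, s2_onset, sustain = 800, window = 100) {
  if (record$duration < s2_onset + sustain)
    stop("simulation shorter than s2_onset + sustain")
  acts <- as.vector(record$act)
  acts <- acts[!is.na(acts) & acts >= s2_onset &
               acts <= s2_onset + sustain]
  if (!length(acts)) return(FALSE)
  edges <- seq(s2_onset, s2_onset + sustain, by = window)
  h <- findInterval(acts, edges, rightmost.closed = TRUE)
  all(seq_len(length(edges) - 1) %in% h)
}

#' Locate the VT exit point
#'
#' The exit point is the node with the earliest second activation
#' (upstroke) counted from the start of S2; ties break to the lowest node
#' index.
#'
#' @param record an \code{sw_record}.
#' @param s2_onset S2 onset time (ms).
#' @return node index (attribute \code{time}: its second activation time).
#' @export
locate_exit_point <- function(record, s2_onset) {
  n <- record$mesh_n
  second <- rep(Inf, n)
  for (i in seq_len(n)) {
    a <- record$act[i, ]
    a <- a[!is.na(a) & a >= s2_onset]
    if (length(a) >= 2) second[i] <- sort(a)[2]
  }
  if (all(is.infinite(second)))
    stop("inconsistent record: no node has a second activation after S2")
  idx <- which.min(second)  # which.min returns the first (lowest) index
  structure(as.integer(idx), time = second[idx])
}

# capture = activation beyond the stimulus neighborhood after S2
s2_captures <- function(record, mesh, site, spec, s2_onset) {
  ctr <- if (length(site) == 1) mesh$nodes[as.integer(site), ] else
    rep_len(as.numeric(site), 3)
  d <- sqrt(colSums((t(mesh$nodes) - ctr)^2))
  far <- d > spec$stim_diameter / 2 + 2 * max(mesh$resolution, 0.5,
                                              na.rm = TRUE)
  a <- record$act[far, , drop = FALSE]
  any(!is.na(a) & a >= s2_onset & a <= s2_onset + 150)
}

# Scan one pacing site: outcomes per S2 interval plus bounds.
site_scan <- function(model, site, spec, margin = 100) {
  train <- run_s1_train(model, site, spec)
  intervals <- seq(spec$s2_min, spec$s2_max, by = spec$s2_step)
  outcomes <- character(0); exits <- integer(0); scanned <- numeric(0)
  # chained checkpoints: advance the last-S1 beat to each S2 onset once
  chk <- train$checkpoint
  t_cursor <- 0
  first_capture <- NA_real_; last_vt <- NA_real_
  last_s1_stim <- s1_stim(spec, site, 0)
  for (iv in intervals) {
    seg_stims <- if (t_cursor == 0) list(last_s1_stim) else list()
    seg <- solve_monodomain(model$mesh, model$sigma6,
                            stimuli = lapply(seg_stims, function(s) {
                              s$onset <- s$onset - t_cursor; s }),
                            duration = iv - t_cursor, params = model$params,
                            warm_start = chk, early_stop = FALSE,
                            n_beats_warm = model$n_beats_warm,
                            bcl_warm = model$bcl_warm,
                            t_offset = t_cursor)
    chk <- list(Vm = seg$Vm, states = seg$states)
    t_cursor <- iv
    # branch: S2 now, watch for capture then sustained activity
    need_vt <- !is.na(first_capture)
    dur <- if (need_vt) spec$vt_sustain + margin else 200
    branch <- solve_monodomain(model$mesh, model$sigma6,
                               stimuli = list(stim_for_site(spec, site, 0)),
                               duration = dur, params = model$params,
                               warm_start = chk, early_stop = TRUE,
                               t_offset = iv)
    cap <- s2_captures(branch, model$mesh, site, spec, iv)
    if (!cap) {
      outcomes <- c(outcomes, "no_capture")
      exits <- c(exits, NA_integer_)
      scanned <- c(scanned, iv)
      next
    }
    if (is.na(first_capture)) {
      first_capture <- iv
      # rerun this interval at full VT-detection length
      branch <- solve_monodomain(model$mesh, model$sigma6,
                                 stimuli = list(stim_for_site(spec, site, 0)),
                                 duration = spec$vt_sustain + margin,
                                 params = model$params, warm_start = chk,
                                 early_stop = TRUE, t_offset = iv)
    }
    vt <- detect_vt(branch, iv, sustain = spec$vt_sustain)
    if (vt) {
      last_vt <- iv
      ex <- tryCatch(as.integer(locate_exit_point(branch, iv)),
                     error = function(e) NA_integer_)
    } else ex <- NA_integer_
    outcomes <- c(outcomes, if (vt) "VT" else "no_VT")
    exits <- c(exits, ex)
    scanned <- c(scanned, iv)
    # stop scanning 15 ms past the latest VT once capture is established
    if (!is.na(first_capture) && iv > spec$s2_max - spec$s2_step) break
    if (!is.na(last_vt) && iv >= last_vt + 15 &&
        sum(outcomes == "no_VT" & scanned > last_vt) >= 3) break
  }
  upper <- if (!is.na(last_vt)) last_vt + 15 else spec$s2_max
  list(site = site,
       outcomes = data.frame(interval = scanned, outcome = outcomes,
                             exit_node = exits),
       bounds = c(lower = first_capture, upper = upper),
       s1_record = train$record)
}

#' Scanned S2 bounds for one pacing site
#'
#' Lower bound: earliest S2 interval (at the scan step) whose stimulus
#' captures, i.e. elicits propagated activation beyond the stimulus region.
#' Upper bound: latest VT-inducing interval + 15 ms, or the configured scan
#' cap when no VT occurs.
#'
#' @param site stimulus center (node index or coordinate).
#' @param spec \code{\link{stress_test_spec}}.
#' @param model \code{\link{build_model}} output.
#' @return numeric \code{c(lower, upper)} (ms).
#' @export
find_s2_bounds <- function(site, spec, model) {
  site_scan(model, site, spec)$bounds
}

#' Scan the vulnerable window of a configured model
#'
#' For each pacing site, applies the S1 drive train followed by a premature
#' S2 at every scanned interval, records the outcome (no capture / no VT /
#' VT) and the exit point of induced VT, and reports the window width
#' (number of VT-positive intervals times the scan step).
#'
#' @param spec \code{\link{stress_test_spec}} with \code{pacing_sites} set.
#' @param model \code{\link{build_model}} output.
#' @return object of class \code{sw_vulnerable_window}: data.frame of
#'   outcomes with per-site attributes \code{bounds} and
#'   \code{window_width_ms}.
#' @export
scan_vulnerable_window <- function(spec, model) {
  if (!length(spec$pacing_sites)) {
    out <- data.frame(site = integer(0), interval = numeric(0),
                      outcome = character(0), exit_node = integer(0))
    attr(out, "window_width_ms") <- numeric(0)
    class(out) <- c("sw_vulnerable_window", "data.frame")
    return(out)
  }
  res <- lapply(seq_along(spec$pacing_sites), function(si) {
    sc <- site_scan(model, spec$pacing_sites[[si]], spec)
    cbind(site = si, sc$outcomes,
          lower = sc$bounds[["lower"]], upper = sc$bounds[["upper"]])
  })
  out <- do.call(rbind, res)
  ww <- vapply(split(out$outcome == "VT", out$site), function(z)
    sum(z) * spec$s2_step, numeric(1))
  attr(out, "window_width_ms") <- ww
  class(out) <- c("sw_vulnerable_window", "data.frame")
  out
}

#' @export
print.sw_vulnerable_window <- function(x, ...) {
  cat("sw_vulnerable_window:\n")
  if (nrow(x)) {
    print.data.frame(x)
    cat("window width (ms) per site:",
        paste(attr(x, "window_width_ms"), collapse = " "), "\n")
  } else cat("  (no sites scanned)\n")
  invisible(x)
}
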