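#' Layer- and region-specific myocyte conductance scalings
#'
#' Builds the per-cell conductance multipliers of the Ten Tusscher-Panfilov
#' (2006, epicardial base) model. The transmural layers carry an intrinsic
#' APD gradient implemented purely through the slow delayed-rectifier
#' conductance: Gks is scaled by 2.10 (endo, +110\%), 0.95 (sub-endo, -5\%),
#' 1.30 (mid, +30\%) and 2.45 (epi, +145\%). Structural border-zone
#' remodeling multiplies, on top of the layer scaling, GNa by 0.38 (-62\%),
#' GCaL by 0.31 (-69\%), GKr by 0.30 (-70\%) and GKs by 0.20 (-80\%).
#'
#' @param layer one of "endo", "sub_endo", "mid", "epi".
#' @param region one of "remote", "structural_bz", "core".
#' @param bz_layer_gradient if FALSE, border-zone cells drop the transmural
#'   Gks gradient (a single border-zone phenotype: the layer factor is
#'   replaced by 1 before the border-zone multiplier).
#' @return an object of class \code{sw_cell_params}: list with
#'   \code{gna_scale}, \code{gcal_scale}, \code{gkr_scale},
#'   \code{gks_scale}, plus the labels.
#' @export
make_cell_params <- function(layer = "mid", region = "remote",
                             bz_layer_gradient = TRUE) {
  gks_layer <- c(endo = 2.10, sub_endo = 0.95, mid = 1.30, epi = 2.45)
  if (!layer %in% names(gks_layer))
    stop("unknown layer label: ", layer)
  if (!region %in% c("remote", "structural_bz", "core"))
    stop("unknown region label: ", region)
  p <- list(gna_scale = 1, gcal_scale = 1, gkr_scale = 1,
            gks_scale = unname(gks_layer[layer]),
            layer = layer, region = region)
  if (region == "structural_bz") {
    if (!bz_layer_gradient) p$gks_scale <- 1
    p$gna_scale <- p$gna_scale * 0.38
    p$gcal_scale <- p$gcal_scale * 0.31
    p$gkr_scale <- p$gkr_scale * 0.30
    p$gks_scale <- p$gks_scale * 0.20
  }
  class(p) <- "sw_cell_params"
  p
}

scales_vector <- function(params) {
  stopifnot(inherits(params, "sw_cell_params"))
  c(params$gna_scale, params$gcal_scale, params$gkr_scale, params$gks_scale)
}

#' Pacing protocol specification
#'
#' @param n_beats number of conditioning beats.
#' @param bcl basic cycle length (ms).
#' @param amplitude stimulus amplitude (uA/cm^2).
#' @param duration stimulus duration (ms).
#' @return an object of class \code{sw_pacing_spec}.
#' @export
pacing_spec <- function(n_beats = 500, bcl = 600, amplitude = 40,
                        duration = 2) {
  if (n_beats < 1) stop("n_beats must be >= 1")
  if (bcl <= duration) stop("bcl must exceed the stimulus duration")
  structure(list(n_beats = as.integer(n_beats), bcl = bcl,
                 amplitude = amplitude, duration = duration),
            class = "sw_pacing_spec")
}

#' Resting initial state of the ventricular myocyte model
#' @return named numeric vector (Vm plus 18 gating/ionic variables).
#' @export
cell_initial_state <- function() tt06_initial_state_cpp()

#' Pace a single myocyte to steady state
#'
#' Integrates the cell ODEs for the full pacing train (fixed-step
#' Rush-Larsen/forward-Euler at \code{dt}) and returns the membrane-voltage
#' trace of the final beat together with the post-train state for
#' warm-starting tissue simulations.
#'
#' @param params an \code{\link{make_cell_params}} object.
#' @param pacing an \code{\link{pacing_spec}}.
#' @param dt time step (ms).
#' @param state0 optional initial state (defaults to rest).
#' @param trace_stride record every \code{trace_stride}-th step of the last
#'   beat.
#' @return an object of class \code{sw_trace}: list with \code{trace}
#'   (data.frame \code{t} (ms, zeroed at the last-beat stimulus),
#'   \code{vm} (mV)), \code{state} (post-train state), \code{apd} (per-beat
#'   APD at the -70 mV tissue definition, ms) and \code{act}/\code{rep}
#'   per-beat activation/repolarization times.
#' @export
pace_cell <- function(params, pacing = pacing_spec(), dt = 0.02,
                      state0 = cell_initial_state(), trace_stride = 5L) {
  stopifnot(inherits(pacing, "sw_pacing_spec"))
  res <- tt06_pace_cpp(state0, scales_vector(params), pacing$n_beats,
                       pacing$bcl, pacing$amplitude, pacing$duration,
                       dt, as.integer(trace_stride))
  t0 <- (pacing$n_beats - 1) * pacing$bcl
  structure(list(
    trace = data.frame(t = res$trace_t - t0, vm = res$trace_v),
    state = res$state,
    act = res$act - (seq_len(pacing$n_beats) - 1) * pacing$bcl,
    rep = res$rep - (seq_len(pacing$n_beats) - 1) * pacing$bcl,
    apd = res$rep - res$act,
    params = params, pacing = pacing, dt = dt), class = "sw_trace")
}

#' @export
print.sw_trace <- function(x, ...) {
  cat(sprintf("sw_trace: %d beats at BCL %g ms; last-beat APD(-70) %.1f ms\n",
              x$pacing$n_beats, x$pacing$bcl, tail(x$apd, 1)))
  invisible(x)
}

#' Measure action potential duration from a voltage trace
#'
#' APD is the time from the maximum upstroke velocity (max dVm/dt) to the
#' subsequent downward crossing of \code{repol_threshold}, with linear
#' interpolation between samples. The default threshold matches the tissue
#' repolarization definition (-70 mV); intrinsic single-cell APDs in this
#' package are reported at -75 mV (see \code{\link{intrinsic_apd}}).
#'
#' @param trace an \code{sw_trace}, or a data.frame with columns \code{t}
#'   and \code{vm}.
#' @param repol_threshold repolarization threshold (mV).
#' @return APD in ms.
#' @export
measure_apd <- function(trace, repol_threshold = -70) {
  tr <- if (inherits(trace, "sw_trace")) trace$trace else trace
  t <- tr$t; v <- tr$vm
  if (length(t) < 3) stop("measurement error: trace too short")
  dv <- diff(v) / diff(t)
  iup <- which.max(dv)
  if (dv[iup] < 1 || max(v) < -40)
    stop("measurement error: no upstroke in trace")
  tup <- t[iup]
  n <- length(v)
  cross <- which(v[-n] > repol_threshold & v[-1] <= repol_threshold &
                 t[-n] >= tup)
  if (!length(cross))
    stop("measurement error: no repolarization below ", repol_threshold,
         " mV after the upstroke")
  k <- cross[1]
  tc <- t[k] + (v[k] - repol_threshold) / (v[k] - v[k + 1]) *
        (t[k + 1] - t[k])
  tc - tup
}

#' Intrinsic steady-state APD of a layer/region phenotype
#'
#' Paces an isolated cell to steady state and measures the APD of the final
#' beat. Intrinsic (isolated-cell) APDs use a -75 mV repolarization
#' threshold, the convention under which the four transmural layer
#' phenotypes reproduce the published 242/294/274/232 ms set at BCL 600 ms.
#'
#' @param layer,region labels as in \code{\link{make_cell_params}}.
#' @param pacing pacing protocol (default 500 beats at BCL 600 ms).
#' @param repol_threshold repolarization threshold (mV).
#' @param dt integration step (ms).
#' @return APD of the final beat (ms).
#' @export
intrinsic_apd <- function(layer, region = "remote",
                          pacing = pacing_spec(), repol_threshold = -75,
                          dt = 0.02) {
  tr <- pace_cell(make_cell_params(layer, region), pacing, dt = dt,
                  trace_stride = 1L)
  measure_apd(tr, repol_threshold = repol_threshold)
}

# session cache of steady-paced cell states keyed by phenotype + protocol
.steady_cache <- new.env(parent = emptyenv())

#' Steady-paced cell state for warm-starting tissue simulations
#'
#' Runs (and caches per session) the single-cell conditioning train and
#' returns the post-train state.
#'
#' @inheritParams intrinsic_apd
#' @param n_beats,bcl conditioning train length and cycle length (ms).
#' @return named state vector (Vm plus 18 variables).
#' @export
cell_steady_state <- function(layer, region = "remote", n_beats = 500,
                              bcl = 600) {
  key <- paste(layer, region, n_beats, bcl, sep = "|")
  if (!is.null(.steady_cache[[key]])) return(.steady_cache[[key]])
  tr <- pace_cell(make_cell_params(layer, region),
                  pacing_spec(n_beats = n_beats, bcl = bcl),
                  trace_stride = 50L)
  .steady_cache[[key]] <- tr$state
  tr$state
}

#' Write / read steady-state cell checkpoints as CSV
#'
#' Plain-text serialization of the steady-state cache: one row per
#' (layer, region, bcl, n_beats) key with the 19 state entries.
#'
#' @param file path to the checkpoint CSV.
#' @export
write_cell_checkpoints <- function(file) {
  keys <- ls(.steady_cache)
  if (!length(keys)) stop("no steady states cached yet")
  rows <- lapply(keys, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    st <- .steady_cache[[k]]
    cbind(data.frame(layer = parts[1], region = parts[2],
                     n_beats = as.integer(parts[3]), bcl = as.numeric(parts[4])),
          as.data.frame(as.list(st)))
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cell_checkpoints
#' @export
read_cell_checkpoints <- function(file) {
  df <- utils::read.csv(file)
  for (i in seq_len(nrow(df))) {
    key <- paste(df$layer[i], df$region[i], df$n_beats[i], df$bcl[i],
                 sep = "|")
    st <- as.numeric(df[i, -(1:4)])
    names(st) <- names(df)[-(1:4)]
    .steady_cache[[key]] <- st
  }
  invisible(length(ls(.steady_cache)))
}
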