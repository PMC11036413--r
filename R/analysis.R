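#' Per-node repolarization-time map of a beat
#'
#' Extracts, per node, the repolarization time (-70 mV downward crossing)
#' of the beat whose activation falls inside the given window — typically
#' the last S1 beat of a stress test. Nodes that never activated or did
#' not repolarize in the window are returned as NA.
#'
#' @param record an \code{sw_record}.
#' @param window numeric \code{c(t0, t1)}: activation-time window (ms)
#'   selecting the beat.
#' @return numeric vector of repolarization times (ms), NA where missing.
#' @export
repolarization_map <- function(record, window) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be an increasing time pair")
  n <- record$mesh_n
  out <- rep(NA_real_, n)
  inw <- !is.na(record$act) & record$act >= window[1] &
         record$act < window[2]
  if (!any(inw)) stop("no beat found in the requested window")
  for (i in seq_len(n)) {
    k <- which(inw[i, ])
    if (length(k)) out[i] <- record$rep[i, k[1]]
  }
  out
}

#' Spatial repolarization-time-gradient map
#'
#' Computes the element-wise constant gradient of the repolarization-time
#' field from linear shape functions, then recovers a nodal gradient
#' magnitude as the volume-weighted average over adjacent elements.
#' Elements touching nodes with missing repolarization times are excluded.
#'
#' @param rt per-node repolarization times (ms, NA = missing).
#' @param mesh the \code{sw_mesh}.
#' @return object of class \code{sw_rtg_map}: list with \code{magnitude}
#'   (ms/mm, NA where undefined), \code{node_vol} (mm^3) and the
#'   element-level gradients.
#' @export
rtg_map <- function(rt, mesh) {
  stopifnot(length(rt) == nrow(mesh$nodes))
  el <- mesh$elems; k <- ncol(el)
  ok_el <- rowSums(matrix(is.na(rt[el]), ncol = k)) == 0
  n <- nrow(mesh$nodes)
  if (!any(ok_el)) {
    warning("all elements touch missing repolarization times: empty map")
    return(structure(list(magnitude = rep(NA_real_, n),
                          node_vol = mesh$node_vol,
                          elem_mag = rep(NA_real_, nrow(el))),
                     class = "sw_rtg_map"))
  }
  G <- shape_gradients(mesh)
  gx <- gy <- gz <- numeric(nrow(el))
  for (j in seq_len(k)) {
    gx <- gx + G[, j, 1] * rt[el[, j]]
    gy <- gy + G[, j, 2] * rt[el[, j]]
    gz <- gz + G[, j, 3] * rt[el[, j]]
  }
  emag <- sqrt(gx^2 + gy^2 + gz^2)
  emag[!ok_el] <- NA_real_
  # nodal recovery: element-volume weighted mean over adjacent valid elems
  wsum <- numeric(n); vsum <- numeric(n)
  share <- mesh$elem_vol
  for (j in seq_len(k)) {
    idx <- el[ok_el, j]
    acc <- tapply(emag[ok_el] * share[ok_el], idx, sum)
    accv <- tapply(share[ok_el], idx, sum)
    ids <- as.integer(names(acc))
    wsum[ids] <- wsum[ids] + as.numeric(acc)
    vsum[ids] <- vsum[ids] + as.numeric(accv)
  }
  mag <- ifelse(vsum > 0, wsum / pmax(vsum, 1e-300), NA_real_)
  structure(list(magnitude = mag, node_vol = mesh$node_vol,
                 elem_mag = emag), class = "sw_rtg_map")
}

#' Repolarization-gradient substrate metrics
#'
#' \code{rtg_vol} is the tissue volume (mL) carrying repolarization-time
#' gradients at or above the threshold; \code{rtg_mean} the volume-weighted
#' mean gradient within that volume (reported as 0, flagged, when no node
#' exceeds the threshold).
#'
#' @param map an \code{\link{rtg_map}}.
#' @param threshold gradient threshold (ms/mm).
#' @return list with \code{rtg_vol} (mL), \code{rtg_mean} (ms/mm) and
#'   \code{any_above} flag.
#' @export
rtg_metrics <- function(map, threshold = 10) {
  stopifnot(inherits(map, "sw_rtg_map"))
  if (threshold < 0) stop("threshold must be nonnegative")
  sel <- !is.na(map$magnitude) & map$magnitude >= threshold
  if (!any(sel))
    return(list(rtg_vol = 0, rtg_mean = 0, any_above = FALSE))
  v <- map$node_vol[sel]
  list(rtg_vol = sum(v) / 1000,
       rtg_mean = sum(map$magnitude[sel] * v) / sum(v),
       any_above = TRUE)
}

#' Tissue volume with severe conduction slowing
#'
#' Total node volume with 0 < CV_T <= threshold, plus the infarct core
#' volume (CV_T = 0) when \code{include_core} is TRUE.
#'
#' @param cvt per-node transverse conduction velocities (m/s).
#' @param mesh the \code{sw_mesh}.
#' @param threshold slow-conduction threshold (m/s).
#' @param include_core count the zero-CV core volume as well.
#' @return volume in mL.
#' @export
slow_cv_volume <- function(cvt, mesh, threshold = 0.1, include_core = TRUE) {
  stopifnot(length(cvt) == nrow(mesh$nodes))
  sel <- (cvt > 0 & cvt <= threshold) | (include_core & cvt == 0)
  sum(mesh$node_vol[sel]) / 1000
}

#' Volume-weighted histogram of a CV_T field
#'
#' @param cvt per-node CV_T values (m/s).
#' @param mesh the \code{sw_mesh}.
#' @param bins bin edges (m/s); defaults to the discretization-level edges
#'   implied by the field's \code{levels} attribute, or 10 equal bins.
#' @return data.frame with \code{lower}, \code{upper}, \code{volume_ml}.
#' @export
cvt_histogram <- function(cvt, mesh, bins = NULL) {
  stopifnot(length(cvt) == nrow(mesh$nodes))
  if (is.null(bins)) {
    lev <- attr(cvt, "levels")
    if (!is.null(lev) && length(lev) > 1) {
      w <- diff(lev)[1]
      bins <- c(lev - w / 2, max(lev) + w / 2)
    } else {
      bins <- seq(min(cvt), max(cvt) + 1e-9, length.out = 11)
    }
  }
  bins <- sort(unique(c(bins, min(cvt), max(cvt) + 1e-12)))
  idx <- pmin(findInterval(cvt, bins, rightmost.closed = TRUE),
              length(bins) - 1)
  vol <- vapply(seq_len(length(bins) - 1), function(b)
    sum(mesh$node_vol[idx == b]) / 1000, numeric(1))
  data.frame(lower = bins[-length(bins)], upper = bins[-1],
             volume_ml = vol)
}
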