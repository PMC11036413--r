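#' Parameters of the strain-amplitude / transverse-conduction-velocity law
#'
#' The transverse conduction velocity is modeled as
#' \deqn{CV_T(x) = CV_{T,ref} \, f_{act}(x) \, g(\varepsilon_a(x)),}
#' \deqn{g(\varepsilon_a) = 1 + \frac{CV_{T,var}}{2\,CV_{T,ref}}
#'   \tanh\big(\alpha(\varepsilon_a - \varepsilon_{ref})\big),}
#' a sigmoid in the fiber-strain amplitude, scaled by the infarct-density
#' factor. With the default parameters the law spans
#' [0.08, 0.52] m/s in healthy tissue and returns exactly 0.30 m/s at the
#' reference strain amplitude.
#'
#' @param cvt_ref basic transverse velocity (m/s).
#' @param cvt_var allowed peak-to-peak variability around it (m/s).
#' @param alpha sensitivity (steepness) constant, dimensionless.
#' @param eps_ref strain amplitude at which g = 1.
#' @return object of class \code{sw_strain_cv_params}.
#' @export
strain_cv_params <- function(cvt_ref = 0.30, cvt_var = 0.44, alpha = 20.6,
                             eps_ref = 0.1665) {
  if (cvt_ref <= 0) stop("cvt_ref must be positive")
  if (cvt_var < 0) stop("cvt_var must be nonnegative")
  if (cvt_ref - cvt_var / 2 < -1e-12)
    stop("cvt_ref - cvt_var/2 must be nonnegative (no negative velocities)")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(cvt_ref = cvt_ref, cvt_var = cvt_var, alpha = alpha,
                 eps_ref = eps_ref), class = "sw_strain_cv_params")
}

#' Sigmoid strain factor g
#'
#' @param eps fiber-strain amplitude(s), dimensionless.
#' @param params \code{\link{strain_cv_params}}.
#' @return dimensionless factor, strictly increasing in \code{eps} and
#'   bounded in (1 - cvt_var/(2 cvt_ref), 1 + cvt_var/(2 cvt_ref)).
#' @export
g_strain <- function(eps, params = strain_cv_params()) {
  stopifnot(inherits(params, "sw_strain_cv_params"), all(is.finite(eps)))
  1 + params$cvt_var / (2 * params$cvt_ref) *
    tanh(params$alpha * (eps - params$eps_ref))
}

#' Transverse conduction-velocity field from strain and infarct density
#'
#' @param strain per-node fiber-strain amplitudes.
#' @param density per-node infarct-density factors in [0, 1] (1 healthy,
#'   0 core).
#' @param params \code{\link{strain_cv_params}}.
#' @return per-node CV_T in m/s; exactly 0 where density is 0.
#' @export
cvt_field <- function(strain, density, params = strain_cv_params()) {
  if (length(strain) != length(density))
    stop("strain and density fields have different lengths")
  if (any(!is.finite(strain)) || any(strain < 0))
    stop("strain amplitudes must be finite and nonnegative")
  if (any(density < -1e-12 | density > 1 + 1e-12))
    stop("density factors must lie in [0, 1]")
  params$cvt_ref * density * g_strain(strain, params)
}

#' Fit the strain-CV law to paired samples
#'
#' Reproduces the two-stage fitting procedure: (1) an ordinary least-squares
#' regression line through the (strain amplitude, CV_T) samples; (2) a
#' least-squares fit of the sigmoid law (at unit infarct density) to that
#' line over the sampled strain range. Alternatively the sigmoid can be fit
#' to the raw points directly.
#'
#' @param eps_samples strain-amplitude samples.
#' @param cv_samples CV_T samples (m/s).
#' @param fixed list with \code{cvt_ref} and \code{cvt_var} (held fixed).
#' @param objective fit the sigmoid to the regression \code{"line"}
#'   (default) or to the raw \code{"points"}.
#' @return \code{\link{strain_cv_params}} with fit diagnostics attached:
#'   attribute \code{fit} containing \code{r_squared} of the regression,
#'   the line coefficients, and the residual sum of squares of the sigmoid
#'   fit.
#' @export
fit_strain_cv <- function(eps_samples, cv_samples,
                          fixed = list(cvt_ref = 0.30, cvt_var = 0.44),
                          objective = c("line", "points")) {
  objective <- match.arg(objective)
  if (length(eps_samples) < 3 || length(eps_samples) != length(cv_samples))
    stop("need at least 3 paired samples")
  if (stats::sd(eps_samples) < 1e-12)
    stop("fitting error: zero strain variance in samples")
  fitln <- stats::lm(cv_samples ~ eps_samples)
  r2 <- summary(fitln)$r.squared
  if (objective == "line") {
    xs <- seq(min(eps_samples), max(eps_samples), length.out = 200)
    ys <- stats::predict(fitln, data.frame(eps_samples = xs))
  } else {
    xs <- eps_samples; ys <- cv_samples
  }
  model <- function(p) {
    fixed$cvt_ref * (1 + fixed$cvt_var / (2 * fixed$cvt_ref) *
                       tanh(exp(p[1]) * (xs - p[2])))
  }
  sse <- function(p) sum((model(p) - ys)^2)
  # start from the slope-matched linearization: g'(eps_ref) gives
  # slope = cvt_var/2 * alpha at the midpoint
  slope <- unname(stats::coef(fitln)[2])
  a0 <- max(slope / (fixed$cvt_var / 2), 1)
  e0 <- mean(range(eps_samples))
  opt <- stats::optim(c(log(a0), e0), sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  out <- strain_cv_params(cvt_ref = fixed$cvt_ref, cvt_var = fixed$cvt_var,
                          alpha = exp(opt$par[1]), eps_ref = opt$par[2])
  attr(out, "fit") <- list(r_squared = r2,
                           line = unname(stats::coef(fitln)),
                           sse = opt$value, converged = opt$convergence == 0)
  out
}

#' Discretize a CV_T field into level center values
#'
#' Nonzero values are binned into \code{n_levels} equal-width bins spanning
#' [min positive, max]; each node is assigned its bin's center value. Zeros
#' (infarct core) are preserved exactly as their own level.
#'
#' @param field per-node CV_T values (m/s).
#' @param n_levels number of nonzero levels.
#' @return leveled field with attribute \code{levels} (the center values).
#' @export
discretize_cvt <- function(field, n_levels = 9) {
  if (n_levels < 1) stop("n_levels must be >= 1")
  pos <- field > 0
  if (!any(pos)) {
    warning("all-zero CV_T field: nothing to discretize")
    attr(field, "levels") <- numeric(0)
    return(field)
  }
  lo <- min(field[pos]); hi <- max(field[pos])
  if (hi - lo < 1e-12) {
    out <- field
    out[pos] <- lo
    attr(out, "levels") <- lo
    return(out)
  }
  edges <- seq(lo, hi, length.out = n_levels + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- pmin(findInterval(field[pos], edges, rightmost.closed = TRUE),
              n_levels)
  out <- field
  out[pos] <- centers[bin]
  attr(out, "levels") <- centers
  out
}
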