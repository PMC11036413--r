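#' Strain-amplitude profile specification
#'
#' Describes the synthetic fiber-strain-amplitude field that stands in for
#' a mechanics simulation under weak coupling: a transmural increase of
#' strain amplitude from epicardium to endocardium in remote tissue,
#' depressed amplitudes (~0.15) in the structural border zone, elevated
#' amplitudes in the bulging (stretching) infarct core, and smooth blending
#' over a transition width.
#'
#' @param eps_epi,eps_endo remote transmural profile endpoints
#'   (dimensionless strain amplitude); \code{eps_endo >= eps_epi}.
#' @param bz_amplitude depressed amplitude inside the structural border
#'   zone.
#' @param core_amplitude amplitude in the bulging core
#'   (> \code{bz_amplitude}).
#' @param transition_width blending length scale (mm).
#' @param noise_sd standard deviation of the optional spatial Gaussian
#'   noise (dimensionless).
#' @param seed RNG seed for the noise.
#' @return object of class \code{sw_strain_spec}.
#' @export
strain_profile_spec <- function(eps_epi = 0.12, eps_endo = 0.21,
                                bz_amplitude = 0.15, core_amplitude = 0.25,
                                transition_width = 5, noise_sd = 0,
                                seed = 1L) {
  if (any(c(eps_epi, eps_endo, bz_amplitude, core_amplitude) < 0))
    stop("strain amplitudes must be nonnegative")
  if (eps_endo < eps_epi) stop("eps_endo must be >= eps_epi")
  if (core_amplitude <= bz_amplitude)
    stop("core_amplitude must exceed bz_amplitude (bulging core)")
  if (transition_width <= 0) stop("transition_width must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(eps_epi = eps_epi, eps_endo = eps_endo,
                 bz_amplitude = bz_amplitude,
                 core_amplitude = core_amplitude,
                 transition_width = transition_width,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sw_strain_spec")
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Generate a synthetic fiber-strain-amplitude field
#'
#' Remote tissue follows the transmural profile (linear from
#' \code{eps_endo} at the endocardium to \code{eps_epi} at the epicardium).
#' Around an infarct, amplitudes blend from \code{core_amplitude} inside
#' the core down to \code{bz_amplitude} through the border zone and back up
#' to the remote profile over \code{transition_width} beyond the border
#' zone's outer boundary — so mechanically impaired but structurally normal
#' tissue adjacent to the infarct also carries depressed amplitudes (the
#' functional border zone). Optional Gaussian noise is smoothed by one
#' Laplacian (neighbor-averaging) pass and is reproducible by seed.
#'
#' @param mesh an \code{sw_mesh} with transmural coordinate and region
#'   labels (and \code{core_dist} when an infarct is present).
#' @param spec a \code{\link{strain_profile_spec}}.
#' @return per-node strain amplitudes (nonnegative).
#' @export
generate_strain_field <- function(mesh, spec = strain_profile_spec()) {
  stopifnot(inherits(spec, "sw_strain_spec"))
  if (is.null(mesh$transmural)) stop("mesh has no transmural coordinate")
  if (is.null(mesh$region)) stop("mesh has no region labels")
  u <- mesh$transmural
  eps <- spec$eps_endo + (spec$eps_epi - spec$eps_endo) * u
  if (any(mesh$region == "core")) {
    d <- mesh$core_dist
    if (is.null(d)) stop("infarcted mesh lacks core_dist; rerun assign_infarct")
    bz <- max(d[mesh$region == "structural_bz"], spec$transition_width)
    # core -> bz plateau over the first half transition width, then bz ->
    # remote profile over transition_width beyond the border-zone boundary
    inner <- smoothstep(d / (spec$transition_width / 2))
    near <- spec$core_amplitude +
      (spec$bz_amplitude - spec$core_amplitude) * inner
    outer <- smoothstep((d - bz) / spec$transition_width)
    eps <- near * (1 - outer) + eps * outer
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    z <- stats::rnorm(length(eps), sd = spec$noise_sd)
    # one lumped Laplacian smoothing pass over the element adjacency
    el <- mesh$elems; k <- ncol(el)
    acc <- numeric(length(eps)); cnt <- numeric(length(eps))
    for (a in seq_len(k)) for (b in seq_len(k)) if (a != b) {
      s <- tapply(z[el[, b]], el[, a], sum)
      idx <- as.integer(names(s))
      acc[idx] <- acc[idx] + as.numeric(s)
      c2 <- tapply(rep(1, nrow(el)), el[, a], sum)
      cnt[idx] <- cnt[idx] + as.numeric(c2)
    }
    z <- ifelse(cnt > 0, 0.5 * z + 0.5 * acc / pmax(cnt, 1), z)
    eps <- eps + z
  }
  pmax(eps, 0)
}
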