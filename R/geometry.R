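#' Simplicial simulation mesh
#'
#' A light-weight container for the unstructured simplicial meshes used by
#' the monodomain solver: segments (1-D cables), triangles (2-D sheets), or
#' tetrahedra (3-D slabs and the idealized left ventricle). Node indices are
#' 1-based throughout.
#'
#' @param nodes numeric n x 3 matrix of node coordinates (mm).
#' @param elems integer m x k connectivity (k = 2 segments, 3 triangles,
#'   4 tetrahedra), 1-based.
#' @param cross_section cross-sectional area (mm^2) for segment meshes or
#'   thickness (mm) for triangle meshes, so that integrated volumes are
#'   mL-convertible. Ignored for tetrahedral meshes.
#'
#' @return An object of class \code{sw_mesh}: a list with \code{nodes},
#'   \code{elems}, \code{dim} (element dimension), per-element
#'   \code{elem_vol} (mm^3), per-node lumped \code{node_vol} (mm^3),
#'   \code{fibers} (m x 3, unit vectors), per-node \code{region}
#'   ("remote", "structural_bz", "core"), \code{layer}
#'   ("endo", "sub_endo", "mid", "epi"), \code{transmural} and \code{height}
#'   normalized coordinates, and infarct-density fields \code{fact},
#'   \code{fpas}.
#' @export
sw_mesh <- function(nodes, elems, cross_section = 1) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) == 2) nodes <- cbind(nodes, 0)
  if (ncol(nodes) == 1) nodes <- cbind(nodes, 0, 0)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  k <- ncol(elems)
  if (!k %in% 2:4) stop("elements must have 2, 3 or 4 nodes")
  m <- structure(list(
    nodes = nodes, elems = elems, dim = k - 1L,
    cross_section = cross_section,
    fibers = NULL, region = NULL, layer = NULL,
    transmural = NULL, height = NULL,
    fact = rep(1, nrow(nodes)), fpas = rep(1, nrow(nodes)),
    resolution = NA_real_
  ), class = "sw_mesh")
  m <- recompute_volumes(m)
  m
}

#' @export
print.sw_mesh <- function(x, ...) {
  cat(sprintf("sw_mesh: %d nodes, %d %s elements, volume %.3f mL\n",
              nrow(x$nodes), nrow(x$elems),
              c("segment", "triangle", "tetrahedral")[x$dim],
              mesh_volume(x)))
  if (!is.null(x$region))
    cat("  regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                    table(x$region)), collapse = " "), "\n")
  invisible(x)
}

# element measures (length/area/volume in mm^dim) and lumped node volumes
recompute_volumes <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems; k <- ncol(el)
  if (k == 2) {
    d <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    meas <- sqrt(rowSums(d^2))
    scale <- mesh$cross_section
  } else if (k == 3) {
    a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
    cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
    cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
    meas <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
    scale <- mesh$cross_section
  } else {
    a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    c <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    det <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
           a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
           a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
    meas <- abs(det) / 6
    scale <- 1
  }
  if (any(meas <= 0)) stop("degenerate (zero-measure) element in mesh")
  mesh$elem_vol <- meas * scale
  nv <- numeric(nrow(nd))
  share <- mesh$elem_vol / k
  for (j in seq_len(k)) {
    acc <- tapply(share, el[, j], sum)
    idx <- as.integer(names(acc))
    nv[idx] <- nv[idx] + as.numeric(acc)
  }
  mesh$node_vol <- nv
  mesh
}

#' Total mesh volume in mL
#' @param mesh an \code{sw_mesh}.
#' @return volume in mL.
#' @export
mesh_volume <- function(mesh) sum(mesh$elem_vol) / 1000

validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "sw_mesh"))
  if (!is.null(mesh$fibers)) {
    nrm <- sqrt(rowSums(mesh$fibers^2))
    if (any(abs(nrm - 1) > 1e-9)) stop("fiber vectors must be unit norm")
  }
  if (any(mesh$elem_vol <= 0)) stop("element volumes must be positive")
  if (!is.null(mesh$fact) &&
      (any(mesh$fact < -1e-12) || any(mesh$fact > 1 + 1e-12)))
    stop("fact must lie in [0, 1]")
  invisible(TRUE)
}

# volume of an ellipsoid (semi-axes a, a, c) truncated at z = zb (apex at
# z = -c); exact closed form
trunc_ellipsoid_volume <- function(a, c, zb) {
  zb <- min(zb, c)
  pi * a^2 * ((zb + c) - (zb^3 + c^3) / (3 * c^2))
}

#' Build an idealized truncated-ellipsoid left-ventricle mesh
#'
#' Generates a basally truncated prolate-ellipsoid shell whose integrated
#' cavity and wall volumes match the requested values. The endocardial and
#' epicardial surfaces are ellipsoids of revolution sharing a long-axis
#' aspect ratio; the wall is a uniform offset solved numerically so the
#' integrated volumes converge to the targets under mesh refinement. Every
#' node carries a normalized transmural coordinate (0 = endocardium,
#' 1 = epicardium) and a normalized height coordinate (0 = apex, 1 = base).
#'
#' @param wall_volume wall volume target (mL).
#' @param cavity_volume cavity volume target (mL).
#' @param truncation_fraction basal truncation plane height as a fraction of
#'   the endocardial long semi-axis above the equator.
#' @param resolution target edge length (mm).
#' @param aspect_ratio long-axis to short-axis ratio of the endocardial
#'   ellipsoid.
#' @return an \code{sw_mesh} (tetrahedral) with transmural/height
#'   coordinates and per-node circumferential/longitudinal direction frames
#'   used by \code{\link{assign_fibers}}.
#' @export
build_lv_mesh <- function(wall_volume = 136, cavity_volume = 44,
                          truncation_fraction = 0.5, resolution = 1,
                          aspect_ratio = 1.8) {
  if (!is.finite(wall_volume) || !is.finite(cavity_volume) ||
      wall_volume <= 0 || cavity_volume <= 0)
    stop("geometric infeasibility: wall and cavity volumes must be positive")
  if (resolution <= 0) stop("resolution must be positive")
  vc <- cavity_volume * 1000  # mm^3
  vw <- wall_volume * 1000

  # endocardial short semi-axis from the cavity volume (closed form in a)
  r <- aspect_ratio; f <- truncation_fraction
  cav_of_a <- function(a) trunc_ellipsoid_volume(a, r * a, f * r * a)
  a_endo <- tryCatch(
    stats::uniroot(function(a) cav_of_a(a) - vc, c(1e-3, 500),
                   tol = 1e-10)$root,
    error = function(e) stop("geometric infeasibility: no real ellipsoid ",
                             "dimensions for the requested cavity volume"))
  c_endo <- r * a_endo
  zb <- f * c_endo
  # uniform wall offset h from the total (wall + cavity) volume
  tot_of_h <- function(h) trunc_ellipsoid_volume(a_endo + h, c_endo + h, zb)
  h <- tryCatch(
    stats::uniroot(function(h) tot_of_h(h) - (vc + vw), c(1e-6, 500),
                   tol = 1e-10)$root,
    error = function(e) stop("geometric infeasibility: no wall offset ",
                             "matches the requested wall volume"))
  a_epi <- a_endo + h; c_epi <- c_endo + h

  # parametric grid: u transmural, v longitudinal (apex..base), phi
  th_endo <- acos(-zb / c_endo)   # polar angle of base on endo surface
  th_epi <- acos(-zb / c_epi)
  # apex-to-base arc length (endo) to size the longitudinal grid
  tt <- seq(0, th_endo, length.out = 400)
  arc <- sum(sqrt((a_endo * cos(tt))^2 + (c_endo * sin(tt))^2) * diff(tt)[1])
  n_u <- max(3L, ceiling(h / resolution) + 1L)
  n_v <- max(4L, ceiling(arc / resolution) + 1L)
  n_phi <- max(8L, ceiling(2 * pi * a_epi / resolution))

  us <- seq(0, 1, length.out = n_u)
  vs <- seq(0, 1, length.out = n_v)         # v = 0 apex, 1 base
  phis <- seq(0, 2 * pi, length.out = n_phi + 1L)[seq_len(n_phi)]

  # surface points at (v, phi) for a given surface (a, c, theta_base):
  # theta measured from the apex (theta = 0 -> z = -c)
  surf <- function(a, c, thb, v, phi) {
    th <- v * thb
    cbind(a * sin(th) * cos(phi), a * sin(th) * sin(phi), -c * cos(th))
  }

  # node table: apex column (one node per u) + rings for v > 0
  n_ring <- (n_v - 1L) * n_phi
  n_nodes <- n_u * (1L + n_ring)
  nodes <- matrix(0, n_nodes, 3)
  transm <- numeric(n_nodes); e_c <- matrix(0, n_nodes, 3)
  e_l <- matrix(0, n_nodes, 3)
  # index helpers (1-based): apex node for layer iu; ring node (iu, iv, ip)
  idx_apex <- function(iu) iu
  idx_ring <- function(iu, iv, ip)
    n_u + ((iu - 1L) * (n_v - 1L) + (iv - 2L)) * n_phi + ip

  for (iu in seq_len(n_u)) {
    u <- us[iu]
    nodes[idx_apex(iu), ] <- c(0, 0, -((1 - u) * c_endo + u * c_epi))
    transm[idx_apex(iu)] <- u
    e_l[idx_apex(iu), ] <- c(1, 0, 0)   # frame undefined at the pole
    e_c[idx_apex(iu), ] <- c(0, 1, 0)
    for (iv in 2:n_v) {
      v <- vs[iv]
      pe <- surf(a_endo, c_endo, th_endo, v, phis)
      pp <- surf(a_epi, c_epi, th_epi, v, phis)
      P <- (1 - u) * pe + u * pp
      ids <- idx_ring(iu, iv, seq_len(n_phi))
      nodes[ids, ] <- P
      transm[ids] <- u
      # local frame: circumferential = d/dphi, longitudinal = d/dv
      a_u <- (1 - u) * a_endo + u * a_epi
      c_u <- (1 - u) * c_endo + u * c_epi
      th_u <- v * ((1 - u) * th_endo + u * th_epi)
      ec <- cbind(-sin(phis), cos(phis), 0)
      el <- cbind(a_u * cos(th_u) * cos(phis), a_u * cos(th_u) * sin(phis),
                  rep(c_u * sin(th_u), n_phi))
      el <- el / sqrt(rowSums(el^2))
      e_c[ids, ] <- ec
      e_l[ids, ] <- el
    }
  }

  # elements: apex wedge layer (v1 -> v2) then Kuhn-split hex layers
  elems <- vector("list", 2L)
  wedges <- list()
  for (iu in seq_len(n_u - 1L)) {
    A0 <- idx_apex(iu); A1 <- idx_apex(iu + 1L)
    for (ip in seq_len(n_phi)) {
      ipn <- if (ip == n_phi) 1L else ip + 1L
      B00 <- idx_ring(iu, 2L, ip);      B01 <- idx_ring(iu, 2L, ipn)
      B10 <- idx_ring(iu + 1L, 2L, ip); B11 <- idx_ring(iu + 1L, 2L, ipn)
      wedges[[length(wedges) + 1L]] <- rbind(
        c(A0, A1, B00, B01), c(A1, B00, B01, B11), c(A1, B00, B11, B10))
    }
  }
  # hex layers: local axes x = u, y = v, z = phi; Kuhn (Freudenthal) split
  # along the main diagonal gives a conforming tetrahedralization
  kuhn <- rbind(  # rows: tets as vertex labels (ix, iy, iz) packed below
    c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
    c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  hexes <- list()
  if (n_v > 2L) {
    for (iu in seq_len(n_u - 1L)) {
      for (iv in 2:(n_v - 1L)) {
        for (ip in seq_len(n_phi)) {
          ipn <- if (ip == n_phi) 1L else ip + 1L
          # corner order: bit1 = u+, bit2 = v+, bit3 = phi+
          corners <- c(
            idx_ring(iu,     iv,     ip),  idx_ring(iu + 1L, iv,     ip),
            idx_ring(iu,     iv + 1L, ip), idx_ring(iu + 1L, iv + 1L, ip),
            idx_ring(iu,     iv,     ipn), idx_ring(iu + 1L, iv,     ipn),
            idx_ring(iu,     iv + 1L, ipn), idx_ring(iu + 1L, iv + 1L, ipn))
          hexes[[length(hexes) + 1L]] <- matrix(corners[t(kuhn)],
                                                ncol = 4, byrow = TRUE)
        }
      }
    }
  }
  el <- do.call(rbind, c(wedges, hexes))
  mesh <- sw_mesh(nodes, el)
  mesh$transmural <- transm
  zmin <- min(nodes[, 3])
  mesh$height <- (nodes[, 3] - zmin) / (zb - zmin)
  mesh$e_c <- e_c; mesh$e_l <- e_l
  mesh$region <- rep("remote", n_nodes)
  mesh$layer <- rep("mid", n_nodes)
  mesh$resolution <- resolution
  attr(mesh, "geometry") <- list(a_endo = a_endo, c_endo = c_endo,
                                 a_epi = a_epi, c_epi = c_epi,
                                 wall_offset = h, z_base = zb,
                                 aspect_ratio = aspect_ratio)
  mesh
}

#' Assign a rule-based transmural helix fiber field
#'
#' The helix angle varies linearly in the transmural coordinate from
#' \code{helix_endo} at the endocardium to \code{helix_epi} at the
#' epicardium; fibers lie in the local circumferential-longitudinal plane.
#' On fixture meshes (no parametric frame) fibers are set parallel to the
#' first axis.
#'
#' @param mesh an \code{sw_mesh} carrying a transmural coordinate.
#' @param helix_endo,helix_epi helix angles in degrees.
#' @return the mesh with per-element unit \code{fibers}.
#' @export
assign_fibers <- function(mesh, helix_endo = 60, helix_epi = -60) {
  if (is.null(mesh$transmural))
    stop("mesh has no transmural coordinate")
  el <- mesh$elems; k <- ncol(el)
  u_el <- rowMeans(matrix(mesh$transmural[el], ncol = k))
  helix <- (helix_endo + (helix_epi - helix_endo) * u_el) * pi / 180
  if (is.null(mesh$e_c)) {
    # fixture: uniform frame along the first axis
    ec <- matrix(rep(c(1, 0, 0), each = nrow(el)), ncol = 3)
    elv <- matrix(rep(c(0, 1, 0), each = nrow(el)), ncol = 3)
  } else {
    avg <- function(M) {
      out <- matrix(0, nrow(el), 3)
      for (j in seq_len(k)) out <- out + M[el[, j], , drop = FALSE]
      out / k
    }
    ec <- avg(mesh$e_c)
    ec <- ec / pmax(sqrt(rowSums(ec^2)), 1e-12)
    elv <- avg(mesh$e_l)
    elv <- elv - rowSums(elv * ec) * ec   # orthogonalize
    elv <- elv / pmax(sqrt(rowSums(elv^2)), 1e-12)
  }
  f <- cos(helix) * ec + sin(helix) * elv
  mesh$fibers <- f / sqrt(rowSums(f^2))
  mesh
}

#' Assign transmural layer labels
#'
#' Nodes are binned by the normalized transmural coordinate into the four
#' standard layers, endocardium adjacent to the cavity.
#'
#' @param mesh an \code{sw_mesh} with a transmural coordinate.
#' @param thickness_fractions length-4 nonnegative vector summing to 1
#'   (endo, sub-endo, mid, epi).
#' @return mesh with per-node \code{layer} labels.
#' @export
assign_layers <- function(mesh,
                          thickness_fractions = c(0.25, 0.25, 0.25, 0.25)) {
  if (length(thickness_fractions) != 4 || any(thickness_fractions < 0) ||
      abs(sum(thickness_fractions) - 1) > 1e-9)
    stop("thickness_fractions must be 4 nonnegative values summing to 1")
  if (is.null(mesh$transmural)) stop("mesh has no transmural coordinate")
  edges <- cumsum(thickness_fractions)
  lab <- c("endo", "sub_endo", "mid", "epi")
  u <- mesh$transmural
  # left-open bins so zero-width layers never capture nodes
  bin <- 1L + (u > edges[1]) + (u > edges[2]) + (u > edges[3])
  mesh$layer <- lab[bin]
  mesh
}

#' Infarct specification
#'
#' @param height_extent pair of normalized height fractions delimiting the
#'   infarct core along the ventricle height.
#' @param transmurality fraction of the wall depth (from the endocardium)
#'   occupied by the core.
#' @param bz_thickness border-zone thickness (mm).
#' @param angular_extent circumferential extent of the core (radians),
#'   centered on phi = 0.
#' @return an object of class \code{sw_infarct_spec}.
#' @export
infarct_spec <- function(height_extent = c(0.14, 0.51), transmurality = 1.0,
                         bz_thickness = 9, angular_extent = 0.15) {
  if (any(height_extent < 0) || any(height_extent > 1) ||
      height_extent[1] >= height_extent[2])
    stop("height_extent must be an increasing pair in [0, 1]")
  if (transmurality < 0 || transmurality > 1)
    stop("transmurality must lie in [0, 1]")
  if (bz_thickness < 0) stop("bz_thickness must be nonnegative")
  structure(list(height_extent = height_extent,
                 transmurality = transmurality,
                 bz_thickness = bz_thickness,
                 angular_extent = angular_extent),
            class = "sw_infarct_spec")
}

#' Label infarct core and border zone and build the infarct-density field
#'
#' Core nodes lie inside the height/angular/transmural extent; the
#' structural border zone is the shell within \code{bz_thickness} of the
#' core (Euclidean distance to the nearest core node). The infarct-density
#' factor is 0 in the core, 1 in remote tissue and distance-linear across
#' the border zone; the passive-stiffness factor runs 10 (core) to 1
#' (remote) on the same coordinate.
#'
#' @param mesh an \code{sw_mesh} with transmural and height coordinates.
#' @param spec an \code{\link{infarct_spec}}.
#' @return mesh with \code{region}, \code{fact}, \code{fpas} and
#'   \code{core_dist} (mm, 0 inside the core) fields.
#' @export
assign_infarct <- function(mesh, spec) {
  stopifnot(inherits(spec, "sw_infarct_spec"))
  if (is.null(mesh$height) || is.null(mesh$transmural))
    stop("mesh has no height/transmural coordinates")
  phi <- atan2(mesh$nodes[, 2], mesh$nodes[, 1])
  dphi <- abs(((phi + pi) %% (2 * pi)) - pi)
  core <- mesh$height >= spec$height_extent[1] &
          mesh$height <= spec$height_extent[2] &
          dphi <= spec$angular_extent / 2 &
          mesh$transmural <= spec$transmurality + 1e-12
  n <- nrow(mesh$nodes)
  if (!any(core)) {
    warning("infarct specification does not intersect the mesh: empty core")
    mesh$region <- rep("remote", n)
    mesh$fact <- rep(1, n); mesh$fpas <- rep(1, n)
    mesh$core_dist <- rep(Inf, n)
    return(mesh)
  }
  cd <- rep(Inf, n)
  cd[core] <- 0
  P <- mesh$nodes
  Q <- P[core, , drop = FALSE]
  # bounding-box prefilter before the chunked cross-distance computation
  pad <- spec$bz_thickness + 1e-9
  cand <- which(!core &
                P[, 1] >= min(Q[, 1]) - pad & P[, 1] <= max(Q[, 1]) + pad &
                P[, 2] >= min(Q[, 2]) - pad & P[, 2] <= max(Q[, 2]) + pad &
                P[, 3] >= min(Q[, 3]) - pad & P[, 3] <= max(Q[, 3]) + pad)
  if (length(cand)) {
    q2 <- rowSums(Q^2)
    chunk <- max(1L, floor(2e7 / nrow(Q)))
    for (s in split(cand, ceiling(seq_along(cand) / chunk))) {
      p <- P[s, , drop = FALSE]
      d2 <- outer(rowSums(p^2), q2, "+") - 2 * p %*% t(Q)
      cd[s] <- sqrt(pmax(apply(d2, 1, min), 0))
    }
  }
  region <- ifelse(core, "core",
                   ifelse(cd <= spec$bz_thickness, "structural_bz", "remote"))
  ramp <- pmin(cd / max(spec$bz_thickness, 1e-12), 1)
  mesh$region <- region
  mesh$fact <- ifelse(core, 0, ramp)
  mesh$fpas <- ifelse(core, 10, 10 - 9 * ramp)
  mesh$core_dist <- cd
  mesh
}

#' Build a regular cable, sheet, or slab fixture mesh
#'
#' Regular simplicial meshes with uniform fibers along the first axis,
#' all-remote region labels, unit infarct density, and a transmural
#' coordinate along the last axis present (so layer assignment can be
#' exercised on fixtures).
#'
#' @param kind one of "cable", "sheet", "slab".
#' @param lengths numeric vector of dimensions (mm): 1, 2 or 3 values.
#' @param resolution node spacing (mm).
#' @param cross_section cross-sectional area (mm^2, cable) or thickness
#'   (mm, sheet).
#' @return an \code{sw_mesh}.
#' @export
build_fixture <- function(kind = c("cable", "sheet", "slab"), lengths,
                          resolution = 0.25, cross_section = 1) {
  kind <- match.arg(kind)
  if (any(lengths <= 0) || resolution <= 0)
    stop("dimensions and resolution must be positive")
  dim_needed <- c(cable = 1, sheet = 2, slab = 3)[[kind]]
  lengths <- rep_len(lengths, dim_needed)
  ns <- pmax(2L, as.integer(round(lengths / resolution)) + 1L)
  xs <- lapply(seq_len(dim_needed),
               function(j) seq(0, lengths[j], length.out = ns[j]))
  if (kind == "cable") {
    nodes <- cbind(xs[[1]], 0, 0)
    elems <- cbind(seq_len(ns[1] - 1L), seq(2L, ns[1]))
    mesh <- sw_mesh(nodes, elems, cross_section = cross_section)
    mesh$transmural <- xs[[1]] / lengths[1]
  } else if (kind == "sheet") {
    # hexagonal (equilateral-triangle) lattice: 6-fold symmetric P1
    # stiffness keeps the numerical conduction velocity nearly isotropic,
    # unlike triangulated square lattices (diagonal bias of several %)
    h <- resolution
    hy <- h * sqrt(3) / 2
    nx <- max(2L, as.integer(round(lengths[1] / h)) + 1L)
    ny <- max(2L, as.integer(round(lengths[2] / hy)) + 1L)
    xo <- (seq_len(ny) %% 2L) * h / 2   # row offsets alternate 0, h/2
    nodes <- cbind(rep(seq_len(nx) - 1L, ny) * h + rep(xo, each = nx),
                   rep(seq_len(ny) - 1L, each = nx) * hy, 0)
    id <- function(i, j) (j - 1L) * nx + i
    tri <- vector("list", ny - 1L)
    for (j in seq_len(ny - 1L)) {
      i <- seq_len(nx - 1L)
      if (xo[j] < xo[j + 1L]) {       # upper row shifted right
        tri[[j]] <- rbind(cbind(id(i, j), id(i + 1L, j), id(i, j + 1L)),
                          cbind(id(i + 1L, j), id(i + 1L, j + 1L),
                                id(i, j + 1L)))
      } else {                         # lower row shifted right
        tri[[j]] <- rbind(cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)),
                          cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)))
      }
    }
    elems <- do.call(rbind, tri)
    mesh <- sw_mesh(nodes, elems, cross_section = cross_section)
    mesh$transmural <- nodes[, 2] / max(nodes[, 2])
  } else {
    g <- expand.grid(x = xs[[1]], y = xs[[2]], z = xs[[3]])
    nodes <- cbind(g$x, g$y, g$z)
    id <- function(i, j, k) ((k - 1L) * ns[2] + (j - 1L)) * ns[1] + i
    ii <- rep(seq_len(ns[1] - 1L), (ns[2] - 1L) * (ns[3] - 1L))
    jj <- rep(rep(seq_len(ns[2] - 1L), each = ns[1] - 1L), ns[3] - 1L)
    kk <- rep(seq_len(ns[3] - 1L), each = (ns[1] - 1L) * (ns[2] - 1L))
    corn <- function(di, dj, dk) id(ii + di, jj + dj, kk + dk)
    # corner order matches the Kuhn split used for the ventricle mesh
    C <- cbind(corn(0, 0, 0), corn(1, 0, 0), corn(0, 1, 0), corn(1, 1, 0),
               corn(0, 0, 1), corn(1, 0, 1), corn(0, 1, 1), corn(1, 1, 1))
    kuhn <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                  c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
    elems <- do.call(rbind, lapply(seq_len(6), function(t) C[, kuhn[t, ]]))
    mesh <- sw_mesh(nodes, elems)
    mesh$transmural <- nodes[, 3] / lengths[3]
  }
  n <- nrow(mesh$nodes)
  mesh$height <- mesh$nodes[, 1] / lengths[1]
  mesh$region <- rep("remote", n)
  mesh$layer <- rep("mid", n)
  mesh$fact <- rep(1, n); mesh$fpas <- rep(1, n)
  mesh$resolution <- resolution
  mesh <- assign_fibers(mesh, 0, 0)
  mesh
}

#' Label a disc-shaped infarct on a fixture mesh
#'
#' Convenience analogue of \code{\link{assign_infarct}} for sheet/slab
#' fixtures: a circular (cylindrical) core of given radius around a center,
#' a border zone within \code{bz_thickness} of it, and the distance-linear
#' infarct-density ramp.
#'
#' @param mesh a fixture \code{sw_mesh}.
#' @param center core center (coordinates, mm).
#' @param core_radius core radius (mm).
#' @param bz_thickness border-zone thickness (mm).
#' @return mesh with \code{region}, \code{fact}, \code{fpas},
#'   \code{core_dist}.
#' @export
assign_disc_infarct <- function(mesh, center, core_radius, bz_thickness = 9) {
  ctr <- rep_len(as.numeric(center), 3)
  d <- sqrt(colSums((t(mesh$nodes) - ctr)^2))
  cd <- pmax(d - core_radius, 0)
  core <- cd == 0
  if (!any(core)) warning("disc infarct does not intersect the mesh")
  ramp <- pmin(cd / max(bz_thickness, 1e-12), 1)
  mesh$region <- ifelse(core, "core",
                        ifelse(cd <= bz_thickness, "structural_bz", "remote"))
  mesh$fact <- ifelse(core, 0, ramp)
  mesh$fpas <- ifelse(core, 10, 10 - 9 * ramp)
  mesh$core_dist <- cd
  mesh
}
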