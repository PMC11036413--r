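# Linear-element FEM machinery shared by the monodomain solver and the
# repolarization-gradient analysis: shape-function gradients, anisotropic
# stiffness assembly with lumped mass, and barycentric point interpolation.

# Per-element shape-function gradients for simplices embedded in 3-D.
# Returns a list with G: m x k x 3 array (gradient of shape function of
# local vertex j, rows = elements).
shape_gradients <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems; k <- ncol(el); m <- nrow(el)
  G <- array(0, c(m, k, 3))
  # edge vectors from vertex 1
  E <- lapply(2:k, function(j)
    nd[el[, j], , drop = FALSE] - nd[el[, 1], , drop = FALSE])
  if (k == 2) {
    len2 <- rowSums(E[[1]]^2)
    G[, 2, ] <- E[[1]] / len2
    G[, 1, ] <- -G[, 2, ]
  } else {
    # solve the (k-1)x(k-1) Gram system per element, vectorized over m
    d <- k - 1
    Gram <- array(0, c(m, d, d))
    for (a in seq_len(d)) for (b in seq_len(d))
      Gram[, a, b] <- rowSums(E[[a]] * E[[b]])
    if (d == 2) {
      det <- Gram[, 1, 1] * Gram[, 2, 2] - Gram[, 1, 2]^2
      inv11 <- Gram[, 2, 2] / det; inv22 <- Gram[, 1, 1] / det
      inv12 <- -Gram[, 1, 2] / det
      for (x in 1:3) {
        G[, 2, x] <- inv11 * E[[1]][, x] + inv12 * E[[2]][, x]
        G[, 3, x] <- inv12 * E[[1]][, x] + inv22 * E[[2]][, x]
      }
    } else {
      # 3x3 inverse via adjugate, vectorized
      a11 <- Gram[, 1, 1]; a12 <- Gram[, 1, 2]; a13 <- Gram[, 1, 3]
      a22 <- Gram[, 2, 2]; a23 <- Gram[, 2, 3]; a33 <- Gram[, 3, 3]
      det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
             a13 * (a12 * a23 - a22 * a13)
      i11 <- (a22 * a33 - a23^2) / det
      i12 <- (a13 * a23 - a12 * a33) / det
      i13 <- (a12 * a23 - a13 * a22) / det
      i22 <- (a11 * a33 - a13^2) / det
      i23 <- (a12 * a13 - a11 * a23) / det
      i33 <- (a11 * a22 - a12^2) / det
      for (x in 1:3) {
        G[, 2, x] <- i11 * E[[1]][, x] + i12 * E[[2]][, x] + i13 * E[[3]][, x]
        G[, 3, x] <- i12 * E[[1]][, x] + i22 * E[[2]][, x] + i23 * E[[3]][, x]
        G[, 4, x] <- i13 * E[[1]][, x] + i23 * E[[2]][, x] + i33 * E[[3]][, x]
      }
    }
    G[, 1, ] <- -apply(G[, -1, , drop = FALSE], c(1, 3), sum)
  }
  G
}

# Assemble the sparse stiffness matrix K (mS mm^-1 scale) for per-element
# 3x3 conductivity tensors given as an m x 6 matrix of the upper triangle
# (xx, yy, zz, xy, xz, yz); returns a dgCMatrix.
assemble_stiffness <- function(mesh, sigma6) {
  el <- mesh$elems; k <- ncol(el); m <- nrow(el)
  G <- shape_gradients(mesh)
  vol <- mesh$elem_vol
  ii <- jj <- xx <- vector("list", k * k)
  q <- 0L
  # sigma * grad for each local vertex
  SG <- array(0, c(m, k, 3))
  for (j in seq_len(k)) {
    gx <- G[, j, 1]; gy <- G[, j, 2]; gz <- G[, j, 3]
    SG[, j, 1] <- sigma6[, 1] * gx + sigma6[, 4] * gy + sigma6[, 5] * gz
    SG[, j, 2] <- sigma6[, 4] * gx + sigma6[, 2] * gy + sigma6[, 6] * gz
    SG[, j, 3] <- sigma6[, 5] * gx + sigma6[, 6] * gy + sigma6[, 3] * gz
  }
  for (a in seq_len(k)) for (b in seq_len(k)) {
    q <- q + 1L
    val <- vol * (G[, a, 1] * SG[, b, 1] + G[, a, 2] * SG[, b, 2] +
                  G[, a, 3] * SG[, b, 3])
    ii[[q]] <- el[, a]; jj[[q]] <- el[, b]; xx[[q]] <- val
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2))
}

# CSR triplet (0-based) of A = M^-1 K / (beta*Cm) for the C++ stepper.
# beta in um^-1 is converted to mm^-1; Cm in uF/cm^2 to uF/mm^2.
diffusion_operator <- function(mesh, sigma6, beta = 0.14, cm = 1) {
  K <- assemble_stiffness(mesh, sigma6)
  beta_cm <- (beta * 1000) * (cm / 100)   # uF / mm^3
  A <- Matrix::Diagonal(x = 1 / mesh$node_vol) %*% K / beta_cm
  A <- as(as(A, "generalMatrix"), "RsparseMatrix")
  list(p = A@p, j = A@j, x = A@x)
}

#' Interpolate a nodal field from one mesh onto points or another mesh
#'
#' Barycentric linear interpolation inside the enclosing source element,
#' with a nearest-element fallback for points lying outside the source mesh
#' by at most one resolution length.
#'
#' @param coarse_mesh source \code{sw_mesh}.
#' @param field per-node values on \code{coarse_mesh}.
#' @param fine_mesh target \code{sw_mesh}, or a numeric matrix of points
#'   (one row per query, 3 columns).
#' @param max_outside maximum allowed distance (mm) outside the source mesh
#'   before an error is raised; defaults to the source resolution.
#' @return numeric vector of interpolated values, one per target point.
#' @export
interpolate_field <- function(coarse_mesh, field, fine_mesh,
                              max_outside = NULL) {
  stopifnot(length(field) == nrow(coarse_mesh$nodes))
  pts <- if (inherits(fine_mesh, "sw_mesh")) fine_mesh$nodes else {
    p <- as.matrix(fine_mesh)
    if (ncol(p) == 2) p <- cbind(p, 0)
    if (ncol(p) == 1) p <- cbind(p, 0, 0)
    p
  }
  if (is.null(max_outside))
    max_outside <- if (is.finite(coarse_mesh$resolution))
      coarse_mesh$resolution else
      max(sqrt(rowSums((coarse_mesh$nodes[coarse_mesh$elems[, 2], ,
                        drop = FALSE] -
                        coarse_mesh$nodes[coarse_mesh$elems[, 1], ,
                        drop = FALSE])^2)))
  bary <- barycentric_coords(coarse_mesh, pts)
  out <- numeric(nrow(pts))
  el <- coarse_mesh$elems
  for (q in seq_len(nrow(pts))) {
    lam <- bary$lambda[q, ]
    e <- bary$elem[q]
    if (bary$penalty[q] > max_outside)
      stop("projection error: point ", q, " lies ",
           format(bary$penalty[q], digits = 3),
           " mm outside the source mesh (limit ", max_outside, " mm)")
    lam <- pmax(lam, 0); lam <- lam / sum(lam)  # clamp fallback points
    out[q] <- sum(field[el[e, ]] * lam[seq_len(ncol(el))])
  }
  out
}

# For each query point: enclosing (or nearest) element, barycentric
# coordinates there, and a penalty = how far outside the element the point
# lies (0 when inside).
barycentric_coords <- function(mesh, pts) {
  el <- mesh$elems; k <- ncol(el); nd <- mesh$nodes; m <- nrow(el)
  nq <- nrow(pts)
  G <- shape_gradients(mesh)  # gradients double as barycentric differentials
  x1 <- nd[el[, 1], , drop = FALSE]
  lambda <- matrix(0, nq, k); elem <- integer(nq); penalty <- numeric(nq)
  # characteristic element size for the out-of-plane penalty
  h_el <- (mesh$elem_vol / mesh$cross_section)^(1 / mesh$dim)
  for (q in seq_len(nq)) {
    d <- sweep(x1, 2, pts[q, ], function(a, b) b - a)  # p - x1 per element
    lam <- matrix(0, m, k)
    for (j in 2:k)
      lam[, j] <- G[, j, 1] * d[, 1] + G[, j, 2] * d[, 2] + G[, j, 3] * d[, 3]
    lam[, 1] <- 1 - rowSums(lam[, -1, drop = FALSE])
    # in-plane deficit
    neg <- pmax(0, -apply(lam, 1, min))
    # out-of-plane distance for lower-dimensional elements: reconstruct the
    # in-plane point x1 + sum_j lam_j (x_j - x1) and measure the offset
    if (mesh$dim < 3) {
      rec <- x1
      for (j in 2:k) rec <- rec + lam[, j] *
          (nd[el[, j], , drop = FALSE] - x1)
      off <- sqrt(rowSums((rec - matrix(pts[q, ], m, 3, byrow = TRUE))^2))
    } else off <- 0
    score <- neg * h_el + off
    e <- which.min(score)
    elem[q] <- e; lambda[q, ] <- lam[e, ]; penalty[q] <- score[e]
  }
  list(elem = elem, lambda = lambda, penalty = penalty)
}
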