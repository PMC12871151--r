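#' Linear-elastic substrate description
#'
#' @param youngs_modulus Young's modulus in Pa (default 5000, a 5 kPa
#'   silicone gel).
#' @param poisson_ratio Poisson ratio, 0 to 0.5 (default 0.5,
#'   incompressible silicone).
#' @return An `elastic_substrate` object.
#' @export
elastic_substrate <- function(youngs_modulus = 5000, poisson_ratio = 0.5) {
  stopifnot(youngs_modulus > 0, poisson_ratio >= 0, poisson_ratio <= 0.5)
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "elastic_substrate")
}

#' Regular quadrilateral traction mesh
#'
#' Piecewise-constant traction elements on a regular grid: nodes are the
#' element centers. Positions in micrometres.
#'
#' @param xlim,ylim extent of the meshed region in um.
#' @param nx,ny number of elements per axis.
#' @return A `traction_mesh` with `nodes` (data frame of x, y), element
#'   sizes `dx`, `dy` and `element_area` (um^2).
#' @export
traction_mesh <- function(xlim, ylim, nx, ny) {
  stopifnot(nx >= 1, ny >= 1, diff(xlim) > 0, diff(ylim) > 0)
  dx <- diff(xlim) / nx; dy <- diff(ylim) / ny
  xs <- xlim[1] + (seq_len(nx) - 0.5) * dx
  ys <- ylim[1] + (seq_len(ny) - 0.5) * dy
  nodes <- expand.grid(x = xs, y = ys)
  structure(list(nodes = nodes, nx = nx, ny = ny, dx = dx, dy = dy,
                 xlim = xlim, ylim = ylim, element_area = dx * dy),
            class = "traction_mesh")
}

#' Gridded traction field on a mesh
#'
#' @param mesh a [traction_mesh()].
#' @param tx,ty traction components in Pa at every mesh node.
#' @param regularization_parameter,residual_norm,solution_norm inversion
#'   metadata (NA for ground-truth fields).
#' @param substrate the `elastic_substrate` the field refers to.
#' @return A `traction_field` object.
#' @export
traction_field <- function(mesh, tx, ty, regularization_parameter = NA_real_,
                           residual_norm = NA_real_,
                           solution_norm = NA_real_, substrate = NULL) {
  stopifnot(inherits(mesh, "traction_mesh"),
            length(tx) == nrow(mesh$nodes), length(ty) == nrow(mesh$nodes),
            all(is.finite(tx)), all(is.finite(ty)))
  structure(list(mesh = mesh, tx = tx, ty = ty,
                 regularization_parameter = regularization_parameter,
                 residual_norm = residual_norm,
                 solution_norm = solution_norm, substrate = substrate),
            class = "traction_field")
}

#' @export
print.traction_field <- function(x, ...) {
  cat(sprintf(
    "traction_field: %d x %d elements (%.3g x %.3g um), |t| max %.4g Pa, lambda = %.4g\n",
    x$mesh$nx, x$mesh$ny, x$mesh$dx, x$mesh$dy,
    max(sqrt(x$tx^2 + x$ty^2)), x$regularization_parameter))
  invisible(x)
}

# Gauss-Legendre nodes/weights on [a, b]; unit-interval rules are cached
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n, a, b) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  gl <- .gl_cache[[key]]
  list(x = (a + b) / 2 + (b - a) / 2 * gl$x, w = (b - a) / 2 * gl$w)
}

# Integral of the Boussinesq-Cerruti surface Green's tensor over one
# rectangular element, evaluated at point p (2-vector), element center c,
# half-sizes hx, hy. The kernel for tangential surface loads is
#   G(r) = (1+nu)/(pi E r) [ (1-nu) I + nu rr^T / r^2 ].
# Far points use tensor-product Gauss quadrature; points inside (or on) the
# element use polar integration over the four triangles formed with the
# corners, where the 1/r singularity cancels exactly against the Jacobian:
#   int_tri G = (1+nu)/(pi E) int_theta [ (1-nu) I + nu e e^T ] R(theta) dtheta.
element_green_integral <- function(p, cx, cy, hx, hy, E, nu) {
  pref <- (1 + nu) / (pi * E)
  x1 <- cx - hx; x2 <- cx + hx; y1 <- cy - hy; y2 <- cy + hy
  inside <- p[1] >= x1 && p[1] <= x2 && p[2] >= y1 && p[2] <= y2
  if (!inside) {
    d <- sqrt((p[1] - cx)^2 + (p[2] - cy)^2)
    h <- sqrt(hx^2 + hy^2)
    n <- if (d > 6 * h) 3 else if (d > 2 * h) 6 else 12
    gx <- gauss_legendre(n, x1, x2); gy <- gauss_legendre(n, y1, y2)
    X <- outer(gx$x, rep(1, n)); Y <- outer(rep(1, n), gy$x)
    W <- outer(gx$w, gy$w)
    rx <- p[1] - X; ry <- p[2] - Y
    r2 <- rx^2 + ry^2; r <- sqrt(r2)
    gxx <- sum(W * ((1 - nu) / r + nu * rx^2 / (r * r2)))
    gyy <- sum(W * ((1 - nu) / r + nu * ry^2 / (r * r2)))
    gxy <- sum(W * (nu * rx * ry / (r * r2)))
    return(pref * matrix(c(gxx, gxy, gxy, gyy), 2, 2))
  }
  # polar integration: 4 triangles (p, corner_i, corner_{i+1})
  corners <- matrix(c(x1, y1, x2, y1, x2, y2, x1, y2), 2)
  acc <- matrix(0, 2, 2)
  nq <- 16
  for (k in 1:4) {
    a <- corners[, k] - p
    b <- corners[, if (k == 4) 1 else k + 1] - p
    th_a <- atan2(a[2], a[1]); th_b <- atan2(b[2], b[1])
    dth <- th_b - th_a
    if (dth <= -pi) dth <- dth + 2 * pi
    if (dth > pi) dth <- dth - 2 * pi
    if (abs(dth) < 1e-14) next
    gt <- gauss_legendre(nq, 0, abs(dth))
    sgn <- sign(dth)
    th <- th_a + sgn * gt$x
    e1 <- cos(th); e2 <- sin(th)
    # R(theta): distance from p to the segment a-b along direction theta;
    # line through a with normal n = perp(b - a): R = (a . n) / (e . n)
    nvec <- c(a[2] - b[2], b[1] - a[1])
    Rth <- (a[1] * nvec[1] + a[2] * nvec[2]) /
      (e1 * nvec[1] + e2 * nvec[2])
    Rth <- abs(Rth)
    acc[1, 1] <- acc[1, 1] + sum(gt$w * ((1 - nu) + nu * e1^2) * Rth)
    acc[2, 2] <- acc[2, 2] + sum(gt$w * ((1 - nu) + nu * e2^2) * Rth)
    acc[1, 2] <- acc[1, 2] + sum(gt$w * nu * e1 * e2 * Rth)
  }
  acc[2, 1] <- acc[1, 2]
  pref * acc
}

#' Assemble the BEM forward matrix mapping tractions to displacements
#'
#' For evaluation points `points` (data frame or matrix of x, y in um) and a
#' piecewise-constant traction mesh, returns the `2P x 2N` matrix `M` such
#' that `u = M %*% t`, with `u = (u_x..., u_y...)` in um and
#' `t = (t_x..., t_y...)` in Pa. Element integrals of the half-space
#' Green's tensor are computed by adaptive Gauss quadrature, switching to an
#' exact-in-radius polar scheme when the point lies on the element (the
#' pointwise kernel is never evaluated at its singularity).
#'
#' @param mesh a [traction_mesh()].
#' @param points evaluation positions in um.
#' @param substrate an [elastic_substrate()].
#' @return Dense numeric matrix.
#' @export
bem_forward_matrix <- function(mesh, points, substrate) {
  stopifnot(inherits(mesh, "traction_mesh"),
            inherits(substrate, "elastic_substrate"))
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  P <- nrow(pts); N <- nrow(mesh$nodes)
  E <- substrate$youngs_modulus; nu <- substrate$poisson_ratio
  hx <- mesh$dx / 2; hy <- mesh$dy / 2
  pref <- (1 + nu) / (pi * E)
  h <- sqrt(hx^2 + hy^2)
  M <- matrix(0, 2 * P, 2 * N)
  for (j in seq_len(N)) {
    cx <- mesh$nodes$x[j]; cy <- mesh$nodes$y[j]
    d <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
    on_elem <- pts[, 1] >= cx - hx & pts[, 1] <= cx + hx &
      pts[, 2] >= cy - hy & pts[, 2] <= cy + hy
    for (band in list(list(sel = !on_elem & d > 4 * h, n = 4),
                      list(sel = !on_elem & d <= 4 * h, n = 12))) {
      sel <- which(band$sel)
      if (!length(sel)) next
      gx <- gauss_legendre(band$n, cx - hx, cx + hx)
      gy <- gauss_legendre(band$n, cy - hy, cy + hy)
      qx <- rep(gx$x, times = band$n); qy <- rep(gy$x, each = band$n)
      qw <- rep(gx$w, times = band$n) * rep(gy$w, each = band$n)
      rx <- outer(pts[sel, 1], qx, "-")
      ry <- outer(pts[sel, 2], qy, "-")
      r2 <- rx^2 + ry^2; r <- sqrt(r2)
      wr <- matrix(qw, length(sel), length(qw), byrow = TRUE)
      gxx <- rowSums(wr * ((1 - nu) / r + nu * rx^2 / (r * r2)))
      gyy <- rowSums(wr * ((1 - nu) / r + nu * ry^2 / (r * r2)))
      gxy <- rowSums(wr * (nu * rx * ry / (r * r2)))
      M[sel, j] <- pref * gxx
      M[sel, N + j] <- pref * gxy
      M[P + sel, j] <- pref * gxy
      M[P + sel, N + j] <- pref * gyy
    }
    for (i in which(on_elem)) {
      G <- element_green_integral(pts[i, ], cx, cy, hx, hy, E, nu)
      M[i, j] <- G[1, 1]
      M[i, N + j] <- G[1, 2]
      M[P + i, j] <- G[2, 1]
      M[P + i, N + j] <- G[2, 2]
    }
  }
  M
}

#' Surface displacements generated by a traction field
#'
#' Forward model: tangential tractions on a semi-infinite elastic
#' half-space, integrated over the mesh elements (Boussinesq-Cerruti).
#'
#' @param traction a [traction_field()].
#' @param substrate an [elastic_substrate()].
#' @param eval_points data frame of x, y (um) where displacement is wanted.
#' @return Data frame with `x`, `y`, `ux`, `uy` in um.
#' @export
boussinesq_forward <- function(traction, substrate, eval_points) {
  stopifnot(inherits(traction, "traction_field"))
  M <- bem_forward_matrix(traction$mesh, eval_points, substrate)
  u <- as.vector(M %*% c(traction$tx, traction$ty))
  P <- nrow(as.data.frame(eval_points))
  data.frame(x = as.data.frame(eval_points)$x,
             y = as.data.frame(eval_points)$y,
             ux = u[1:P], uy = u[P + 1:P])
}
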