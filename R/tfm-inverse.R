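# Zero-normalized cross-correlation of template within search region, all
# valid placements; FFT numerator + integral-image local sums.
normxcorr_valid <- function(template, search) {
  th <- nrow(template); tw <- ncol(template)
  sh <- nrow(search); sw <- ncol(search)
  stopifnot(sh >= th, sw >= tw)
  tz <- template - mean(template)
  tnorm <- sqrt(sum(tz^2))
  nr <- sh; nc <- sw
  FA <- stats::fft(search)
  pad <- matrix(0, nr, nc)
  pad[1:th, 1:tw] <- tz[th:1, tw:1]          # flip for correlation
  num_full <- Re(stats::fft(FA * stats::fft(pad), inverse = TRUE)) / (nr * nc)
  num <- num_full[th:sh, tw:sw]
  # local sums over th x tw windows via cumulated sums
  locsum <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
    cs <- t(cs)
    csp <- matrix(0, nr + 1, nc + 1)
    csp[2:(nr + 1), 2:(nc + 1)] <- cs
    csp[(th + 1):(nr + 1), (tw + 1):(nc + 1)] -
      csp[1:(nr - th + 1), (tw + 1):(nc + 1)] -
      csp[(th + 1):(nr + 1), 1:(nc - tw + 1)] +
      csp[1:(nr - th + 1), 1:(nc - tw + 1)]
  }
  s1 <- locsum(search)
  s2 <- locsum(search^2)
  denom <- tnorm * sqrt(pmax(s2 - s1^2 / (th * tw), 0))
  out <- num / denom
  out[!is.finite(out)] <- 0
  out
}

# 3-point parabolic sub-pixel offset around a peak value triple
parabolic_offset <- function(m, c, p) {
  den <- m - 2 * c + p
  if (den >= 0) return(0)                      # not a proper maximum
  off <- 0.5 * (m - p) / den
  max(min(off, 0.5), -0.5)
}

#' Bead displacement field by cross-correlation particle tracking
#'
#' Beads are detected in the relaxed (cell-free) image; for each bead a
#' square template is matched against the stressed image within a search
#' window of `max_displacement` pixels by zero-normalized cross-correlation,
#' with sub-pixel peak refinement by 3-point parabolic interpolation per
#' axis. Vectors whose correlation peak falls below `corr_floor` are marked
#' invalid (candidate outliers for [filter_displacement_outliers()]).
#'
#' @param stressed,relaxed 2-D matrices of identical dimension (stressed =
#'   with cell, relaxed = after cell removal).
#' @param template_size square template edge in pixels (odd; default 17).
#' @param max_displacement search radius in pixels (default 50).
#' @param pixel_size um per pixel (converts output to um).
#' @param sigma bead PSF sd in pixels for the detection step.
#' @param corr_floor minimum acceptable correlation peak.
#' @return A `displacement_field` data frame: `x`, `y`, `ux`, `uy` (um),
#'   `correlation_peak`, `valid`, `outlier_mask`. Pixel size kept as an
#'   attribute.
#' @export
ptv_displacement <- function(stressed, relaxed, template_size = 17,
                             max_displacement = 50, pixel_size = 1,
                             sigma = 2.1, corr_floor = 0.5) {
  stopifnot(is.matrix(stressed), is.matrix(relaxed),
            all(dim(stressed) == dim(relaxed)),
            template_size %% 2 == 1, max_displacement >= 1)
  # beads are dense fiducials: skip the point-source shape filter, which is
  # tuned for isolated adhesions; bad matches are caught by the correlation
  # floor and the neighborhood outlier test instead
  beads <- detect_point_sources(relaxed, sigma = sigma, gof_p = 0)
  t2 <- (template_size - 1) / 2
  nr <- nrow(relaxed); nc <- ncol(relaxed)
  rows <- vector("list", nrow(beads))
  for (i in seq_len(nrow(beads))) {
    cx <- round(beads$x[i]) + 1; ry <- round(beads$y[i]) + 1
    if (ry - t2 < 1 || ry + t2 > nr || cx - t2 < 1 || cx + t2 > nc) next
    tpl <- relaxed[(ry - t2):(ry + t2), (cx - t2):(cx + t2)]
    r0 <- max(1, ry - t2 - max_displacement)
    r1 <- min(nr, ry + t2 + max_displacement)
    c0 <- max(1, cx - t2 - max_displacement)
    c1 <- min(nc, cx + t2 + max_displacement)
    cc <- normxcorr_valid(tpl, stressed[r0:r1, c0:c1])
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    peak <- cc[pk[1], pk[2]]
    if (peak >= 1 - 1e-9) {
      dr <- dc <- 0                         # exact template match
    } else {
      dr <- ifelse(pk[1] > 1 && pk[1] < nrow(cc),
                   parabolic_offset(cc[pk[1] - 1, pk[2]], peak,
                                    cc[pk[1] + 1, pk[2]]), 0)
      dc <- ifelse(pk[2] > 1 && pk[2] < ncol(cc),
                   parabolic_offset(cc[pk[1], pk[2] - 1], peak,
                                    cc[pk[1], pk[2] + 1]), 0)
    }
    uy <- (r0 + pk[1] - 1 + dr) - (ry - t2)
    ux <- (c0 + pk[2] - 1 + dc) - (cx - t2)
    rows[[i]] <- data.frame(
      x = beads$x[i] * pixel_size, y = beads$y[i] * pixel_size,
      ux = ux * pixel_size, uy = uy * pixel_size,
      correlation_peak = peak, valid = peak >= corr_floor,
      outlier_mask = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0), ux = numeric(0),
                      uy = numeric(0), correlation_peak = numeric(0),
                      valid = logical(0), outlier_mask = logical(0))
  rownames(out) <- NULL
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("displacement_field", class(out))
  out
}

#' Normalized-median outlier filtering of a displacement field
#'
#' Universal normalized-median neighborhood test: for each vector, the
#' residual to the median of its `k` nearest valid neighbors is normalized
#' by the median residual of those neighbors (plus a noise floor `eps`);
#' vectors exceeding `threshold` in either component — and vectors already
#' invalid from the correlation floor — are replaced by the neighbor median
#' and flagged in `outlier_mask`.
#'
#' @param field a `displacement_field` from [ptv_displacement()].
#' @param threshold normalized residual threshold (default 2).
#' @param k number of nearest neighbors (default 8).
#' @param eps_px noise floor in pixels (default 0.1).
#' @return The field with replaced vectors and updated `outlier_mask`.
#' @export
filter_displacement_outliers <- function(field, threshold = 2, k = 8,
                                         eps_px = 0.1) {
  n <- nrow(field)
  if (n < k + 1) {
    warning("too few vectors for neighborhood filtering; field unchanged")
    return(field)
  }
  px <- attr(field, "pixel_size")
  if (is.null(px)) px <- 1
  eps <- eps_px * px
  D <- as.matrix(stats::dist(field[, c("x", "y")]))
  diag(D) <- Inf
  D[, !field$valid] <- Inf                   # invalid vectors aren't references
  ux <- field$ux; uy <- field$uy
  flag <- !field$valid
  med_x <- numeric(n); med_y <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(min(k, sum(is.finite(D[i, ]))))]
    nb <- nb[is.finite(D[i, nb])]
    if (length(nb) < 5) { med_x[i] <- ux[i]; med_y[i] <- uy[i]; next }
    mx <- stats::median(ux[nb]); my <- stats::median(uy[nb])
    med_x[i] <- mx; med_y[i] <- my
    rx <- abs(ux[i] - mx) / (stats::median(abs(ux[nb] - mx)) + eps)
    ry <- abs(uy[i] - my) / (stats::median(abs(uy[nb] - my)) + eps)
    if (max(rx, ry) > threshold) flag[i] <- TRUE
  }
  field$ux[flag] <- med_x[flag]
  field$uy[flag] <- med_y[flag]
  field$outlier_mask <- flag
  field$valid <- TRUE
  field
}

#' L2-regularized traction reconstruction
#'
#' Solves the Tikhonov problem
#' \eqn{\min_t \|M t - u\|^2 + \lambda \|t\|^2}
#' on a piecewise-constant traction mesh, where `M` is the BEM forward
#' matrix from [bem_forward_matrix()]. The residual and solution norms of
#' the chosen solution are recorded on the returned field.
#'
#' @param field a `displacement_field` (um); only rows with `valid` are used.
#' @param substrate an [elastic_substrate()].
#' @param mesh a [traction_mesh()].
#' @param lambda regularization parameter (>= 0).
#' @param forward_matrix optional precomputed forward matrix for these bead
#'   positions (saves reassembly across lambda values).
#' @return A [traction_field()] in Pa.
#' @export
reconstruct_traction <- function(field, substrate, mesh, lambda,
                                 forward_matrix = NULL) {
  stopifnot(lambda >= 0)
  use <- field$valid
  pts <- field[use, c("x", "y")]
  M <- if (is.null(forward_matrix))
    bem_forward_matrix(mesh, pts, substrate) else forward_matrix
  u <- c(field$ux[use], field$uy[use])
  A <- crossprod(M) + diag(lambda, ncol(M))
  if (lambda == 0 && rcond(A) < .Machine$double.eps * 100)
    stop("forward matrix is rank-deficient with lambda = 0; ",
         "use lambda > 0")
  t_hat <- solve(A, crossprod(M, u))
  N <- nrow(mesh$nodes)
  traction_field(mesh, tx = t_hat[1:N], ty = t_hat[N + 1:N],
                 regularization_parameter = lambda,
                 residual_norm = sqrt(sum((M %*% t_hat - u)^2)),
                 solution_norm = sqrt(sum(t_hat^2)),
                 substrate = substrate)
}

#' L-curve corner selection of the regularization parameter
#'
#' Sweeps `lambda_grid` (at least 10 values spanning at least 4 decades),
#' computes the residual and solution norms via one SVD of the forward
#' matrix, and returns the lambda of maximum (signed) curvature of the
#' spline-smoothed log-log L-curve. When the curvature has no positive
#' maximum (no corner — e.g. noiseless data), a warning is issued and the
#' curvature maximum is returned anyway, flagged.
#'
#' @inheritParams reconstruct_traction
#' @param lambda_grid increasing vector of candidate lambdas (> 0).
#' @return List: `lambda_corner`, `lcurve` (data frame of lambda, residual
#'   and solution norms, curvature), `corner_found`, `forward_matrix`.
#' @export
select_regularization <- function(field, substrate, mesh, lambda_grid,
                                  forward_matrix = NULL) {
  lambda_grid <- sort(lambda_grid)
  if (length(lambda_grid) < 10)
    stop("lambda grid too small: need >= 10 values")
  if (max(lambda_grid) / min(lambda_grid) < 1e4)
    stop("lambda grid must span at least 4 decades")
  use <- field$valid
  pts <- field[use, c("x", "y")]
  M <- if (is.null(forward_matrix))
    bem_forward_matrix(mesh, pts, substrate) else forward_matrix
  u <- c(field$ux[use], field$uy[use])
  sv <- svd(M)
  beta <- as.vector(crossprod(sv$u, u))
  u_out2 <- max(sum(u^2) - sum(beta^2), 0)   # component outside col space
  d <- sv$d
  rho <- eta <- kappa <- numeric(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    f <- d^2 / (d^2 + lambda_grid[i])
    rho[i] <- sqrt(sum(((1 - f) * beta)^2) + u_out2)
    eta[i] <- sqrt(sum((f / d * beta)^2))
    kappa[i] <- tikhonov_lcurve_curvature(lambda_grid[i], d, beta, u_out2)
  }
  # corner = interior local curvature maximum (grid-end maxima are
  # truncation artifacts, not corners)
  loc <- which(diff(sign(diff(kappa))) == -2) + 1
  loc <- loc[kappa[loc] > 0]
  corner_found <- length(loc) > 0
  i_best <- if (corner_found) loc[which.max(kappa[loc])] else
    which.max(kappa)
  if (!corner_found)
    warning("L-curve has no interior positive-curvature corner; ",
            "returning curvature maximum anyway")
  list(lambda_corner = lambda_grid[i_best],
       lcurve = data.frame(lambda = lambda_grid, residual_norm = rho,
                           solution_norm = eta, curvature = kappa),
       corner_found = corner_found, forward_matrix = M)
}

# Exact curvature of the Tikhonov L-curve (log rho, log eta) at lambda,
# from the SVD quantities: all derivatives of rho^2 and eta^2 with respect
# to lambda are closed-form sums over the spectrum, so no numerical
# differentiation is needed.
tikhonov_lcurve_curvature <- function(l, d, beta, u_out2 = 0) {
  b2 <- beta^2; d2 <- d^2; dl <- d2 + l
  r2 <- sum(b2 * l^2 / dl^2) + u_out2
  e2 <- sum(b2 * d2 / dl^2)
  dr2 <- sum(b2 * 2 * l * d2 / dl^3)          # d(rho^2)/d lambda
  de2 <- -2 * sum(b2 * d2 / dl^3)             # d(eta^2)/d lambda
  d2r2 <- sum(2 * b2 * d2 * (d2 - 2 * l) / dl^4)
  d2e2 <- 6 * sum(b2 * d2 / dl^4)
  # reparameterize by t = log(lambda)
  r2t <- l * dr2; e2t <- l * de2
  r2tt <- l * dr2 + l^2 * d2r2
  e2tt <- l * de2 + l^2 * d2e2
  xp <- 0.5 * r2t / r2; yp <- 0.5 * e2t / e2
  xpp <- 0.5 * (r2tt / r2 - (r2t / r2)^2)
  ypp <- 0.5 * (e2tt / e2 - (e2t / e2)^2)
  (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
}

#' Total traction force over the cell area
#'
#' Sum of traction magnitudes times element area over mesh nodes inside the
#' cell mask, in Pa um^2 (1e4 Pa um^2 = 10 nN).
#'
#' @param traction a [traction_field()].
#' @param cell_mask either a logical vector over mesh nodes, or a binary
#'   image matrix (with `pixel_size` in um) sampled at node positions.
#' @param pixel_size um per pixel of `cell_mask` when it is an image.
#' @return Total force in Pa um^2.
#' @export
total_force <- function(traction, cell_mask, pixel_size = NULL) {
  nodes <- traction$mesh$nodes
  if (is.matrix(cell_mask)) {
    if (is.null(pixel_size))
      stop("pixel_size required when cell_mask is an image")
    r <- round(nodes$y / pixel_size) + 1
    c <- round(nodes$x / pixel_size) + 1
    inside <- r >= 1 & r <= nrow(cell_mask) & c >= 1 & c <= ncol(cell_mask)
    sel <- inside
    sel[inside] <- cell_mask[cbind(r[inside], c[inside])] > 0
  } else {
    stopifnot(length(cell_mask) == nrow(nodes))
    sel <- as.logical(cell_mask)
  }
  if (!any(sel)) stop("empty cell mask")
  sum(sqrt(traction$tx[sel]^2 + traction$ty[sel]^2)) *
    traction$mesh$element_area
}

#' Mean traction magnitude at adhesions, grouped by class
#'
#' Bilinearly interpolates the traction magnitude at each adhesion position
#' (um) and averages per adhesion, then per adhesion class. Adhesions
#' outside the mesh are excluded and reported.
#'
#' @param traction a [traction_field()].
#' @param adhesions data frame with `x`, `y` (um), `adhesion_class`, and
#'   optionally `id` (several rows per adhesion footprint are averaged).
#' @return List: `per_adhesion` data frame, `class_means` named vector,
#'   `n_excluded`.
#' @export
adhesion_traction <- function(traction, adhesions) {
  mesh <- traction$mesh
  xs <- sort(unique(mesh$nodes$x)); ys <- sort(unique(mesh$nodes$y))
  mag <- matrix(sqrt(traction$tx^2 + traction$ty^2), length(xs),
                length(ys))                     # nodes ordered x-fastest
  inside <- adhesions$x >= min(xs) & adhesions$x <= max(xs) &
    adhesions$y >= min(ys) & adhesions$y <= max(ys)
  n_excluded <- sum(!inside)
  if (n_excluded > 0)
    message(n_excluded, " adhesion position(s) outside the traction mesh; excluded")
  a <- adhesions[inside, , drop = FALSE]
  if (is.null(a$id)) a$id <- seq_len(nrow(a))
  vals <- pracma::interp2(ys, xs, mag, a$y, a$x, method = "linear")
  per <- stats::aggregate(
    data.frame(traction = vals),
    by = list(id = a$id, adhesion_class = a$adhesion_class), FUN = mean)
  cm <- tapply(per$traction, per$adhesion_class, mean)
  list(per_adhesion = per, class_means = cm, n_excluded = n_excluded)
}
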