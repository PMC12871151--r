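# Shared fixture builders. All scenes are generated in code; nothing is
# read from disk.

# render a frame of isotropic Gaussian spots on a constant background
render_spot_frame <- function(nr, nc, spots, sigma = 2.1, background = 10) {
  fr <- matrix(background, nr, nc)
  X <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  Y <- matrix(0:(nr - 1), nr, nc)
  for (i in seq_len(nrow(spots)))
    fr <- fr + spots$amplitude[i] *
      exp(-((X - spots$x[i])^2 + (Y - spots$y[i])^2) / (2 * sigma^2))
  fr
}

# spots on a jittered grid so planted positions are >= min_sep apart
planted_spot_positions <- function(n, nr, nc, margin = 10, min_sep = 16) {
  gx <- seq(margin, nc - 1 - margin, by = min_sep)
  gy <- seq(margin, nr - 1 - margin, by = min_sep)
  g <- expand.grid(x = gx, y = gy)
  stopifnot(nrow(g) >= n)
  g <- g[sample.int(nrow(g), n), ]
  g$x <- g$x + stats::runif(n, -2, 2)
  g$y <- g$y + stats::runif(n, -2, 2)
  g
}

# match detections to planted positions within a radius; returns recall
# and precision
match_detections <- function(det, planted, radius = 2) {
  if (nrow(det) == 0)
    return(list(recall = 0, precision = NA_real_))
  D <- sqrt(outer(planted$x, det$x, "-")^2 + outer(planted$y, det$y, "-")^2)
  hit <- apply(D, 1, min) <= radius
  used <- apply(D, 2, min) <= radius
  list(recall = mean(hit), precision = mean(used))
}

# piecewise exponential-rise / plateau / exponential-decay intensity trace
piecewise_trace <- function(k_on, k_off, i0 = 50, plateau = 400,
                            dt = 20, n = 31, t_plateau_frac = 0.5) {
  tt <- (seq_len(n) - 1) * dt
  t_pl <- tt[ceiling(n * t_plateau_frac)]
  rise <- pmin(plateau, i0 * exp(k_on / 60 * tt))
  ifelse(tt <= t_pl, rise, rise[tt == t_pl][1] * exp(-k_off / 60 * (tt - t_pl)))
}

# two-patch traction dipole truth on a square mesh
dipole_truth <- function(mesh, substrate) {
  gaussian_traction_field(mesh, data.frame(
    x = c(24, 40), y = c(24, 40), sd = c(5, 5),
    tx = c(200, -200), ty = c(100, -100)), substrate)
}
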