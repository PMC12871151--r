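#' Scale-normalized Laplacian-of-Gaussian blob filter
#'
#' Convolves a frame with the negated, scale-normalized LoG kernel
#' \eqn{-\sigma^2 \nabla^2 G_\sigma}, so that bright blobs of width matching
#' `sigma` produce positive response peaks. The kernel is zero-mean, hence a
#' constant image maps to an (exactly) all-zero response.
#'
#' @param frame 2-D numeric matrix.
#' @param sigma kernel scale in pixels (> 0).
#' @return Filtered matrix of the same dimension.
#' @export
log_filter <- function(frame, sigma) {
  stopifnot(is.matrix(frame), sigma > 0)
  bad <- which(!is.finite(frame))
  if (length(bad)) {
    idx <- arrayInd(bad[seq_len(min(5, length(bad)))], dim(frame))
    stop("non-finite pixels at [row,col]: ",
         paste(apply(idx, 1, paste, collapse = ","), collapse = "; "))
  }
  k <- log_kernel(sigma)
  as.matrix(EBImage::filter2(frame, k, boundary = "replicate"))
}

# Negated scale-normalized LoG kernel, zero-mean so constants vanish.
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  xs <- -r:r
  g <- exp(-xs^2 / (2 * sigma^2))
  gx <- outer(g, g)                        # unnormalized Gaussian
  r2 <- outer(xs^2, xs^2, "+")
  k <- (2 * sigma^2 - r2) / sigma^2 * gx / (2 * pi * sigma^2)
  k - mean(k)
}

#' Robust per-frame noise estimate
#'
#' Estimates the additive noise standard deviation from the median absolute
#' deviation of horizontal first differences (structure-insensitive for
#' images whose features are wider than one pixel).
#'
#' @param frame 2-D numeric matrix.
#' @return Estimated noise sd (may be 0 for noiseless synthetic frames).
#' @export
estimate_noise_sd <- function(frame) {
  d <- frame[, -1] - frame[, -ncol(frame)]
  stats::mad(as.vector(d), center = 0) / sqrt(2)
}

# 8-connected local maxima; ties resolved to the first in raster order
# (row-major): strict > against raster-earlier neighbours, >= against later.
local_maxima <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- x
  sh <- function(dr, dc) pad[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc]
  ok <- x > sh(-1, -1) & x > sh(-1, 0) & x > sh(-1, 1) & x > sh(0, -1) &
        x >= sh(0, 1) & x >= sh(1, -1) & x >= sh(1, 0) & x >= sh(1, 1)
  which(ok, arr.ind = TRUE)
}

#' Fixed-width isotropic Gaussian fit of an intensity patch
#'
#' Least-squares fit of
#' \eqn{A \exp(-((x-x_0)^2+(y-y_0)^2)/(2\sigma^2)) + b}
#' with \eqn{\sigma} held fixed, by Levenberg-Marquardt. Coordinates are in
#' the global 0-based pixel-center convention; `patch_origin` gives the
#' (x, y) of the patch's `[1, 1]` pixel.
#'
#' @param patch 2-D numeric matrix spanning at least +/- 3 sigma around the
#'   center guess.
#' @param center_guess numeric `(x, y)` starting position, global coordinates.
#' @param sigma_fixed Gaussian sd in pixels, not optimized.
#' @param patch_origin global `(x, y)` of the patch's first pixel.
#' @return List with `x`, `y`, `amplitude`, `background`, `residuals`
#'   (matrix, data minus model), `converged`, and `ok` (`FALSE` when the fit
#'   failed to converge or the amplitude is non-positive — such detections
#'   are flagged, never silently dropped as `NaN`).
#' @export
fit_isotropic_gaussian <- function(patch, center_guess, sigma_fixed,
                                   patch_origin = c(0, 0)) {
  stopifnot(is.matrix(patch), length(center_guess) == 2, sigma_fixed > 0)
  xs <- patch_origin[1] + (seq_len(ncol(patch)) - 1)
  ys <- patch_origin[2] + (seq_len(nrow(patch)) - 1)
  X <- matrix(xs, nrow(patch), ncol(patch), byrow = TRUE)
  Y <- matrix(ys, nrow(patch), ncol(patch))
  s2 <- 2 * sigma_fixed^2

  model <- function(p) p[3] * exp(-((X - p[1])^2 + (Y - p[2])^2) / s2) + p[4]
  resid_fun <- function(p) as.vector(patch - model(p))

  b0 <- min(patch)
  a0 <- max(patch) - b0
  start <- c(center_guess[1], center_guess[2], max(a0, .Machine$double.eps),
             b0)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(x = NA_real_, y = NA_real_, amplitude = NA_real_,
                background = NA_real_, residuals = patch * NA,
                converged = FALSE, ok = FALSE))
  }
  p <- fit$par
  converged <- fit$info %in% 1:4
  res <- patch - model(p)
  amp_floor <- 1e-8 * max(abs(patch), 1)   # flat patches fit A ~ eps
  list(x = p[1], y = p[2], amplitude = p[3], background = p[4],
       residuals = res, converged = converged,
       ok = converged && is.finite(p[3]) && p[3] > amp_floor)
}

#' Goodness-of-fit outlier filter for point-source fits
#'
#' Chi-square test on the standardized fit residuals within the fit window:
#' detections whose residuals are inconsistent with a point source plus
#' i.i.d. Gaussian noise (p below `p_threshold`) are removed. Survivors carry
#' the p-value in `gof_pvalue`.
#'
#' @param detections data frame of detections as produced by
#'   [detect_point_sources()], with a `residual_ss` and `n_pixels` column, or
#'   a list of fit objects from [fit_isotropic_gaussian()].
#' @param noise_sd noise standard deviation of the frame; required.
#' @param p_threshold significance level of the residual test (default 0.05);
#'   0 retains everything.
#' @return The retained detections with `gof_pvalue` filled in.
#' @export
goodness_of_fit_filter <- function(detections, noise_sd, p_threshold = 0.05) {
  if (missing(noise_sd) || is.null(noise_sd) || !is.finite(noise_sd))
    stop("noise estimate (noise_sd) is required for the goodness-of-fit test")
  sd_eff <- max(noise_sd, 1e-12)   # noiseless frames: perfect fits score p=1
  stopifnot(is.data.frame(detections),
            all(c("residual_ss", "n_pixels") %in% names(detections)))
  df <- detections$n_pixels - 4    # 4 fitted parameters: x, y, A, b
  stat <- detections$residual_ss / sd_eff^2
  p <- stats::pchisq(stat, df = pmax(df, 1), lower.tail = FALSE)
  detections$gof_pvalue <- p
  detections[p >= p_threshold, , drop = FALSE]
}

#' Detect diffraction-limited point sources in a frame
#'
#' The nascent-adhesion / bead detector: LoG filtering at the PSF scale,
#' 8-connected local maxima thresholded against a robust (median/MAD) null
#' model of the filtered response with Bonferroni control at level `alpha`
#' per frame, sub-pixel localization by fixed-width isotropic Gaussian
#' fitting, and a chi-square goodness-of-fit filter.
#'
#' @param frame 2-D numeric matrix, at least 4 sigma wide in each dimension.
#' @param sigma PSF standard deviation in pixels (default 2.1).
#' @param alpha significance level controlling expected false maxima per
#'   frame (default 0.05).
#' @param gof_p p-value threshold of the goodness-of-fit residual filter.
#' @param noise_sd noise sd; estimated from the frame when `NULL`.
#' @return Data frame with columns `frame` (filled by [detect_stack()]; 0
#'   here), `x`, `y`, `amplitude`, `background`, `sigma`, `gof_pvalue`,
#'   `residual_ss`, `n_pixels`, sorted by decreasing amplitude. Zero rows
#'   when nothing passes the threshold.
#' @export
detect_point_sources <- function(frame, sigma = 2.1, alpha = 0.05,
                                 gof_p = 0.05, noise_sd = NULL) {
  stopifnot(is.matrix(frame))
  if (any(dim(frame) < 4 * sigma))
    stop("frame must span at least 4 sigma in each dimension")
  L <- log_filter(frame, sigma)
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(frame)

  mx <- local_maxima(L)
  empty <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      amplitude = numeric(0), background = numeric(0),
                      sigma = numeric(0), gof_pvalue = numeric(0),
                      residual_ss = numeric(0), n_pixels = integer(0))
  if (nrow(mx) == 0) return(empty)

  med <- stats::median(L)
  s <- stats::mad(L)
  if (s <= 0) s <- 1e-12
  z <- (L[mx] - med) / s
  # Bonferroni over all pixels: expected false detections per frame under
  # the null is at most alpha (local maxima of a smooth field are a subset
  # of threshold exceedances)
  pz <- stats::pnorm(z, lower.tail = FALSE)
  keep <- pz < alpha / length(L)
  mx <- mx[keep, , drop = FALSE]
  if (nrow(mx) == 0) return(empty)

  w <- ceiling(3 * sigma)
  nr <- nrow(frame); nc <- ncol(frame)
  out <- vector("list", nrow(mx))
  for (i in seq_len(nrow(mx))) {
    r0 <- mx[i, 1]; c0 <- mx[i, 2]
    if (r0 - w < 1 || r0 + w > nr || c0 - w < 1 || c0 + w > nc) next
    patch <- frame[(r0 - w):(r0 + w), (c0 - w):(c0 + w)]
    fit <- fit_isotropic_gaussian(patch, center_guess = c(c0 - 1, r0 - 1),
                                  sigma_fixed = sigma,
                                  patch_origin = c(c0 - 1 - w, r0 - 1 - w))
    if (!fit$ok) next
    if (fit$x < 0 || fit$x > nc - 1 || fit$y < 0 || fit$y > nr - 1) next
    out[[i]] <- data.frame(
      frame = 0L, x = fit$x, y = fit$y, amplitude = fit$amplitude,
      background = fit$background, sigma = sigma, gof_pvalue = NA_real_,
      residual_ss = sum(fit$residuals^2),
      n_pixels = length(patch))
  }
  det <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(det) || nrow(det) == 0) return(empty)
  det <- goodness_of_fit_filter(det, noise_sd = noise_sd,
                                p_threshold = gof_p)
  det[order(-det$amplitude), , drop = FALSE]
}

#' Detect point sources in every frame of a stack
#'
#' @param stack an `image_stack`.
#' @param ... passed to [detect_point_sources()].
#' @return Combined detection data frame with 0-based `frame` indices,
#'   sorted by frame then decreasing amplitude.
#' @export
detect_stack <- function(stack, ...) {
  dets <- lapply(seq_along(stack$frames), function(i) {
    d <- detect_point_sources(stack$frames[[i]], ...)
    if (nrow(d)) d$frame <- i - 1L
    d
  })
  out <- do.call(rbind, dets)
  rownames(out) <- NULL
  out[order(out$frame, -out$amplitude), , drop = FALSE]
}
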