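#' Gaussian smoothing and background subtraction for adhesion segmentation
#'
#' Smooths the paxillin frame with a small Gaussian and subtracts a
#' large-radius median-filter background estimate, clamping at zero. The
#' median background tracks slow illumination gradients while passing over
#' adhesion-scale features, so feature contrast is preserved and a second
#' application changes little (the operation is close to idempotent).
#'
#' @param frame 2-D numeric matrix.
#' @param smooth_sigma sd of the smoothing Gaussian in pixels.
#' @param background_radius radius of the median background filter in
#'   pixels; must be larger than the features of interest.
#' @return Non-negative filtered matrix of the same dimension.
#' @export
preprocess_for_segmentation <- function(frame, smooth_sigma = 1,
                                        background_radius = 20) {
  stopifnot(is.matrix(frame))
  rng <- range(frame)
  if (diff(rng) == 0) return(frame * 0)
  norm <- (frame - rng[1]) / diff(rng)
  r <- min(background_radius, floor((min(dim(frame)) - 1) / 2))
  bg <- as.matrix(EBImage::medianFilter(norm, size = r)) * diff(rng) +
    rng[1]
  pmax(gaussian_blur(frame, smooth_sigma) - bg, 0)
}

# Gaussian blur with the kernel capped to the image size (EBImage's default
# brush can exceed small frames at background-scale sigmas)
gaussian_blur <- function(frame, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  rmax <- min(dim(frame))
  if (rmax %% 2 == 0) rmax <- rmax - 1
  as.matrix(EBImage::gblur(frame, sigma = sigma, radius = min(r, rmax),
                           boundary = "replicate"))
}

#' Otsu threshold of a frame
#'
#' Thin wrapper around the between-class-variance maximizer, computed on a
#' 256-bin histogram of the frame's range.
#'
#' @param frame 2-D numeric matrix with at least two distinct values.
#' @return Scalar threshold on the intensity scale of `frame`.
#' @export
otsu_threshold <- function(frame) {
  rng <- range(frame)
  if (diff(rng) <= 0) stop("degenerate histogram: constant image")
  EBImage::otsu(EBImage::Image(frame), range = rng, levels = 256)
}

#' Rosin (triangle / unimodal) threshold
#'
#' For a unimodal histogram with a long tail, draws the line from the
#' histogram peak to the far end of the tail and returns the bin with
#' maximum perpendicular distance below that line.
#'
#' @param frame 2-D numeric matrix with at least two distinct values.
#' @param n_bins histogram resolution.
#' @return Scalar threshold on the intensity scale of `frame`.
#' @export
rosin_threshold <- function(frame, n_bins = 256) {
  rng <- range(frame)
  if (diff(rng) <= 0) stop("degenerate histogram: constant image")
  h <- graphics::hist(as.vector(frame),
                      breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
                      plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  ipk <- which.max(counts)
  nz <- which(counts > 0)
  # tail = the longer side of the peak
  iend <- if ((max(nz) - ipk) >= (ipk - min(nz))) max(nz) else min(nz)
  if (iend == ipk) return(mids[ipk])
  idx <- if (iend > ipk) ipk:iend else iend:ipk
  # perpendicular distance of (x_i, c_i) from the peak-to-end chord
  x1 <- mids[ipk]; y1 <- counts[ipk]; x2 <- mids[iend]; y2 <- counts[iend]
  # scale axes so the chord geometry is resolution-independent
  sx <- abs(x2 - x1); sy <- abs(y1 - y2)
  if (sx == 0 || sy == 0) return(mids[ipk])
  xs <- (mids[idx] - x1) / sx; ys <- (counts[idx] - y1) / sy
  xe <- (x2 - x1) / sx; ye <- (y2 - y1) / sy
  d <- abs(xs * ye - ys * xe) / sqrt(xe^2 + ye^2)
  mids[idx[which.max(d)]]
}

#' Combined Otsu/Rosin segmentation threshold
#'
#' Computes both the Otsu (bimodal) and the Rosin (unimodal) thresholds and
#' combines them. The default `mean` mode blends the two estimators, which
#' is robust across the range of adhesion densities seen in paxillin images
#' (sparse images have near-unimodal histograms where Otsu alone
#' over-segments). Both component values are returned for auditability.
#'
#' @param frame filtered frame from [preprocess_for_segmentation()].
#' @param mode one of `"mean"`, `"otsu"`, `"rosin"`, `"min"`, `"max"`.
#' @return Scalar threshold with attributes `otsu` and `rosin`.
#' @export
combined_threshold <- function(frame,
                               mode = c("mean", "otsu", "rosin", "min",
                                        "max")) {
  mode <- match.arg(mode)
  to <- otsu_threshold(frame)
  tr <- rosin_threshold(frame)
  th <- switch(mode, mean = (to + tr) / 2, otsu = to, rosin = tr,
               min = min(to, tr), max = max(to, tr))
  structure(th, otsu = to, rosin = tr, mode = mode)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged through their adjacency graph.
label_components_8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(pairs), ncol = 2), directed = FALSE)
  missing <- setdiff(as.character(1:n), igraph::V(g)$name)
  if (length(missing))
    g <- igraph::add_vertices(g, length(missing), name = missing)
  comp <- igraph::components(g)$membership
  map <- integer(n)
  map[as.integer(names(comp))] <- comp
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Classify a segmented adhesion region by area
#'
#' Area classes follow the standard thresholds: below 0.24 um^2 a region is
#' too small to be a focal complex (`below_FC`; regions of 0.2 um^2 or less
#' are discarded before classification), 0.24-0.6 um^2 is a focal complex
#' (`FC`), and 0.6 um^2 or more a focal adhesion (`FA`). Intervals are
#' closed on the lower bound.
#'
#' @param area region area in um^2 (> 0); vectorized.
#' @return Character vector in `{"below_FC", "FC", "FA"}`.
#' @export
classify_region <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("area must be positive and finite")
  ifelse(area >= 0.6, "FA", ifelse(area >= 0.24, "FC", "below_FC"))
}

#' Segment adhesion regions above a threshold
#'
#' 8-connected components of the thresholded (filtered) frame. Components
#' of 0.2 um^2 or less are discarded outright; the rest are measured
#' (area, ellipse axes by second moments, centroid) and classified with
#' [classify_region()].
#'
#' @param frame filtered frame from [preprocess_for_segmentation()].
#' @param threshold intensity threshold (e.g. from [combined_threshold()]).
#' @param pixel_size um per pixel.
#' @param min_area_um2 discard floor in um^2 (default 0.2).
#' @return List with `regions` — data frame of `label`, `area` (um^2),
#'   `major_axis`, `minor_axis` (um), `eccentricity_ratio` (minor/major),
#'   `adhesion_class`, `centroid_x`, `centroid_y` (0-based pixels) — and
#'   `labels`, the relabelled integer matrix (0 = background) aligned to
#'   `regions$label`.
#' @export
segment_regions <- function(frame, threshold, pixel_size,
                            min_area_um2 = 0.2) {
  stopifnot(is.matrix(frame), pixel_size > 0)
  mask <- frame > threshold
  lab <- label_components_8(mask)
  px_area <- pixel_size^2
  empty <- list(
    regions = data.frame(label = integer(0), area = numeric(0),
                         major_axis = numeric(0), minor_axis = numeric(0),
                         eccentricity_ratio = numeric(0),
                         adhesion_class = character(0),
                         centroid_x = numeric(0), centroid_y = numeric(0)),
    labels = lab * 0L)
  if (max(lab) == 0) return(empty)

  tab <- tabulate(lab[lab > 0])
  keep <- which(tab * px_area > min_area_um2)
  if (length(keep) == 0) return(empty)

  relab <- integer(length(tab))
  relab[keep] <- seq_along(keep)
  out_lab <- lab
  out_lab[lab > 0] <- relab[lab[lab > 0]]

  idx <- which(out_lab > 0, arr.ind = TRUE)
  lb <- out_lab[out_lab > 0]
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  rows <- lapply(seq_along(keep), function(i) {
    sel <- lb == i
    x <- xs[sel]; y <- ys[sel]
    n <- length(x)
    cx <- mean(x); cy <- mean(y)
    # second moments with the 1/12 pixel-variance correction
    sxx <- mean((x - cx)^2) + 1 / 12
    syy <- mean((y - cy)^2) + 1 / 12
    sxy <- mean((x - cx) * (y - cy))
    ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2),
                symmetric = TRUE)$values
    major <- 4 * sqrt(max(ev[1], 0)) * pixel_size  # full axis of the
    minor <- 4 * sqrt(max(ev[2], 0)) * pixel_size  # equivalent ellipse
    area <- n * px_area
    data.frame(label = i, area = area, major_axis = major,
               minor_axis = minor,
               eccentricity_ratio = if (major > 0) minor / major else 1,
               adhesion_class = classify_region(area),
               centroid_x = cx, centroid_y = cy)
  })
  regions <- do.call(rbind, rows)
  rownames(regions) <- NULL
  list(regions = regions, labels = out_lab)
}

#' Segment every frame of a paxillin stack
#'
#' Runs [preprocess_for_segmentation()], [combined_threshold()] and
#' [segment_regions()] per frame.
#'
#' @param stack an `image_stack`.
#' @param mode threshold combination mode, see [combined_threshold()].
#' @param ... passed to [preprocess_for_segmentation()].
#' @return List (one element per frame) of [segment_regions()] results, each
#'   with a `threshold` element added.
#' @export
segment_stack <- function(stack, mode = "mean", ...) {
  lapply(stack$frames, function(f) {
    filt <- preprocess_for_segmentation(f, ...)
    th <- tryCatch(combined_threshold(filt, mode = mode),
                   error = function(e) max(filt) + 1)  # blank frame
    seg <- segment_regions(filt, th, stack$pixel_size)
    seg$threshold <- as.numeric(th)
    seg
  })
}
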