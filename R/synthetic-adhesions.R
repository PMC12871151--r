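#' Configuration of a synthetic adhesion movie
#'
#' Defaults mirror the imaging conditions the package targets: 20 s frame
#' interval, PSF sd 2.1 px, pixel size 0.086 um/px (so 2.1 px is about
#' 180 nm).
#'
#' @param frame_count number of frames (>= 2).
#' @param width,height frame size in pixels.
#' @param frame_interval seconds between frames (default 20).
#' @param pixel_size um per pixel (default 0.086).
#' @param psf_sigma PSF standard deviation in pixels (default 2.1).
#' @param background_level uniform background in photons.
#' @param background_gradient linear background slope along x,
#'   photons/pixel.
#' @param poisson_noise apply Poisson shot noise.
#' @param read_noise_sd additive Gaussian read noise sd (0 disables).
#' @param rng_seed integer seed; identical seeds give bit-identical scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(frame_count, width = 128, height = 128,
                         frame_interval = 20, pixel_size = 0.086,
                         psf_sigma = 2.1, background_level = 100,
                         background_gradient = 0, poisson_noise = FALSE,
                         read_noise_sd = 0, rng_seed = 1L) {
  stopifnot(frame_count >= 2, pixel_size > 0, psf_sigma > 0,
            width >= 8, height >= 8, read_noise_sd >= 0)
  structure(list(frame_count = as.integer(frame_count), width = width,
                 height = height, frame_interval = frame_interval,
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 poisson_noise = poisson_noise,
                 read_noise_sd = read_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' Ground truth of one synthetic adhesion
#'
#' The peak intensity follows an exponential rise capped at a plateau and
#' then an exponential decay:
#' \deqn{I(t) = \min(I_p, I_i e^{k_a (t - t_n)})}{I(t) = min(Ip, Ii exp(ka (t - tn)))}
#' for nucleation frame \eqn{t_n \le t <} disassembly start, then
#' \eqn{I(t_d) e^{-k_d (t - t_d)}}. This piecewise-exponential shape makes
#' \eqn{\ln(I/I_0)} exactly linear in each phase, so the planted rates are
#' recoverable by the log-linear estimators and every downstream window
#' selection is testable against a known changepoint.
#'
#' @param id integer identifier.
#' @param x,y position in pixels (0-based, pixel-center origin; constant
#'   over time).
#' @param nucleation_frame 0-based frame at which the adhesion appears.
#' @param assembly_rate exponential growth rate, per minute (> 0).
#' @param plateau_intensity peak photon amplitude at plateau.
#' @param disassembly_start_frame 0-based frame at which decay begins
#'   (> nucleation_frame).
#' @param disassembly_rate exponential decay rate, per minute (> 0).
#' @param initial_intensity amplitude at nucleation (default plateau/20).
#' @param footprint_area footprint in um^2: scalar, or vector over frames
#'   (non-decreasing until disassembly). 0 = pure point source.
#' @param elongation minor/major axis ratio of the footprint (1 =
#'   circular).
#' @param gfp_coupling intensity scale of the same adhesion in the GFP
#'   channel.
#' @return An `adhesion_truth` list.
#' @export
adhesion_truth <- function(id, x, y, nucleation_frame, assembly_rate,
                           plateau_intensity, disassembly_start_frame,
                           disassembly_rate,
                           initial_intensity = plateau_intensity / 20,
                           footprint_area = 0, elongation = 1,
                           gfp_coupling = 1) {
  stopifnot(assembly_rate > 0, disassembly_rate > 0,
            disassembly_start_frame > nucleation_frame,
            plateau_intensity > 0, initial_intensity > 0,
            elongation > 0, elongation <= 1, all(footprint_area >= 0))
  if (length(footprint_area) > 1 && any(diff(footprint_area) < 0))
    stop("footprint_area must be non-decreasing over frames")
  structure(list(id = id, x = x, y = y,
                 nucleation_frame = nucleation_frame,
                 assembly_rate = assembly_rate,
                 plateau_intensity = plateau_intensity,
                 disassembly_start_frame = disassembly_start_frame,
                 disassembly_rate = disassembly_rate,
                 initial_intensity = initial_intensity,
                 footprint_area = footprint_area, elongation = elongation,
                 gfp_coupling = gfp_coupling),
            class = "adhesion_truth")
}

#' Analytic peak-intensity time course of an adhesion
#'
#' @param truth an [adhesion_truth()].
#' @param frame 0-based frame index (vectorized).
#' @param frame_interval seconds per frame.
#' @return Peak amplitude in photons (0 before nucleation).
#' @export
adhesion_intensity <- function(truth, frame, frame_interval = 20) {
  t_min <- (frame - truth$nucleation_frame) * frame_interval / 60
  td_min <- (truth$disassembly_start_frame - truth$nucleation_frame) *
    frame_interval / 60
  rise <- pmin(truth$plateau_intensity,
               truth$initial_intensity * exp(truth$assembly_rate * t_min))
  i_d <- min(truth$plateau_intensity,
             truth$initial_intensity * exp(truth$assembly_rate * td_min))
  decay <- i_d * exp(-truth$disassembly_rate * (t_min - td_min))
  ifelse(t_min < 0, 0, ifelse(t_min < td_min, rise, decay))
}

# render one elliptical-Gaussian spot (PSF-convolved footprint) with peak
# amplitude A at (x, y); footprint ellipse area pi * (2 s_maj)(2 s_min)
render_spot <- function(frame, x, y, amplitude, psf_sigma, footprint_um2,
                        elongation, pixel_size) {
  if (amplitude <= 0) return(frame)
  if (footprint_um2 > 0) {
    # semi-axes (at 2 sigma) of the footprint ellipse, in pixels
    a <- sqrt(footprint_um2 / (pi * elongation)) / pixel_size
    b <- a * elongation
    s_maj <- sqrt(psf_sigma^2 + (a / 2)^2)
    s_min <- sqrt(psf_sigma^2 + (b / 2)^2)
  } else {
    s_maj <- s_min <- psf_sigma
  }
  r <- ceiling(4 * max(s_maj, s_min))
  nr <- nrow(frame); nc <- ncol(frame)
  rows <- max(1, round(y) + 1 - r):min(nr, round(y) + 1 + r)
  cols <- max(1, round(x) + 1 - r):min(nc, round(x) + 1 + r)
  dx <- outer(rep(1, length(rows)), cols - 1 - x)
  dy <- outer(rows - 1 - y, rep(1, length(cols)))
  frame[rows, cols] <- frame[rows, cols] +
    amplitude * exp(-(dx^2 / (2 * s_maj^2) + dy^2 / (2 * s_min^2)))
  frame
}

#' Generate a two-channel synthetic adhesion movie
#'
#' Renders each adhesion as a PSF-convolved elliptical footprint whose peak
#' amplitude follows the analytic intensity model of [adhesion_intensity()];
#' the GFP channel renders the same adhesions scaled by their per-adhesion
#' coupling factor. Background (uniform plus optional linear gradient) is
#' added, then noise last. Generation is a pure function of
#' (config, truths): identical seeds give bit-identical stacks.
#'
#' @param config a [scene_config()].
#' @param truths list of [adhesion_truth()] objects.
#' @return List: `paxillin` and `gfp` [image_stack()]s and `truths`
#'   (returned unmodified).
#' @export
generate_adhesion_scene <- function(config, truths = list()) {
  stopifnot(inherits(config, "scene_config"))
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    if (tr$x < 0 || tr$x > config$width - 1 ||
        tr$y < 0 || tr$y > config$height - 1)
      stop("adhesion truth ", i, " placed outside the frame")
  }
  bg <- matrix(config$background_level, config$height, config$width)
  if (config$background_gradient != 0)
    bg <- bg + config$background_gradient *
      matrix(0:(config$width - 1), config$height, config$width,
             byrow = TRUE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$rng_seed)

  render_channel <- function(scale_fun) {
    lapply(seq_len(config$frame_count) - 1L, function(f) {
      fr <- bg
      for (tr in truths) {
        A <- adhesion_intensity(tr, f, config$frame_interval) *
          scale_fun(tr)
        fp <- if (length(tr$footprint_area) > 1)
          tr$footprint_area[min(f + 1, length(tr$footprint_area))] else
            tr$footprint_area
        fr <- render_spot(fr, tr$x, tr$y, A, config$psf_sigma, fp,
                          tr$elongation, config$pixel_size)
      }
      fr
    })
  }
  pax <- render_channel(function(tr) 1)
  gfp <- render_channel(function(tr) tr$gfp_coupling)

  add_noise <- function(frames) lapply(frames, function(fr) {
    if (config$poisson_noise)
      fr <- matrix(stats::rpois(length(fr), lambda = fr), nrow(fr),
                   ncol(fr))
    if (config$read_noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), sd = config$read_noise_sd),
                        nrow(fr), ncol(fr))
    fr
  })
  pax <- add_noise(pax)
  gfp <- add_noise(gfp)

  list(paxillin = image_stack(pax, config$pixel_size,
                              config$frame_interval, "paxillin"),
       gfp = image_stack(gfp, config$pixel_size, config$frame_interval,
                         "gfp"),
       truths = truths)
}
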