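#' Gaussian traction patch ground truth on a mesh
#'
#' Convenience builder for synthetic scenes: a sum of tangential Gaussian
#' traction patches, clipped to zero outside the cell mask radius.
#'
#' @param mesh a [traction_mesh()].
#' @param patches data frame with `x`, `y` (center, um), `sd` (um),
#'   `tx`, `ty` (peak traction, Pa).
#' @param substrate optional [elastic_substrate()] stored on the field.
#' @return A [traction_field()].
#' @export
gaussian_traction_field <- function(mesh, patches, substrate = NULL) {
  tx <- ty <- numeric(nrow(mesh$nodes))
  for (i in seq_len(nrow(patches))) {
    g <- exp(-((mesh$nodes$x - patches$x[i])^2 +
               (mesh$nodes$y - patches$y[i])^2) / (2 * patches$sd[i]^2))
    tx <- tx + patches$tx[i] * g
    ty <- ty + patches$ty[i] * g
  }
  traction_field(mesh, tx, ty, substrate = substrate)
}

#' Generate a synthetic TFM bead-image pair with known ground truth
#'
#' Beads are placed uniformly at random; their stressed positions are the
#' reference positions plus the forward displacement of `traction_truth`
#' evaluated at the reference positions (beads outside the cell mask move
#' only by the elastic far field — they are never displaced independently).
#' Both images are rendered as Gaussian PSF point sources; noise optional.
#'
#' @param traction_truth a [traction_field()] vanishing outside the cell
#'   mask.
#' @param substrate an [elastic_substrate()].
#' @param bead_count number of beads.
#' @param seed integer RNG seed.
#' @param image_size image edge in pixels.
#' @param pixel_size um per pixel (image extent should cover the mesh).
#' @param psf_sigma bead PSF sd in pixels.
#' @param bead_amplitude photon amplitude per bead.
#' @param background photon background.
#' @param read_noise_sd Gaussian noise sd (0 = noiseless).
#' @param template_size PTV template size used to validate displacements.
#' @return List: `stressed`, `relaxed` (matrices), `bead_reference`,
#'   `bead_stressed` (data frames, um and px), `cell_mask` (binary matrix),
#'   `traction_truth`, `substrate`, `max_displacement_px`, and `warnings`.
#' @export
generate_tfm_scene <- function(traction_truth, substrate, bead_count, seed,
                               image_size = 256, pixel_size = 0.5,
                               psf_sigma = 1.6, bead_amplitude = 2000,
                               background = 100, read_noise_sd = 0,
                               template_size = 17) {
  stopifnot(inherits(traction_truth, "traction_field"),
            inherits(substrate, "elastic_substrate"), bead_count >= 1)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  ext_um <- image_size * pixel_size
  margin <- 4 * psf_sigma * pixel_size
  ref <- data.frame(x = stats::runif(bead_count, margin, ext_um - margin),
                    y = stats::runif(bead_count, margin, ext_um - margin))
  u <- boussinesq_forward(traction_truth, substrate, ref)
  stressed_pos <- data.frame(x = ref$x + u$ux, y = ref$y + u$uy)
  max_disp_px <- max(sqrt(u$ux^2 + u$uy^2)) / pixel_size
  warnings <- character(0)
  if (max_disp_px > template_size / 2) {
    warnings <- c(warnings, sprintf(
      "maximum displacement %.2f px exceeds half the template size (%d px)",
      max_disp_px, template_size))
    warning(warnings[length(warnings)])
  }

  render <- function(pos) {
    fr <- matrix(background, image_size, image_size)
    for (i in seq_len(nrow(pos)))
      fr <- render_spot(fr, pos$x[i] / pixel_size, pos$y[i] / pixel_size,
                        bead_amplitude, psf_sigma, 0, 1, pixel_size)
    if (read_noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), sd = read_noise_sd),
                        nrow(fr), ncol(fr))
    fr
  }
  relaxed <- render(ref)
  stressed <- render(stressed_pos)

  # cell mask: support of the true traction, dilated by one element
  mag <- sqrt(traction_truth$tx^2 + traction_truth$ty^2)
  mask <- matrix(0L, image_size, image_size)
  thr <- max(mag) * 0.01
  nodes <- traction_truth$mesh$nodes
  half <- max(traction_truth$mesh$dx, traction_truth$mesh$dy)
  for (i in which(mag > thr)) {
    r0 <- max(1, floor((nodes$y[i] - half) / pixel_size) + 1)
    r1 <- min(image_size, ceiling((nodes$y[i] + half) / pixel_size) + 1)
    c0 <- max(1, floor((nodes$x[i] - half) / pixel_size) + 1)
    c1 <- min(image_size, ceiling((nodes$x[i] + half) / pixel_size) + 1)
    mask[r0:r1, c0:c1] <- 1L
  }

  list(stressed = stressed, relaxed = relaxed,
       bead_reference = ref, bead_stressed = stressed_pos,
       bead_displacement = u,
       cell_mask = mask, traction_truth = traction_truth,
       substrate = substrate, max_displacement_px = max_disp_px,
       warnings = warnings, pixel_size = pixel_size)
}
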