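# adhesionTFM

Quantification of integrin-based adhesion dynamics from two-channel TIRF
time-lapse movies, and of cell-generated traction forces from substrate
bead displacements — for cell biologists and image analysts studying
adhesion assembly, maturation and mechanotransduction.

The package implements the full analysis chain as composable R functions:

* **Detection** — nascent adhesions as diffraction-limited point sources:
  scale-normalized Laplacian-of-Gaussian filtering, local maxima with a
  noise-calibrated threshold, fixed-width isotropic Gaussian fitting
  (σ = 2.1 px ≈ 180 nm), chi-square goodness-of-fit outlier removal.
* **Segmentation** — focal complexes (FC, 0.24–0.6 µm²) and focal
  adhesions (FA, ≥ 0.6 µm²) by combined Otsu/Rosin thresholding after
  Gaussian smoothing and median-background subtraction; ellipse shape
  descriptors.
* **Tracking** — globally optimal frame-to-frame linear assignment with
  gap closing; per-frame status (`BA`/`NA`/`FC`/`FA`) by overlap with the
  segmentation; lifetimes with censoring, nucleation and maturation
  fractions.
* **Kinetics** — assembly and disassembly rate constants as the slopes of
  ln(I/I₀) and ln(I₀/I) over adaptively selected time windows (largest
  adjusted R², ties to the longer window), with the adjusted-R² ≥ 0.3
  noise filter.
* **TFM** — bead displacements by normalized cross-correlation particle
  tracking (17 px template, sub-pixel parabolic peak), normalized-median
  outlier filtering, a Boussinesq–Cerruti boundary-element forward model
  on an elastic half-space (E = 5 kPa, ν = 0.5 by default), L2-regularized
  inversion min‖Mt − u‖² + λ‖t‖², and L-curve corner selection of λ from
  the analytic curvature of the Tikhonov L-curve. Readouts: total force
  over the cell mask, per-class adhesion tractions.
* **Statistics** — Mann-Whitney rank-sum comparisons (exact by exhaustive
  enumeration for n ≤ 8, ties included), activation index
  AI = (F − F₀)/(F_max − F₀), report tables with significance stars.
* **Synthetic scenes** — movie and TFM generators with exhaustively known
  ground truth (exponential-rise/plateau/exponential-decay intensity
  model, PSF-convolved footprints, Poisson + Gaussian noise, seeded and
  bit-reproducible), so the whole chain is testable offline.

## Worked example

Simulate a two-adhesion movie with known rates, then recover them:

```r
library(adhesionTFM)

cfg <- scene_config(frame_count = 30, width = 96, height = 96,
                    read_noise_sd = 3, rng_seed = 42)
truths <- list(
  adhesion_truth(1, x = 30, y = 40, nucleation_frame = 2,
                 assembly_rate = 1.0, plateau_intensity = 500,
                 disassembly_start_frame = 18, disassembly_rate = 0.6),
  adhesion_truth(2, x = 65, y = 55, nucleation_frame = 4,
                 assembly_rate = 1.8, plateau_intensity = 400,
                 disassembly_start_frame = 20, disassembly_rate = 0.9))
scene <- generate_adhesion_scene(cfg, truths)
scene$paxillin
#> image_stack 'paxillin': 30 frame(s) of 96 x 96 px, 0.086 um/px, dt = 20 s

det    <- detect_stack(scene$paxillin)
tracks <- assign_status(link_detections(det), segment_stack(scene$paxillin))
kin    <- track_kinetics(tracks, cfg$frame_interval)
subset(kin, passed_filter,
       select = c(track_id, phase, rate_constant, adjusted_r2))
#>   track_id       phase rate_constant adjusted_r2
#> 1        1    assembly     1.0024392   0.9999458
#> 2        1 disassembly     0.5991369   0.9998866
#> 3        2    assembly     1.6153814   0.9709968
#> 4        2 disassembly     0.8951933   0.9995781
```

The planted rates (1.0/0.6 and 1.8/0.9 min⁻¹) are recovered from the
fitted amplitude traces; adhesion 2's fast assembly is slightly
under-estimated because only a handful of samples fall in its rise phase —
the adjusted-R² column shows the quality of each selected window. The
`rate_constant` unit is min⁻¹ (natural log); lifetimes are reported in
seconds as (frames spanned) × 20 s.

`run_pipeline(run_config(seed = 1L), "out/")` runs every stage on a
seeded synthetic scene and writes TIFFs, per-stage CSV tables (with unit
and convention headers) and a manifest with MD5 checksums.

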