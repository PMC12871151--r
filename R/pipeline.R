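#' Default run configuration
#'
#' All stage parameters of the pipeline in one serializable list. Unknown
#' keys passed in `...` are rejected, so configs round-trip losslessly
#' through YAML/JSON.
#'
#' @param ... named overrides of the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    detection = list(sigma = 2.1, alpha = 0.05, gof_p = 0.05),
    segmentation = list(mode = "mean", smooth_sigma = 1,
                        background_radius = 20),
    tracking = list(search_radius = 3, max_gap = 2),
    kinetics = list(min_points = 7, r2_threshold = 0.3, min_length = 8),
    tfm = list(template_size = 17, max_displacement = 50,
               corr_floor = 0.5, outlier_threshold = 2,
               poisson_ratio = 0.5, youngs_modulus = 5000,
               mesh_n = 16,
               lambda_grid = 10^seq(-10, 0, length.out = 21)),
    scene = list(frame_count = 40, width = 128, height = 128,
                 frame_interval = 20, pixel_size = 0.086,
                 n_adhesions = 12, read_noise_sd = 4))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config key: ", nm)
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config key: ", nm, "$", bad[1])
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration
#'
#' @param path YAML or JSON file (by extension).
#' @param config a `run_config`.
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
    simplifyVector = TRUE) else yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}

# CSV with a '#'-prefixed header block carrying units and conventions
write_csv_commented <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-scene analysis pipeline
#'
#' Generates (or loads) a two-channel adhesion movie, then runs detection,
#' segmentation, tracking, status assignment, lifetime/nucleation
#' statistics, kinetics, optional TFM, and the readout report, writing each
#' stage's table to `out_dir` together with a manifest (config, seed,
#' package version, MD5 of every output). Reruns with the same config are
#' bit-identical for all deterministic stages.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, created if needed.
#' @param paxillin_tiff,gfp_tiff optional paths to input movies; when
#'   `NULL` a synthetic scene is generated from `config$scene`.
#' @param run_tfm also run a synthetic TFM round trip.
#' @return Invisible list of in-memory stage results; the manifest records
#'   the on-disk bundle (and the failure point, should a stage fail).
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         paxillin_tiff = NULL, gfp_tiff = NULL,
                         run_tfm = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("adhesionTFM")),
                   seed = config$seed, config = unclass(config),
                   outputs = list(), failed_at = NULL)
  results <- list()
  conv <- paste0(
    "coordinates: 0-based pixel-center, x = column; log base: natural; ",
    "lifetime = frames spanned x frame interval; rates per minute")
  finish <- function() {
    files <- names(manifest$outputs)
    manifest$outputs <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(manifest$outputs) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  record <- function(name) manifest$outputs[[name]] <<- TRUE
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_at <<- stage
      finish()
      stop("pipeline failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  # --- input ---
  scene <- step("input", {
    if (is.null(paxillin_tiff)) {
      sc <- config$scene
      cfg <- scene_config(frame_count = sc$frame_count, width = sc$width,
                          height = sc$height,
                          frame_interval = sc$frame_interval,
                          pixel_size = sc$pixel_size,
                          read_noise_sd = sc$read_noise_sd,
                          rng_seed = config$seed)
      truths <- default_truths(cfg, sc$n_adhesions, config$seed)
      s <- generate_adhesion_scene(cfg, truths)
      write_stack_tiff(s$paxillin, file.path(out_dir, "paxillin.tif"))
      write_stack_tiff(s$gfp, file.path(out_dir, "gfp.tif"))
      record("paxillin.tif"); record("gfp.tif")
      truth_df <- do.call(rbind, lapply(truths, function(tr)
        data.frame(id = tr$id, x = tr$x, y = tr$y,
                   nucleation_frame = tr$nucleation_frame,
                   assembly_rate = tr$assembly_rate,
                   disassembly_rate = tr$disassembly_rate)))
      jsonlite::write_json(truth_df, file.path(out_dir, "ground_truth.json"),
                           digits = NA)
      record("ground_truth.json")
      s
    } else {
      sc <- config$scene
      list(paxillin = read_stack_tiff(paxillin_tiff, sc$pixel_size,
                                      sc$frame_interval, "paxillin"),
           gfp = if (!is.null(gfp_tiff))
             read_stack_tiff(gfp_tiff, sc$pixel_size, sc$frame_interval,
                             "gfp") else NULL,
           truths = NULL)
    }
  })
  results$scene <- scene

  # --- detection ---
  detections <- step("detection", {
    d <- detect_stack(scene$paxillin, sigma = config$detection$sigma,
                      alpha = config$detection$alpha,
                      gof_p = config$detection$gof_p)
    write_csv_commented(
      d[, c("frame", "x", "y", "amplitude", "background", "gof_pvalue")],
      file.path(out_dir, "detections.csv"), conv)
    record("detections.csv")
    d
  })
  results$detections <- detections

  # --- segmentation ---
  segs <- step("segmentation", {
    s <- segment_stack(scene$paxillin, mode = config$segmentation$mode,
                       smooth_sigma = config$segmentation$smooth_sigma,
                       background_radius = config$segmentation$background_radius)
    regions <- do.call(rbind, lapply(seq_along(s), function(i) {
      r <- s[[i]]$regions
      if (nrow(r)) cbind(frame = i - 1L, r) else NULL
    }))
    if (is.null(regions)) regions <- data.frame()
    write_csv_commented(regions, file.path(out_dir, "regions.csv"), conv)
    record("regions.csv")
    s
  })
  results$segmentations <- segs

  # --- tracking + status ---
  tracks <- step("tracking", {
    tr <- link_detections(detections,
                          search_radius = config$tracking$search_radius,
                          max_gap = config$tracking$max_gap)
    tr <- assign_status(tr, segs)
    write_csv_commented(
      tr[, c("track_id", "frame", "x", "y", "amplitude", "status")],
      file.path(out_dir, "tracks.csv"), conv)
    record("tracks.csv")
    tr
  })
  results$tracks <- tracks

  # --- lifetimes / nucleation ---
  results$lifetimes <- step("lifetimes", {
    lt <- compute_lifetimes(tracks, scene$paxillin$frame_interval,
                            length(scene$paxillin))
    nm <- nucleation_and_maturation(tracks)
    write_csv_commented(lt$tracks, file.path(out_dir, "lifetimes.csv"),
                        conv)
    record("lifetimes.csv")
    c(lt, nm)
  })

  # --- kinetics ---
  results$kinetics <- step("kinetics", {
    kin <- track_kinetics(tracks, scene$paxillin$frame_interval,
                          min_length = config$kinetics$min_length)
    write_csv_commented(kin, file.path(out_dir, "kinetics.csv"), conv)
    record("kinetics.csv")
    kin
  })

  # --- TFM (synthetic round trip) ---
  if (run_tfm) {
    results$tfm <- step("tfm", {
      tc <- config$tfm
      sub <- elastic_substrate(tc$youngs_modulus, tc$poisson_ratio)
      mesh <- traction_mesh(c(0, 64), c(0, 64), tc$mesh_n, tc$mesh_n)
      truth <- gaussian_traction_field(mesh, data.frame(
        x = c(24, 40), y = c(24, 40), sd = c(5, 5),
        tx = c(200, -200), ty = c(100, -100)), sub)
      sc <- generate_tfm_scene(truth, sub, bead_count = 300,
                               seed = config$seed, image_size = 256,
                               pixel_size = 0.25,
                               read_noise_sd = 4)
      fld <- ptv_displacement(sc$stressed, sc$relaxed,
                              template_size = tc$template_size,
                              max_displacement = tc$max_displacement,
                              pixel_size = sc$pixel_size,
                              corr_floor = tc$corr_floor)
      fld <- filter_displacement_outliers(fld,
                                          threshold = tc$outlier_threshold)
      sel <- select_regularization(fld, sub, mesh, tc$lambda_grid)
      rec <- reconstruct_traction(fld, sub, mesh, sel$lambda_corner,
                                  forward_matrix = sel$forward_matrix)
      node_tab <- cbind(rec$mesh$nodes, tx = rec$tx, ty = rec$ty)
      write_csv_commented(node_tab, file.path(out_dir, "tfm_nodes.csv"),
                          paste0(conv, "; lambda = ",
                                 signif(sel$lambda_corner, 4)))
      record("tfm_nodes.csv")
      list(field = fld, selection = sel, reconstruction = rec,
           scene = sc,
           total_force = total_force(rec, sc$cell_mask, sc$pixel_size))
    })
  }

  # --- report ---
  results$report <- step("report", {
    kin <- results$kinetics
    ok <- kin[!kin$failed & kin$passed_filter, ]
    samples <- list(
      assembly_rate = ok$rate_constant[ok$phase == "assembly"],
      disassembly_rate = ok$rate_constant[ok$phase == "disassembly"],
      na_lifetime = results$lifetimes$na_lifetimes)
    samples <- samples[lengths(samples) > 0]
    if (length(samples)) {
      rep <- build_report(list(condition_summary("run", samples,
                                                 n_cells = 1L)))
      tab <- do.call(rbind, lapply(names(rep$tables), function(r)
        cbind(readout = r, rep$tables[[r]])))
      write_csv_commented(tab, file.path(out_dir, "report.csv"), conv)
      record("report.csv")
      rep
    } else NULL
  })

  finish()
  invisible(results)
}

# deterministic set of plausible adhesion truths for default pipeline runs
default_truths <- function(cfg, n, seed) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed + 1000L)
  lapply(seq_len(n), function(i) {
    nuc <- sample(1:max(2, cfg$frame_count %/% 3), 1)
    adhesion_truth(
      id = i,
      x = stats::runif(1, 12, cfg$width - 13),
      y = stats::runif(1, 12, cfg$height - 13),
      nucleation_frame = nuc,
      assembly_rate = stats::runif(1, 0.5, 2.5),
      plateau_intensity = stats::runif(1, 300, 800),
      disassembly_start_frame = nuc +
        sample(8:max(9, cfg$frame_count %/% 2), 1),
      disassembly_rate = stats::runif(1, 0.3, 1.5),
      footprint_area = stats::runif(1, 0, 0.3),
      gfp_coupling = stats::runif(1, 0.5, 1.5))
  })
}
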