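# Manifest I/O, configuration validation and the end-to-end pipeline:
# correct -> clean -> normalize -> crop -> stitch, each stage skippable.

MANIFEST_SCHEMA_VERSION <- 1L

#' Write a snap manifest
#'
#' One JSON object per line (JSON-lines). The `pixels` list column, if
#' present, is dropped; unknown fields are preserved as-is.
#'
#' @param records Manifest tibble (one row per snap); must contain
#'   `strip_idx`, `angle_idx`, `angle_deg`, `depth_mm`, `band_nm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  validate_manifest(records)
  records <- dplyr::select(records, -dplyr::any_of("pixels"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(schema_version = MANIFEST_SCHEMA_VERSION),
                              auto_unbox = TRUE), con)
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                                digits = NA, null = "null"), con)
  }
  invisible(path)
}

#' Read a snap manifest
#'
#' @param path JSON-lines manifest written by [write_manifest()].
#' @param check_paths Verify that every `path` field points to an existing
#'   file (resolved relative to the manifest's directory).
#' @return Manifest tibble.
#' @export
read_manifest <- function(path, check_paths = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("Empty manifest.")
  header <- jsonlite::fromJSON(lines[1])
  body <- lines
  if (!is.null(header$schema_version)) body <- lines[-1]
  records <- dplyr::bind_rows(lapply(body, function(l) {
    tibble::as_tibble(lapply(jsonlite::fromJSON(l), function(x)
      if (is.null(x)) NA else x))
  }))
  validate_manifest(records)
  if (check_paths && "path" %in% names(records)) {
    full <- file.path(dirname(path), records$path)
    missing <- records$path[!file.exists(full)]
    if (length(missing)) {
      abort(sprintf("Manifest references missing files: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
  }
  records
}

validate_manifest <- function(records) {
  need <- c("strip_idx", "angle_idx", "angle_deg", "depth_mm", "band_nm")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(sprintf("Manifest lacks required fields: %s",
                  paste(miss, collapse = ", ")))
  }
  key <- paste(records$strip_idx, records$angle_idx, records$band_nm)
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate (strip_idx, angle_idx, band_nm) in manifest: %s",
                  key[anyDuplicated(key)]))
  }
  invisible(records)
}

#' Write a simulated acquisition to disk
#'
#' Writes every snap as PNG, the manifest as JSON-lines, the ground-truth
#' texture and the scene metadata - the on-disk layout the file-based
#' pipeline consumes.
#'
#' @param snaps A `snap_set` from [acquire()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with `path` column), invisibly.
#' @export
write_snap_set <- function(snaps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scene <- attr(snaps, "scene"); plan <- attr(snaps, "plan")
  camera <- attr(snaps, "camera")
  records <- dplyr::select(tibble::as_tibble(snaps), -dplyr::any_of("pixels"))
  records$path <- sprintf("snap_s%03d_a%02d_%s.png", snaps$strip_idx,
                          snaps$angle_idx, snaps$band_nm)
  purrr::walk2(snaps$pixels, records$path,
               ~ write_image(.x, file.path(dir, .y)))
  write_manifest(records, file.path(dir, "manifest.json"))
  if (!is.null(scene)) {
    write_image(scene$texture, file.path(dir, "ground_truth.png"))
    meta <- list(
      mm_per_px = scene$mm_per_px, tube_id_mm = scene$tube_id_mm,
      tube_len_mm = scene$tube_len_mm, seed = scene$seed,
      root_params = scene$root_params,
      plan = if (!is.null(plan)) unclass(plan),
      camera = if (!is.null(camera))
        unclass(camera)[setdiff(names(unclass(camera)), "forward_distortion")]
    )
    jsonlite::write_json(meta, file.path(dir, "scene_meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(records)
}

#' Load a snap set from a manifest
#'
#' @param manifest Manifest tibble (with `path`) or path to a manifest file.
#' @param dir Directory the image paths are relative to; defaults to the
#'   manifest's directory when `manifest` is a path.
#' @return A `snap_set` tibble with a `pixels` list column.
#' @export
read_snap_set <- function(manifest, dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(dir)) dir <- "."
  if (!"path" %in% names(manifest)) abort("Manifest has no `path` column.")
  manifest$pixels <- purrr::map(file.path(dir, manifest$path), read_image)
  class(manifest) <- c("snap_set", class(manifest))
  manifest
}

#' Save a distortion profile as JSON
#' @param profile A [distortion_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  jsonlite::write_json(
    list(cx = profile$cx, cy = profile$cy, k = profile$k,
         r_norm = profile$r_norm, r_max = profile$r_max,
         rms_px = profile$rms_px),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Load a distortion profile from JSON
#' @param path Profile JSON written by [write_profile()].
#' @return A [distortion_profile()].
#' @export
read_profile <- function(path) {
  p <- jsonlite::fromJSON(path)
  distortion_profile(k = p$k, cx = p$cx, cy = p$cy, r_norm = p$r_norm,
                     r_max = if (is.null(p$r_max)) 1.2 * p$r_norm else p$r_max,
                     rms_px = if (is.null(p$rms_px)) NA_real_ else p$rms_px)
}

#' Default pipeline configuration
#'
#' All defaults mirror the prototype tube imager: 60 degree lens, 40%
#' angular overlap, 35 x 28 mm snap footprint, 63.5 mm ID tube, 15 mm step.
#'
#' @return Nested configuration list (see [run_pipeline()]).
#' @export
default_config <- function() {
  list(
    plan = list(fov_deg = 60, angular_overlap_frac = 0.4, frame_w_mm = 35,
                frame_h_mm = 28, tube_id_mm = 63.5, tube_len_mm = 1000,
                step_mm = 15),
    stages = list(correct = TRUE, clean = TRUE, normalize = TRUE,
                  crop = TRUE, stitch = TRUE),
    profile = NULL,                 # path to profile.json or a profile object
    clean = list(policy = "auto", v_min = 0.5, s_max = 1, close_radius = 2,
                 fill = "interpolate"),
    crop = list(guard_px = 6),
    stitch = list(search_px = 2),
    seed = 1
  )
}

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("Config must be a list or a YAML file path.")
  config <- utils::modifyList(default_config(), config)
  st <- config$stages
  if (!is.list(st) || !all(vapply(st, is.logical, logical(1)))) {
    abort("`stages` must be a list of logical flags.")
  }
  if (!config$clean$fill %in% c("interpolate", "clamp_hue")) {
    abort("`clean$fill` must be 'interpolate' or 'clamp_hue'.")
  }
  if (config$crop$guard_px < 0) abort("`crop$guard_px` must be >= 0.")
  config
}

#' Run the full reconstruction pipeline
#'
#' Fixed stage order: reflection cleaning, distortion correction, exposure
#' normalization, overlap cropping, stitching. Reflections are removed
#' before geometric correction because the streaks are artifacts of the
#' sensor frame: they are straight and hue-coherent there, and whatever the
#' fill invents is then warped together with the real pixels. Each stage can
#' be skipped via `config$stages`; skipping everything still stitches the
#' raw geometric crops into a panorama.
#'
#' @param config Configuration list or YAML path (see [default_config()]).
#' @param snaps A `snap_set` (e.g. from [acquire()] or [read_snap_set()]);
#'   alternatively set `config$manifest` to load from disk.
#' @param plan,camera Geometry; default to the snap set's attributes.
#' @return List with `panorama` (a `tube_panorama`), `strips`, and `report`
#'   (per-stage timings, seam scores, mask coverage, provenance digest).
#' @export
run_pipeline <- function(config = list(), snaps = NULL,
                         plan = NULL, camera = NULL) {
  config <- validate_config(config)
  if (is.null(snaps)) {
    if (is.null(config$manifest)) {
      abort("Provide `snaps` or `config$manifest`.")
    }
    snaps <- read_snap_set(config$manifest, config$input_dir)
  }
  if (is.null(plan)) plan <- attr(snaps, "plan")
  if (is.null(camera)) camera <- attr(snaps, "camera")
  if (is.null(plan)) plan <- do.call(acquisition_plan, config$plan)
  if (is.null(camera)) {
    abort("No camera geometry available: pass `camera` or use a snap set from acquire().")
  }
  st <- config$stages
  report <- list(stages = list())
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, s = proc.time()[["elapsed"]] - t0)
  }

  if (isTRUE(st$clean) && n_channels(snaps$pixels[[1]]) == 3L) {
    cc <- config$clean
    tm <- clock({
      coverage <- numeric(nrow(snaps))
      masks <- vector("list", nrow(snaps))
      for (i in seq_len(nrow(snaps))) {
        m <- detect_reflections(snaps$pixels[[i]], policy = cc$policy,
                                hue_band = cc$hue_band, v_min = cc$v_min,
                                s_max = cc$s_max,
                                close_radius = cc$close_radius)
        coverage[i] <- m$coverage_frac
        masks[[i]] <- m$mask
        if (m$coverage_frac > 0 && m$coverage_frac < 1) {
          snaps$pixels[[i]] <- remove_reflections(snaps$pixels[[i]], m,
                                                  fill = cc$fill)
        }
      }
      # keep the masks: downstream registration must not trust filled pixels
      snaps$mask <- masks
      list(snaps = snaps, coverage = coverage)
    })
    snaps <- tm$value$snaps
    report$stages$clean <- list(seconds = tm$s,
                                mean_mask_coverage = mean(tm$value$coverage))
  }

  if (isTRUE(st$correct)) {
    profile <- config$profile
    if (is.character(profile)) {
      if (!file.exists(profile)) {
        abort(sprintf(paste(
          "Distortion correction is enabled but profile '%s' does not exist;",
          "run a calibration first or disable the correct stage."), profile))
      }
      profile <- read_profile(profile)
    }
    if (is.null(profile)) profile <- camera$forward_distortion
    if (is.null(profile)) {
      abort(paste("Distortion correction is enabled but no profile is",
                  "available; supply config$profile or disable the stage."))
    }
    tm <- clock({
      snaps$pixels <- purrr::map(snaps$pixels, correct_distortion,
                                 profile = profile)
      if ("mask" %in% names(snaps)) {
        # warp the reflection masks with the pixels; out-of-frame samples
        # are unreliable, so they stay flagged
        snaps$mask <- purrr::map(snaps$mask, function(m) {
          if (is.null(m)) return(NULL)
          warp_radial(m * 1, profile,
                      function(r) radial_forward(r, profile), fill = 1) > 0.2
        })
      }
      snaps
    })
    snaps <- tm$value
    report$stages$correct <- list(seconds = tm$s)
  }

  if (isTRUE(st$normalize)) {
    tm <- clock(exposure_normalize(snaps, plan = plan, camera = camera))
    snaps <- tm$value
    report$stages$normalize <- list(seconds = tm$s,
                                    gain_range = range(snaps$gain))
  }

  guard <- if (isTRUE(st$crop)) config$crop$guard_px else 0L
  tm <- clock(crop_usable(snaps, plan = plan, camera = camera,
                          guard_px = guard))
  snaps <- tm$value
  report$stages$crop <- list(seconds = tm$s, guard_px = guard)

  search <- if (isTRUE(st$stitch)) config$stitch$search_px else 0L
  tm <- clock({
    snaps |>
      dplyr::group_by(.data$strip_idx) |>
      dplyr::group_split() |>
      lapply(stitch_strip, search_px = search)
  })
  strips <- tm$value
  pano <- stitch_panorama(strips, search_px = search, plan = plan)
  report$stages$stitch <- list(
    seconds = tm$s,
    closure_px = vapply(strips, function(s) as.numeric(s$closure_residual_px),
                        numeric(1)),
    seam_scores = purrr::map(strips, "seam_scores"),
    alignment = pano$alignment
  )
  report$provenance <- rlang::hash(list(dim(pano$pixels),
                                        round(pano$pixels * 255),
                                        config[setdiff(names(config), "manifest")]))
  list(panorama = pano, strips = strips, report = report)
}
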