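# Synthetic cylinder scenes and degraded snap rendering. The generator
# emulates what the in-tube camera sees: a soil-textured cylinder interior
# with bright curvilinear roots pressed against the tube wall, imaged as
# overlapping snaps degraded by barrel distortion, vignetting, exposure
# jitter, specular reflection streaks and sensor noise. Ground truth is the
# unwrapped texture, so every downstream stage can be scored exactly.

#' Generate a synthetic tube scene
#'
#' The ground-truth unwrapped cylinder texture: width maps to the tube
#' circumference (angularly seamless), height to the tube length. Soil is
#' band-limited smooth noise around a brown base colour; roots are seeded
#' random-walk polylines with a Gaussian cross-section, brighter than any
#' soil pixel.
#'
#' @param tube_id_mm Tube inner diameter, mm.
#' @param tube_len_mm Imaged tube length, mm.
#' @param mm_per_px Texture scale, mm per pixel.
#' @param n_roots Number of root polylines.
#' @param root_width_mm Mean root width, mm (Gaussian cross-section sigma is
#'   half this width in px).
#' @param root_contrast Root brightness above the soil background, in
#'   intensity units (0-1 scale).
#' @param branch_prob Probability per path step that a root spawns a branch.
#' @param band_gains Named list/vector mapping band wavelength (nm, as
#'   character) to an intensity multiplier for single-band rendering.
#'   Defaults cover the ten LED bands 395-850 nm with gains rising towards
#'   the near infrared, where root/soil contrast is strongest.
#' @param seed RNG seed; the scene is deterministic given the seed.
#' @return A `tube_scene`: list with `texture` (H x W x 3), `mm_per_px`,
#'   `tube_id_mm`, `tube_len_mm`, `seed`, `root_params`, `band_gains`.
#' @export
tube_scene <- function(tube_id_mm = 63.5, tube_len_mm = 320,
                       mm_per_px = 1 / 3, n_roots = 6, root_width_mm = 1.5,
                       root_contrast = 0.35, branch_prob = 0.02,
                       band_gains = default_band_gains(), seed = 1) {
  check_positive(c(tube_id_mm, tube_len_mm, mm_per_px), "scene dimensions")
  w <- as.integer(round(pi * tube_id_mm / mm_per_px))
  h <- as.integer(round(tube_len_mm / mm_per_px))
  if (w < 8L || h < 8L) abort("Scene texture would be degenerately small.")

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }

  texture <- withr_seed({
    soil <- soil_texture(h, w)
    root_map <- matrix(0, h, w)
    sigma_px <- root_width_mm / mm_per_px / 2
    if (n_roots > 0) {
      pts <- do.call(rbind, lapply(seq_len(n_roots), function(i)
        root_path(h, w, sigma_px, branch_prob)))
      root_map <- stamp_all(h, w, pts)
    }
    a <- pmin(root_map, 1)
    root_col <- c(0.88, 0.82, 0.66)        # pale root tissue
    tex <- soil
    for (ch in 1:3) {
      tex[, , ch] <- soil[, , ch] * (1 - a) +
        (pmin(soil[, , ch] + root_contrast, 1) * 0.35 + root_col[ch] * 0.65) * a
    }
    clamp01(tex)
  })

  structure(list(
    texture = texture, mm_per_px = mm_per_px, tube_id_mm = tube_id_mm,
    tube_len_mm = tube_len_mm, seed = seed,
    root_params = list(n_roots = n_roots, root_width_mm = root_width_mm,
                       root_contrast = root_contrast,
                       branch_prob = branch_prob),
    band_gains = band_gains
  ), class = "tube_scene")
}

#' Default spectral gains for single-band rendering
#'
#' Intensity multipliers for the ten LED wavelengths of the multispectral
#' light source. Values are plausible relative reflectances (rising towards
#' the near infrared); they are a modelling choice, not measurements.
#'
#' @return Named numeric vector keyed by wavelength in nm.
#' @export
default_band_gains <- function() {
  c(`850` = 1.25, `700` = 1.1, `630` = 1.0, `610` = 0.97, `590` = 0.93,
    `555` = 0.88, `525` = 0.82, `475` = 0.72, `465` = 0.7, `395` = 0.55)
}

# Band-limited soil background: brown base modulated by two scales of
# circularly smoothed noise (wraps in both axes; only the angular wrap
# matters physically).
soil_texture <- function(h, w) {
  base <- c(0.42, 0.30, 0.20)
  coarse <- smooth_noise(h, w, sigma = 9)
  fine <- smooth_noise(h, w, sigma = 2.5)
  mod <- 0.75 + 0.5 * coarse + 0.25 * fine    # multiplicative shading field
  tint <- 0.1 * (smooth_noise(h, w, sigma = 13) - 0.5)
  tex <- array(0, c(h, w, 3L))
  tex[, , 1] <- base[1] * mod + tint
  tex[, , 2] <- base[2] * mod + 0.3 * tint
  tex[, , 3] <- base[3] * mod - 0.3 * tint
  clamp01(tex)
}

# White noise smoothed with a circular-boundary Gaussian, rescaled to [0, 1].
smooth_noise <- function(h, w, sigma) {
  z <- matrix(rnorm(h * w), h, w)
  side <- 2L * ceiling(2.5 * sigma) + 1L
  k <- EBImage::makeBrush(side, "gaussian", sigma = sigma)
  s <- EBImage::filter2(z, k, boundary = "circular")
  (s - min(s)) / (max(s) - min(s) + 1e-12)
}

# One root as a random-walk polyline growing downwards, with optional
# branches; returns the path as a matrix of (row, col, sigma) stamp points.
root_path <- function(h, w, sigma_px, branch_prob, start = NULL,
                      heading = NULL, max_len = NULL, depth_budget = 2L) {
  if (is.null(start)) start <- c(runif(1, 1, h / 3), runif(1, 1, w))
  if (is.null(heading)) heading <- pi / 2 + rnorm(1, 0, 0.3)  # mostly down
  if (is.null(max_len)) max_len <- h * runif(1, 0.6, 1.4)
  pos <- start
  step <- max(1, sigma_px / 2)
  n_steps <- ceiling(max_len / step)
  pts <- matrix(0, n_steps, 3L)
  used <- 0L
  extra <- NULL
  for (i in seq_len(n_steps)) {
    used <- used + 1L
    pts[used, ] <- c(pos, sigma_px)
    heading <- heading + rnorm(1, 0, 0.15) + 0.02 * (pi / 2 - heading)
    pos <- pos + step * c(sin(heading), cos(heading))
    pos[2] <- ((pos[2] - 1) %% w) + 1
    if (pos[1] > h || pos[1] < 1) break
    if (depth_budget > 0 && runif(1) < branch_prob) {
      extra <- rbind(extra, root_path(
        h, w, sigma_px * 0.7, branch_prob, start = pos,
        heading = heading + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
        max_len = max_len / 2, depth_budget = depth_budget - 1L
      ))
    }
  }
  rbind(pts[seq_len(used), , drop = FALSE], extra)
}

# Rasterize stamp points as max-combined Gaussians, x-wrapped. One function
# owns the map so the subassignments stay in place.
stamp_all <- function(h, w, pts) {
  map <- matrix(0, h, w)
  for (p in seq_len(nrow(pts))) {
    row <- pts[p, 1]; col <- pts[p, 2]; sigma <- pts[p, 3]
    rad <- ceiling(3 * sigma)
    rows <- max(1, floor(row - rad)):min(h, ceiling(row + rad))
    cols_raw <- floor(col - rad):ceiling(col + rad)
    cols <- ((cols_raw - 1) %% w) + 1
    patch <- exp(-(outer((rows - row)^2, (cols_raw - col)^2, "+")) /
                   (2 * sigma^2))
    map[rows, cols] <- pmax(map[rows, cols], patch)
  }
  map
}

#' @export
print.tube_scene <- function(x, ...) {
  d <- dim(x$texture)
  cat(sprintf(
    "<tube_scene> %d x %d px (%.3g mm/px), tube %g mm ID x %g mm, %d roots, seed %d\n",
    d[1], d[2], x$mm_per_px, x$tube_id_mm, x$tube_len_mm,
    x$root_params$n_roots, x$seed
  ))
  invisible(x)
}

#' @export
autoplot.tube_scene <- function(object, ...) plot_raster(object$texture,
  title = "Unwrapped tube scene (ground truth)")

#' Single-band view of a scene
#'
#' @param scene A [tube_scene()].
#' @param band_nm Wavelength key into `scene$band_gains`.
#' @return Luminance image scaled by the band gain.
#' @export
scene_band_image <- function(scene, band_nm) {
  key <- as.character(band_nm)
  if (!key %in% names(scene$band_gains)) {
    abort(sprintf("No band gain defined for %s nm.", key))
  }
  clamp01(luminance(scene$texture) * scene$band_gains[[key]])
}

# ---- Camera ----------------------------------------------------------------

#' Camera model for snap rendering
#'
#' Bundles the sensor geometry and all degradation parameters. With the
#' defaults every degradation is off, so a rendered snap is a plain bilinear
#' resample of the scene window.
#'
#' @param fov_deg Horizontal field of view, degrees.
#' @param sensor_w_px,sensor_h_px Sensor size in px.
#' @param frame_h_mm Vertical footprint of one snap on the tube wall, mm.
#' @param forward_distortion Optional [distortion_profile()] applied when
#'   rendering (the lens the correction stage must undo).
#' @param vignette_strength Peripheral darkening: intensity is scaled by
#'   `1 - strength * rho^2` with `rho` the corner-normalized radius.
#' @param exposure_jitter_sd SD of the per-snap log exposure gain
#'   (`gain = exp(N(0, sd))`).
#' @param reflection List: `n_streaks`, `width_px`, `value_boost`, `hue`
#'   (the artifact hue in [0,1)), `saturation_scale`.
#' @param noise_sd Additive Gaussian pixel noise SD (0-1 intensity scale).
#' @return A `camera_model` object.
#' @export
camera_model <- function(fov_deg = 60, sensor_w_px = 100, sensor_h_px = 84,
                         frame_h_mm = 28, forward_distortion = NULL,
                         vignette_strength = 0, exposure_jitter_sd = 0,
                         reflection = list(n_streaks = 0), noise_sd = 0) {
  check_positive(c(sensor_w_px, sensor_h_px, frame_h_mm), "sensor geometry")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  refl_defaults <- list(n_streaks = 0L, width_px = 3, value_boost = 0.35,
                        hue = 0.83, saturation_scale = 0.3)
  reflection <- utils::modifyList(refl_defaults, as.list(reflection))
  structure(list(
    fov_deg = fov_deg, sensor_w_px = as.integer(sensor_w_px),
    sensor_h_px = as.integer(sensor_h_px), frame_h_mm = frame_h_mm,
    forward_distortion = forward_distortion,
    vignette_strength = vignette_strength,
    exposure_jitter_sd = exposure_jitter_sd,
    reflection = reflection, noise_sd = noise_sd
  ), class = "camera_model")
}

#' Camera matched 1:1 to a scene's resolution
#'
#' Chooses sensor dimensions so one sensor pixel maps to roughly one scene
#' texture pixel (minimal resampling loss), given the plan geometry.
#'
#' @param scene A [tube_scene()].
#' @param plan An [acquisition_plan()].
#' @param ... Degradation parameters passed to [camera_model()].
#' @return A [camera_model()].
#' @export
camera_for_scene <- function(scene, plan, ...) {
  w_scene <- ncol(scene$texture)
  camera_model(
    fov_deg = plan$fov_deg,
    sensor_w_px = round(w_scene * plan$fov_deg / 360),
    sensor_h_px = round(plan$frame_h_mm / scene$mm_per_px),
    frame_h_mm = plan$frame_h_mm,
    ...
  )
}

#' A typical degraded field camera
#'
#' The default degradation set used in end-to-end tests: mild barrel
#' distortion, two reflection streaks, exposure jitter sd 0.05, additive
#' noise sd 2/255.
#'
#' @inheritParams camera_for_scene
#' @return A [camera_model()].
#' @export
degraded_camera_for_scene <- function(scene, plan, ...) {
  cam <- camera_for_scene(scene, plan)
  profile <- distortion_profile(
    k = c(-0.06, 0.01, 0), cx = (cam$sensor_w_px + 1) / 2,
    cy = (cam$sensor_h_px + 1) / 2,
    r_norm = sqrt(cam$sensor_w_px^2 + cam$sensor_h_px^2) / 2
  )
  camera_for_scene(scene, plan, forward_distortion = profile,
                   vignette_strength = 0.08, exposure_jitter_sd = 0.05,
                   reflection = list(n_streaks = 2L), noise_sd = 2 / 255, ...)
}

# ---- Rendering -------------------------------------------------------------

# Angular coordinate convention: angle 0 at the tube top, increasing
# clockwise viewed from the open end; scene column c spans angles
# [(c-1), c] * 360/W. Depth 0 at the top of the imaged window, increasing
# downward; depth_mm is the TOP edge of the snap footprint.
scene_col_of_angle <- function(angle_deg, w) (angle_deg / 360) * w + 0.5
scene_row_of_depth <- function(depth_mm, mm_per_px) depth_mm / mm_per_px + 0.5

#' Render one snap
#'
#' Extracts the angular window `[angle - fov/2, angle + fov/2]` and the
#' vertical window `[depth, depth + frame_h]` (wrapping angularly), resamples
#' it to the sensor grid, then applies in order: forward barrel distortion,
#' vignetting, exposure gain, reflection streaks, additive noise, clipping
#' and 8-bit quantization.
#'
#' @param scene A [tube_scene()].
#' @param camera A [camera_model()].
#' @param angle_deg Central angle of the snap, degrees.
#' @param depth_mm Top edge of the snap footprint, mm from the tube top.
#' @param band_nm `"RGB"` (default) or a wavelength key for single-band
#'   rendering.
#' @return A `snap` object: list with `pixels` and position metadata. The
#'   simulated reflection mask (if any) is attached as attribute
#'   `reflection_mask` of the pixels - ground truth for detection tests.
#' @export
render_snap <- function(scene, camera, angle_deg, depth_mm, band_nm = "RGB") {
  if (depth_mm < 0 || depth_mm + camera$frame_h_mm > scene$tube_len_mm + 1e-9) {
    abort(sprintf("Snap window [%g, %g] mm lies outside the tube (0-%g mm).",
                  depth_mm, depth_mm + camera$frame_h_mm, scene$tube_len_mm))
  }
  src <- if (identical(band_nm, "RGB")) scene$texture else
    scene_band_image(scene, band_nm)
  w_scene <- ncol(src); h_scene <- nrow(src)
  sw <- camera$sensor_w_px; sh <- camera$sensor_h_px

  ang <- angle_deg - camera$fov_deg / 2 +
    (seq_len(sw) - 0.5) * camera$fov_deg / sw
  src_col <- ((scene_col_of_angle(ang, w_scene) - 0.5) %% w_scene) + 0.5
  dep <- depth_mm + (seq_len(sh) - 0.5) * camera$frame_h_mm / sh
  src_row <- pmin(pmax(scene_row_of_depth(dep, scene$mm_per_px), 1), h_scene)

  col_m <- matrix(rep(src_col, each = sh), sh, sw)
  row_m <- matrix(rep(src_row, times = sw), sh, sw)
  # wrap-aware horizontal bilinear: sample twice only if the window crosses
  # the seam; simpler and exact: sample on an extended source
  img <- sample_wrapped(src, row_m, col_m)

  if (!is.null(camera$forward_distortion)) {
    img <- forward_distort(img, camera$forward_distortion, fill = 0)
  }
  if (camera$vignette_strength > 0) {
    cx <- (sw + 1) / 2; cy <- (sh + 1) / 2
    r2 <- outer((seq_len(sh) - cy)^2, (seq_len(sw) - cx)^2, "+")
    rho2 <- r2 / ((sw / 2)^2 + (sh / 2)^2)   # corner-normalized radius^2
    vig <- 1 - camera$vignette_strength * rho2
    img <- apply_gain(img, vig)
  }
  if (camera$exposure_jitter_sd > 0) {
    img <- clamp01(img * exp(rnorm(1, 0, camera$exposure_jitter_sd)))
  }
  refl_mask <- NULL
  if (camera$reflection$n_streaks > 0) {
    streaks <- streak_mask(sh, sw, camera$reflection)
    img <- apply_streaks(img, streaks, camera$reflection)
    refl_mask <- streaks
  }
  if (camera$noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, camera$noise_sd), dim(img))
  }
  img <- quantize8(img)
  if (!is.null(refl_mask)) attr(img, "reflection_mask") <- refl_mask
  structure(list(pixels = img, strip_idx = NA_integer_,
                 angle_idx = NA_integer_, angle_deg = angle_deg %% 360,
                 depth_mm = depth_mm, band_nm = band_nm),
            class = "snap")
}

# bilinear sampling with horizontal wraparound: pad one column on each side
sample_wrapped <- function(src, row_m, col_m) {
  w <- ncol(src)
  pad <- function(band) cbind(band[, w], band, band[, 1])
  if (n_channels(src) == 1L) {
    resample_grid(pad(src), row_m, col_m + 1)
  } else {
    out <- array(0, c(nrow(row_m), ncol(row_m), 3L))
    for (ch in 1:3) out[, , ch] <- resample_grid(pad(src[, , ch]), row_m, col_m + 1)
    out
  }
}

apply_gain <- function(img, gain) {
  if (n_channels(img) == 1L) return(clamp01(img * gain))
  for (ch in 1:3) img[, , ch] <- img[, , ch] * gain
  clamp01(img)
}

# Near-vertical streak lines with random position and slight slant.
streak_mask <- function(sh, sw, refl) {
  mask <- matrix(FALSE, sh, sw)
  for (i in seq_len(refl$n_streaks)) {
    x0 <- runif(1, sw * 0.1, sw * 0.9)
    slant <- rnorm(1, 0, 0.08)
    rows <- seq_len(sh)
    centre <- x0 + slant * (rows - sh / 2)
    half <- refl$width_px / 2
    for (r in rows) {
      c0 <- max(1L, floor(centre[r] - half))
      c1 <- min(sw, ceiling(centre[r] + half))
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  mask
}

apply_streaks <- function(img, mask, refl) {
  if (n_channels(img) == 1L) {
    img[mask] <- clamp01(img[mask] + refl$value_boost)
    return(img)
  }
  hsv <- to_hsv(img)
  h <- hsv[, , 1]; s <- hsv[, , 2]; v <- hsv[, , 3]
  h[mask] <- refl$hue
  s[mask] <- pmax(s[mask] * refl$saturation_scale, 0.15)  # keep hue defined
  v[mask] <- pmin(v[mask] + refl$value_boost, 1)
  hsv[, , 1] <- h; hsv[, , 2] <- s; hsv[, , 3] <- v
  from_hsv(hsv)
}

#' @export
print.snap <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<snap> %d x %d px, angle %.1f deg, depth %.1f mm, band %s\n",
              d[1], d[2], x$angle_deg, x$depth_mm, x$band_nm))
  invisible(x)
}

# ---- Acquisition -----------------------------------------------------------

#' Simulate a full scan
#'
#' Renders `snaps_per_rotation` snaps per strip at equal angular spacing and
#' strips at depths `0, step, 2 step, ...`, reproducing the automated scan
#' order (rotate through 360 degrees, then step down the tube). Deterministic
#' for a fixed seed.
#'
#' @param scene A [tube_scene()].
#' @param plan An [acquisition_plan()]; strips are limited to those whose
#'   windows fit inside the scene.
#' @param camera A [camera_model()].
#' @param seed RNG seed for the degradations.
#' @param bands `NULL` for RGB snaps, or a vector of wavelength keys for a
#'   multispectral acquisition (one snap per band per position).
#' @return A `snap_set`: a tibble with columns `snap_id`, `strip_idx`,
#'   `angle_idx`, `angle_deg`, `depth_mm`, `band_nm` and a `pixels` list
#'   column, with the scene/plan/camera attached as attributes.
#' @export
acquire <- function(scene, plan, camera, seed = 1, bands = NULL) {
  n_ang <- plan$snaps_per_rotation
  max_strips <- floor((scene$tube_len_mm - camera$frame_h_mm) / plan$step_mm) + 1
  n_strips <- min(plan$n_strips, max_strips)
  if (n_strips < 1) abort("Scene is too short for even one strip.")
  band_list <- if (is.null(bands)) "RGB" else as.character(bands)

  set.seed(seed)
  rows <- list()
  id <- 0L
  for (i in seq_len(n_strips) - 1L) {
    depth <- i * plan$step_mm
    for (j in seq_len(n_ang) - 1L) {
      angle <- j * 360 / n_ang
      for (b in band_list) {
        sn <- render_snap(scene, camera, angle, depth, band_nm = b)
        id <- id + 1L
        rows[[id]] <- tibble::tibble(
          snap_id = id, strip_idx = i, angle_idx = j,
          angle_deg = angle, depth_mm = depth, band_nm = b,
          pixels = list(sn$pixels)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "scene") <- scene
  attr(out, "plan") <- plan
  attr(out, "camera") <- camera
  attr(out, "seed") <- seed
  class(out) <- c("snap_set", class(out))
  out
}

#' Geometry-consistent ground truth for a reconstructed panorama
#'
#' Resamples the scene texture onto the panorama's own pixel grid (same
#' angular origin and depth mapping the crop/stitch geometry uses), so a
#' reconstruction can be scored with [ncc()] without geometric bias.
#'
#' @param scene The [tube_scene()] that was acquired.
#' @param plan The [acquisition_plan()] used.
#' @param camera The [camera_model()] used (fixes the exact sub-pixel crop
#'   offsets).
#' @param pano_dim `c(h, w)` of the reconstructed panorama.
#' @param n_strips Number of strips the panorama stacks (its height is
#'   `n_strips` equal blocks, each covering `step_mm` of depth).
#' @return Image array matching `pano_dim`.
#' @export
panorama_ground_truth <- function(scene, plan, camera, pano_dim, n_strips) {
  h <- pano_dim[1]; w <- pano_dim[2]
  geo <- crop_geometry(plan, camera)
  # panorama column 1 holds the first retained sensor column of snap 0
  # (angle 0); row 1 the first retained sensor row of strip 0 (depth 0)
  ang0 <- -plan$fov_deg / 2 + (geo$x0 + 0.5) * plan$fov_deg / camera$sensor_w_px
  ang <- ang0 + (seq_len(w) - 1) * 360 / w
  depth0 <- (geo$y0 + 0.5) * camera$frame_h_mm / camera$sensor_h_px
  dep <- depth0 + (seq_len(h) - 1) * plan$step_mm * n_strips / h
  src <- scene$texture
  w_s <- ncol(src); h_s <- nrow(src)
  col_m <- matrix(rep(((scene_col_of_angle(ang, w_s) - 0.5) %% w_s) + 0.5,
                      each = h), h, w)
  row_m <- matrix(rep(pmin(pmax(scene_row_of_depth(dep, scene$mm_per_px), 1),
                           h_s), times = w), h, w)
  sample_wrapped(src, row_m, col_m)
}
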