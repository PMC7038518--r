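# Exposure/colour normalization across snaps and extraction of the usable
# (non-overlapped) region of each snap. Normalization is gain-only, so the
# pixel rank order inside every snap is preserved; the overlap regions that
# the 40% angular / strip overlaps provide are the only cross-snap anchor.

overlap_px_angular <- function(plan, camera) {
  round(camera$sensor_w_px * (1 - (360 / plan$snaps_per_rotation) / plan$fov_deg))
}

overlap_px_vertical <- function(plan, camera) {
  round(camera$sensor_h_px * (plan$frame_h_mm - plan$step_mm) / plan$frame_h_mm)
}

median_lum <- function(img) median(luminance(img))

#' Exposure-normalize a snap set
#'
#' Estimates one scalar gain per snap so that the median luminance of each
#' snap's overlap regions matches its neighbours', anchored at a reference
#' snap. Adjacent snaps within a strip (including the 360-degree wraparound
#' pair) and vertically adjacent snaps across strips contribute one
#' log-gain equation each; the full system is solved by least squares, which
#' distributes any cycle-closure inconsistency evenly. Gains are clipped to
#' `[0.5, 2]`.
#'
#' @param snaps A `snap_set` tibble (see [acquire()]).
#' @param plan,camera Geometry; default to the snap set's attributes.
#' @param reference `snap_id` of the anchor snap (gain fixed at 1 before
#'   clipping); defaults to the first snap.
#' @return The snap set with a `gain` column and rescaled `pixels`.
#' @export
exposure_normalize <- function(snaps, plan = attr(snaps, "plan"),
                               camera = attr(snaps, "camera"),
                               reference = NULL) {
  if (is.null(plan) || is.null(camera)) {
    abort("Provide `plan` and `camera` (or a snap set carrying them).")
  }
  n <- nrow(snaps)
  if (is.null(reference)) reference <- snaps$snap_id[1]
  ref_row <- match(reference, snaps$snap_id)
  ov_x <- overlap_px_angular(plan, camera)
  ov_y <- overlap_px_vertical(plan, camera)

  if (ov_x <= 0 && ov_y <= 0) {
    warn("No overlap between snaps; falling back to global median matching.")
    med <- vapply(snaps$pixels, median_lum, numeric(1))
    g <- pmin(pmax(med[ref_row] / med, 0.5), 2)
    snaps$gain <- g
    snaps$pixels <- purrr::map2(snaps$pixels, g, ~ clamp01(.x * .y))
    return(snaps)
  }

  key <- paste(snaps$strip_idx, snaps$angle_idx, snaps$band_nm, sep = "/")
  lookup <- setNames(seq_len(n), key)
  n_ang <- plan$snaps_per_rotation
  edges <- list()  # each: c(i, j, d) meaning gamma_i - gamma_j = d
  add_edge <- function(i, j, d) edges[[length(edges) + 1L]] <<- c(i, j, d)

  for (r in seq_len(n)) {
    si <- snaps$strip_idx[r]; ai <- snaps$angle_idx[r]; bd <- snaps$band_nm[r]
    a_img <- snaps$pixels[[r]]
    sw <- ncol(luminance(a_img))
    # right neighbour in the same strip (wrapping 360 degrees)
    jn <- lookup[paste(si, (ai + 1) %% n_ang, bd, sep = "/")]
    if (!is.na(jn) && ov_x > 0) {
      b_img <- snaps$pixels[[jn]]
      ma <- median_lum(crop_cols(a_img, sw - ov_x + 1, sw))
      mb <- median_lum(crop_cols(b_img, 1, ov_x))
      if (ma > 0 && mb > 0) add_edge(r, jn, log(mb) - log(ma))
    }
    # same angle, next strip down
    kn <- lookup[paste(si + 1, ai, bd, sep = "/")]
    if (!is.na(kn) && ov_y > 0) {
      b_img <- snaps$pixels[[kn]]
      sh <- nrow(luminance(a_img))
      ma <- median_lum(crop_rows(a_img, sh - ov_y + 1, sh))
      mb <- median_lum(crop_rows(b_img, 1, ov_y))
      if (ma > 0 && mb > 0) add_edge(r, kn, log(mb) - log(ma))
    }
  }

  gamma <- rep(0, n)
  if (length(edges) > 0) {
    E <- do.call(rbind, edges)
    A <- matrix(0, nrow(E) + 1L, n)
    A[cbind(seq_len(nrow(E)), E[, 1])] <- 1
    A[cbind(seq_len(nrow(E)), E[, 2])] <- -1
    A[nrow(E) + 1L, ref_row] <- 1           # anchor the reference at 0
    b <- c(E[, 3], 0)
    gamma <- stats::lm.fit(A, b)$coefficients
    gamma[is.na(gamma)] <- 0
  }
  g <- pmin(pmax(exp(gamma - gamma[ref_row]), 0.5), 2)
  snaps$gain <- unname(g)
  snaps$pixels <- purrr::map2(snaps$pixels, snaps$gain,
                              ~ clamp01(.x * .y))
  snaps
}

crop_cols <- function(img, c0, c1) {
  if (n_channels(img) == 1L) img[, c0:c1, drop = FALSE] else img[, c0:c1, , drop = FALSE]
}
crop_rows <- function(img, r0, r1) {
  if (n_channels(img) == 1L) img[r0:r1, , drop = FALSE] else img[r0:r1, , , drop = FALSE]
}

#' Colour-correct a snap towards a reference gray
#'
#' Per-channel gains map the snap's median channel values toward the
#' reference gray ratio while preserving overall luminance. Single-band
#' images pass through unchanged.
#'
#' @param img Image array.
#' @param reference_gray Length-3 vector giving the target channel ratio
#'   (any scale); the default is neutral gray.
#' @return Colour-corrected image.
#' @export
color_correct <- function(img, reference_gray = c(1, 1, 1)) {
  img <- as_image(img, "img")
  if (n_channels(img) == 1L) return(img)
  med <- vapply(1:3, function(ch) median(img[, , ch]), numeric(1))
  if (any(med <= 0)) return(img)
  ref <- reference_gray / mean(reference_gray)
  gains <- ref * mean(med) / med
  for (ch in 1:3) img[, , ch] <- img[, , ch] * gains[ch]
  out <- clamp01(img)
  attr(out, "channel_gains") <- gains
  out
}

#' Crop geometry implied by a plan and camera
#'
#' The usable (non-overlapped) region of a snap spans `360 / n` degrees of
#' the `fov`-degree frame and `step_mm` of the `frame_h_mm`-tall frame; a
#' guard margin is kept on each side for stitching refinement and feather
#' blending.
#'
#' @param plan An [acquisition_plan()].
#' @param camera A [camera_model()].
#' @param guard_px Guard margin in px, `c(horizontal, vertical)` (scalar is
#'   recycled).
#' @return List with `crop_w`, `crop_h` (usable size, excluding guards),
#'   `x0`, `y0` (0-based offsets of the retained region including guards),
#'   and `guard = c(gx, gy)`.
#' @export
crop_geometry <- function(plan, camera, guard_px = 0L) {
  guard_px <- rep(as.integer(guard_px), length.out = 2L)
  crop_w <- round(camera$sensor_w_px * (360 / plan$snaps_per_rotation) /
                    plan$fov_deg)
  crop_h <- round(camera$sensor_h_px * plan$step_mm / plan$frame_h_mm)
  x0 <- floor((camera$sensor_w_px - crop_w) / 2) - guard_px[1]
  y0 <- floor((camera$sensor_h_px - crop_h) / 2) - guard_px[2]
  if (x0 < 0 || y0 < 0 ||
      x0 + crop_w + 2 * guard_px[1] > camera$sensor_w_px ||
      y0 + crop_h + 2 * guard_px[2] > camera$sensor_h_px) {
    abort("Guard margin exceeds the available overlap region.")
  }
  list(crop_w = as.integer(crop_w), crop_h = as.integer(crop_h),
       x0 = as.integer(x0), y0 = as.integer(y0), guard = guard_px)
}

#' Crop snaps to their usable regions
#'
#' Retains the central `360/n`-degree by `step_mm` region of each snap plus
#' a configurable guard margin, recording the crop offset so exact
#' reassembly coordinates are available downstream.
#'
#' @param snaps A `snap_set` tibble.
#' @param plan,camera Geometry; default to the snap set's attributes.
#' @param guard_px Guard margin in px (scalar or `c(gx, gy)`).
#' @return The snap set with cropped `pixels` and columns `crop_x0`,
#'   `crop_y0`, `crop_w`, `crop_h` (usable size) added; the crop geometry is
#'   attached as attribute `crop_geometry`.
#' @export
crop_usable <- function(snaps, plan = attr(snaps, "plan"),
                        camera = attr(snaps, "camera"), guard_px = 0L) {
  if (is.null(plan) || is.null(camera)) {
    abort("Provide `plan` and `camera` (or a snap set carrying them).")
  }
  geo <- crop_geometry(plan, camera, guard_px)
  w_keep <- geo$crop_w + 2L * geo$guard[1]
  h_keep <- geo$crop_h + 2L * geo$guard[2]
  crop_one <- function(img) {
    img <- crop_rows(img, geo$y0 + 1L, geo$y0 + h_keep)
    crop_cols(img, geo$x0 + 1L, geo$x0 + w_keep)
  }
  snaps$pixels <- purrr::map(snaps$pixels, crop_one)
  if ("mask" %in% names(snaps)) {
    snaps$mask <- purrr::map(snaps$mask, function(m)
      if (is.null(m)) NULL else crop_one(m))
  }
  snaps$crop_x0 <- geo$x0
  snaps$crop_y0 <- geo$y0
  snaps$crop_w <- geo$crop_w
  snaps$crop_h <- geo$crop_h
  attr(snaps, "crop_geometry") <- geo
  snaps
}
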