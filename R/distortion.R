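# Radial (barrel/pincushion) distortion: an even-order polynomial model
# fitted to point correspondences or a dot-grid target, with image
# correction by an inverse radius lookup table.
#
# Forward model: a scene point at undistorted radius r_u (about the
# distortion centre) images at r_d = r_u * (1 + k1 rho^2 + k2 rho^4 +
# k3 rho^6), rho = r_u / r_norm. Negative k1 gives barrel distortion
# (magnification falls off towards the edges), positive gives pincushion.

#' Radial distortion profile
#'
#' @param k Numeric length-3 vector of radial coefficients `(k1, k2, k3)`
#'   applied to `rho^2`, `rho^4`, `rho^6`.
#' @param cx,cy Distortion centre, pixel coordinates (col, row).
#' @param r_norm Normalization radius in pixels (typically half the sensor
#'   diagonal); coefficients are dimensionless w.r.t. this radius.
#' @param r_max Largest undistorted radius the profile must cover; the
#'   mapping is required to be strictly increasing on `[0, r_max]`.
#'   Defaults to `1.2 * r_norm`.
#' @param rms_px Fit residual, px (filled by [calibrate_distortion()]).
#' @return A `distortion_profile` object.
#' @export
distortion_profile <- function(k = c(0, 0, 0), cx, cy, r_norm,
                               r_max = 1.2 * r_norm, rms_px = NA_real_) {
  if (length(k) != 3L || !is.numeric(k)) abort("`k` must be numeric length 3.")
  check_positive(r_norm, "r_norm")
  p <- structure(list(k = as.numeric(k), cx = cx, cy = cy,
                      r_norm = r_norm, r_max = r_max, rms_px = rms_px),
                 class = "distortion_profile")
  assert_monotone(p)
  p
}

#' @export
print.distortion_profile <- function(x, ...) {
  cat(sprintf(
    "<distortion_profile> k = (%.5g, %.5g, %.5g), centre (%.2f, %.2f), r_norm %.1f px%s\n",
    x$k[1], x$k[2], x$k[3], x$cx, x$cy, x$r_norm,
    if (is.na(x$rms_px)) "" else sprintf(", rms %.3g px", x$rms_px)
  ))
  invisible(x)
}

# r_u -> r_d
radial_forward <- function(r, profile) {
  rho2 <- (r / profile$r_norm)^2
  r * (1 + profile$k[1] * rho2 + profile$k[2] * rho2^2 + profile$k[3] * rho2^3)
}

# d r_d / d r_u
radial_derivative <- function(r, profile) {
  rho2 <- (r / profile$r_norm)^2
  1 + 3 * profile$k[1] * rho2 + 5 * profile$k[2] * rho2^2 +
    7 * profile$k[3] * rho2^3
}

# Reject profiles that fold the image plane within the working radius.
assert_monotone <- function(profile, r_max = profile$r_max) {
  r <- seq(0, r_max, length.out = 512L)
  if (any(radial_derivative(r, profile) <= 0)) {
    abort("Distortion profile is not monotone increasing on [0, r_max].")
  }
  invisible(profile)
}

# Inverse radius lookup table r_d -> r_u, linear interpolation over 1024
# knots. Exact at the knots; the LUT is the documented numerical inverse.
radial_inverse_lut <- function(profile, r_max = profile$r_max,
                               n_knots = 1024L) {
  r_u <- seq(0, r_max, length.out = n_knots)
  r_d <- radial_forward(r_u, profile)
  function(r) approx(x = r_d, y = r_u, xout = r, rule = 2)$y
}

as_points <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$x, x$y)
  if (!is.matrix(x) || ncol(x) != 2L) {
    abort("Points must be an n x 2 matrix or a data frame with columns x, y.")
  }
  x
}

map_points_radial <- function(pts, profile, radius_fun) {
  dx <- pts[, 1] - profile$cx
  dy <- pts[, 2] - profile$cy
  r <- sqrt(dx^2 + dy^2)
  r_new <- radius_fun(r)
  scale <- ifelse(r > 0, r_new / r, 1)
  cbind(x = profile$cx + dx * scale, y = profile$cy + dy * scale)
}

# Radial image warp: output pixel at radius r samples the input at radius
# src_radius_fun(r) about the distortion centre.
warp_radial <- function(img, profile, src_radius_fun, fill = 0) {
  img <- as_image(img, "img")
  h <- nrow(img); w <- ncol(img)
  col <- matrix(rep(seq_len(w), each = h), h, w)
  row <- matrix(rep(seq_len(h), times = w), h, w)
  dx <- col - profile$cx
  dy <- row - profile$cy
  r <- sqrt(dx^2 + dy^2)
  r_src <- matrix(src_radius_fun(as.vector(r)), h, w)
  s <- ifelse(r > 0, r_src / r, 1)
  resample_grid(img, profile$cy + dy * s, profile$cx + dx * s, fill = fill)
}

#' Apply forward distortion
#'
#' Maps undistorted input to its distorted appearance: a point at
#' undistorted radius `r_u` moves to `r_d = r_u (1 + k1 rho^2 + ...)`.
#' Points are mapped in closed form; images are resampled bilinearly
#' (each output pixel samples the source at the numerically inverted
#' radius, so image features move by the forward mapping).
#'
#' @param x An image array, or points as an n x 2 matrix / data frame with
#'   columns `x` (col) and `y` (row).
#' @param profile A [distortion_profile()].
#' @param fill Fill value for out-of-frame samples (images only).
#' @return Same type as `x`.
#' @export
forward_distort <- function(x, profile, fill = 0) {
  assert_monotone(profile)
  if (is_points_input(x)) {
    pts <- as_points(x)
    return(map_points_radial(pts, profile, function(r) radial_forward(r, profile)))
  }
  inv <- radial_inverse_lut(profile, r_max = frame_r_max(x, profile))
  warp_radial(x, profile, inv, fill = fill)
}

#' Correct distortion
#'
#' Inverse of [forward_distort()]: restores the undistorted geometry.
#' Points are mapped through the numerically inverted radius LUT; each
#' corrected image pixel samples the distorted source at its forward-mapped
#' radius.
#'
#' @inheritParams forward_distort
#' @return Same type as `x`.
#' @export
correct_distortion <- function(x, profile, fill = 0) {
  assert_monotone(profile)
  if (is_points_input(x)) {
    pts <- as_points(x)
    inv <- radial_inverse_lut(profile, r_max = max(profile$r_max,
                                                   point_r_max(pts, profile)))
    return(map_points_radial(pts, profile, inv))
  }
  warp_radial(x, profile, function(r) radial_forward(r, profile), fill = fill)
}

# Data frames and two-column matrices are point sets; anything else with
# image dimensions is an image (a 2-px-wide image is not a supported input).
is_points_input <- function(x) {
  is.data.frame(x) || (is.matrix(x) && ncol(x) == 2L)
}

frame_r_max <- function(img, profile) {
  h <- nrow(img); w <- ncol(img)
  corners <- rbind(c(1, 1), c(w, 1), c(1, h), c(w, h))
  max(sqrt((corners[, 1] - profile$cx)^2 + (corners[, 2] - profile$cy)^2),
      profile$r_max)
}

point_r_max <- function(pts, profile) {
  max(sqrt((pts[, 1] - profile$cx)^2 + (pts[, 2] - profile$cy)^2))
}

#' Calibrate a radial distortion profile from point correspondences
#'
#' Least-squares fit of `(k1, k2, k3, cx, cy)` minimizing the squared
#' distance between predicted and observed distorted positions. Given a
#' centre the residual is linear in `k`, so `k` is solved by linear least
#' squares inside a Nelder-Mead search over the centre.
#'
#' @param undistorted,distorted Matching point sets (n x 2 matrices or data
#'   frames with `x`, `y`): ideal target positions and their observed
#'   (distorted) image positions. At least 12 correspondences spanning at
#'   least 3 distinct radii are required, and the points must not be
#'   collinear.
#' @param r_norm Normalization radius; defaults to the largest point radius
#'   about the initial centre.
#' @param center_init Initial centre `(cx, cy)`; defaults to the centroid of
#'   the undistorted points.
#' @param fix_center Keep the centre at `center_init` (linear fit only).
#' @return A [distortion_profile()] with `rms_px` set to the RMS residual.
#' @export
calibrate_distortion <- function(undistorted, distorted, r_norm = NULL,
                                 center_init = NULL, fix_center = FALSE) {
  pu <- as_points(undistorted)
  pd <- as_points(distorted)
  if (nrow(pu) != nrow(pd)) abort("Point sets must have equal length.")
  if (nrow(pu) < 12L) {
    abort("Need at least 12 point correspondences to calibrate.")
  }
  ctr <- if (is.null(center_init)) colMeans(pu) else center_init
  # geometry checks at the initial centre
  r0 <- sqrt((pu[, 1] - ctr[1])^2 + (pu[, 2] - ctr[2])^2)
  if (length(unique(signif(r0, 6))) < 3L) {
    abort("Degenerate geometry: points span fewer than 3 distinct radii.")
  }
  sv <- svd(scale(pu, center = TRUE, scale = FALSE))$d
  if (sv[2] < 1e-8 * sv[1]) {
    abort("Degenerate geometry: calibration points are collinear.")
  }
  if (is.null(r_norm)) r_norm <- max(r0)

  # Given a centre, solve k by linear LS on stacked x/y displacement
  # equations: pd - pu = (pu - c) * (k1 rho^2 + k2 rho^4 + k3 rho^6).
  solve_k <- function(ctr) {
    dx <- pu[, 1] - ctr[1]; dy <- pu[, 2] - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    rho2 <- (r / r_norm)^2
    A <- rbind(cbind(dx * rho2, dx * rho2^2, dx * rho2^3),
               cbind(dy * rho2, dy * rho2^2, dy * rho2^3))
    b <- c(pd[, 1] - pu[, 1], pd[, 2] - pu[, 2])
    fit <- stats::lm.fit(A, b)
    res <- matrix(fit$residuals, ncol = 2L)
    list(k = unname(coef(fit)),
         rss = sum(fit$residuals^2),
         rms = sqrt(mean(res[, 1]^2 + res[, 2]^2)))
  }

  if (fix_center) {
    sol <- solve_k(ctr)
  } else {
    obj <- function(theta) solve_k(theta)$rss
    opt <- optim(ctr, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 500))
    ctr <- opt$par
    sol <- solve_k(ctr)
  }
  if (any(is.na(sol$k))) {
    abort("Degenerate geometry: radial design matrix is rank deficient.")
  }
  distortion_profile(k = sol$k, cx = ctr[1], cy = ctr[2], r_norm = r_norm,
                     r_max = max(r0) * 1.05, rms_px = sol$rms)
}

#' Render a synthetic dot-grid calibration target
#'
#' A white background with dark circular dots on a regular grid, centred in
#' the frame - the software analogue of the printed target used to measure
#' a lens distortion profile.
#'
#' @param nx,ny Dots per row / column.
#' @param spacing_px Dot pitch, px.
#' @param dot_radius_px Dot radius, px.
#' @param size `c(h, w)` output size in px; defaults to the grid extent plus
#'   one pitch of margin.
#' @return A list with `image` (matrix) and `points` (n x 2 matrix of dot
#'   centres, columns `x`, `y`, row-major order).
#' @export
render_dot_grid <- function(nx = 9, ny = 7, spacing_px = 20, dot_radius_px = 3,
                            size = NULL) {
  if (is.null(size)) {
    size <- c(ceiling((ny + 1) * spacing_px), ceiling((nx + 1) * spacing_px))
  }
  h <- size[1]; w <- size[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  gx <- (seq_len(nx) - (nx + 1) / 2) * spacing_px + cx
  gy <- (seq_len(ny) - (ny + 1) / 2) * spacing_px + cy
  pts <- cbind(x = rep(gx, times = ny), y = rep(gy, each = nx))
  img <- matrix(1, h, w)
  col <- matrix(rep(seq_len(w), each = h), h, w)
  row <- matrix(rep(seq_len(h), times = w), h, w)
  for (i in seq_len(nrow(pts))) {
    d2 <- (col - pts[i, 1])^2 + (row - pts[i, 2])^2
    # soft-edged dot: 1 px anti-aliasing ramp keeps centroids accurate
    img <- pmin(img, clamp01((sqrt(d2) - dot_radius_px) / 1 + 0.5))
  }
  list(image = img, points = pts)
}

#' Detect dot centroids in a grid-target image
#'
#' Thresholds dark dots, labels connected components and returns intensity-
#' weighted centroids.
#'
#' @param img Single-band image of dark dots on a light background.
#' @param threshold Intensity below which a pixel belongs to a dot.
#' @param min_px Minimum component area in px to count as a dot.
#' @return n x 2 matrix of centroids (columns `x`, `y`).
#' @export
detect_grid_points <- function(img, threshold = 0.5, min_px = 4L) {
  img <- as_image(img, "img")
  if (n_channels(img) != 1L) img <- luminance(img)
  mask <- img < threshold
  lab <- EBImage::bwlabel(mask)
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  if (length(ids) == 0L) abort("No dots found below the threshold.")
  wgt <- (threshold - img) * mask          # darker pixels weigh more
  h <- nrow(img); w <- ncol(img)
  col <- matrix(rep(seq_len(w), each = h), h, w)
  row <- matrix(rep(seq_len(h), times = w), h, w)
  out <- t(vapply(ids, function(id) {
    sel <- lab == id
    if (sum(sel) < min_px) return(c(NA_real_, NA_real_))
    ww <- wgt[sel]
    c(sum(col[sel] * ww) / sum(ww), sum(row[sel] * ww) / sum(ww))
  }, numeric(2)))
  out <- out[stats::complete.cases(out), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Calibrate from a distorted dot-grid image
#'
#' Detects dot centroids in a distorted image of a [render_dot_grid()]-style
#' target, pairs each ideal grid point with its nearest detected centroid,
#' and fits the radial profile.
#'
#' @param img Distorted image of the target.
#' @param grid_points Ideal (undistorted) dot centres, n x 2.
#' @param ... Passed to [calibrate_distortion()].
#' @inheritParams detect_grid_points
#' @return A [distortion_profile()].
#' @export
calibrate_from_grid <- function(img, grid_points, threshold = 0.5, ...) {
  det <- detect_grid_points(img, threshold = threshold)
  gp <- as_points(grid_points)
  if (nrow(det) < nrow(gp)) {
    warn(sprintf("Detected %d of %d grid dots.", nrow(det), nrow(gp)))
  }
  # pair each ideal point with the nearest detected centroid
  idx <- vapply(seq_len(nrow(gp)), function(i) {
    which.min((det[, 1] - gp[i, 1])^2 + (det[, 2] - gp[i, 2])^2)
  }, integer(1))
  if (anyDuplicated(idx)) {
    keep <- !duplicated(idx)
    gp <- gp[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  calibrate_distortion(gp, det[idx, , drop = FALSE], ...)
}

#' @export
tidy.distortion_profile <- function(x, ...) {
  tibble::tibble(term = c("k1", "k2", "k3", "cx", "cy", "r_norm"),
                 estimate = c(x$k, x$cx, x$cy, x$r_norm))
}

#' @export
glance.distortion_profile <- function(x, ...) {
  tibble::tibble(k1 = x$k[1], k2 = x$k[2], k3 = x$k[3], cx = x$cx, cy = x$cy,
                 r_norm = x$r_norm, rms_px = x$rms_px)
}

#' @export
autoplot.distortion_profile <- function(object, r_max = object$r_max, ...) {
  r <- seq(0, r_max, length.out = 256)
  d <- tibble::tibble(r_u = r, r_d = radial_forward(r, object))
  ggplot2::ggplot(d, ggplot2::aes(.data$r_u, .data$r_d)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2a6f97") +
    ggplot2::labs(x = "undistorted radius (px)", y = "distorted radius (px)",
                  title = "Radial distortion profile") +
    ggplot2::theme_minimal()
}
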