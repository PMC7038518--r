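# Radial distortion model: forward mapping, calibration, correction.

test_that("identity and closed-form point mappings behave as derived", {
  prof0 <- distortion_profile(k = c(0, 0, 0), cx = 50, cy = 40, r_norm = 60)
  pts <- cbind(x = c(50, 10, 80, 33.5), y = c(40, 5, 70, 61.2))
  expect_equal(forward_distort(pts, prof0), pts,
               ignore_attr = TRUE, tolerance = 0)
  # the centre is a fixed point for any coefficients
  prof <- distortion_profile(k = c(0.1, -0.02, 0.003), cx = 50, cy = 40,
                             r_norm = 60)
  expect_equal(forward_distort(cbind(x = 50, y = 40), prof),
               cbind(x = 50, y = 40), ignore_attr = TRUE)
  # a point at rho = 1 with k1 = 0.1 moves radially outward by 10%
  prof1 <- distortion_profile(k = c(0.1, 0, 0), cx = 0, cy = 0, r_norm = 100)
  moved <- forward_distort(cbind(x = 100, y = 0), prof1)
  expect_equal(unname(moved[1, 1]), 110)
  expect_equal(unname(moved[1, 2]), 0)
  # identity profile on an image returns the image
  img <- small_scene()$texture[1:40, 1:50, ]
  expect_images_equal(forward_distort(img, distortion_profile(
    k = c(0, 0, 0), cx = 25.5, cy = 20.5, r_norm = 32)), img, tol = 1e-6)
})

test_that("noise-free calibration recovers the generating profile exactly", {
  true <- distortion_profile(k = c(-0.08, 0.015, -0.002), cx = 51.2, cy = 40.7,
                             r_norm = 60)
  pu <- cbind(x = rep(seq(10, 90, 10), 7), y = rep(seq(10, 70, 10), each = 9))
  pd <- forward_distort(pu, true)
  fit <- calibrate_distortion(pu, pd, r_norm = 60)
  expect_lt(max(abs(fit$k - true$k)), 1e-6)
  expect_lt(abs(fit$cx - true$cx) + abs(fit$cy - true$cy), 1e-4)
  expect_lt(fit$rms_px, 1e-6)
})

test_that("calibration under 0.2 px noise recovers the barrel profile", {
  # strong barrel, as for a wide-angle lens; 100 grid points
  set.seed(314)
  true <- distortion_profile(k = c(-0.28, 0.045, -0.006), cx = 60.5, cy = 50.5,
                             r_norm = 78)
  pu <- cbind(x = rep(seq(6, 115, length.out = 10), 10),
              y = rep(seq(5, 96, length.out = 10), each = 10))
  pd <- forward_distort(pu, true) + rnorm(length(pu), 0, 0.2)
  fit <- calibrate_distortion(pu, pd, r_norm = 78)
  expect_lt(abs(fit$k[1] - true$k[1]) / abs(true$k[1]), 0.05)
  # the recovered radial curve agrees with the true one to sub-pixel level
  r <- seq(0, 78, length.out = 200)
  curve_err <- max(abs(rhizopan:::radial_forward(r, fit) -
                         rhizopan:::radial_forward(r, true)))
  expect_lt(curve_err, 0.5)     # sub-pixel agreement under 0.2 px noise
  expect_lt(fit$rms_px, 0.4)
})

test_that("degenerate calibration geometries are rejected", {
  prof <- test_profile()
  # too few points (8 collinear points also fail the count gate)
  line <- cbind(x = seq(10, 80, 10), y = seq(5, 40, 5))
  expect_error(calibrate_distortion(line, line), "12")
  # collinear points, enough of them
  line2 <- cbind(x = seq_len(15) * 5, y = seq_len(15) * 2 + 3)
  expect_error(calibrate_distortion(line2, line2), "collinear")
  # all points at one radius about the centroid
  th <- seq(0, 2 * pi, length.out = 16)[-16]
  circ <- cbind(x = 50 + 30 * cos(th), y = 40 + 30 * sin(th))
  expect_error(calibrate_distortion(circ, circ, center_init = c(50, 40)),
               "radii")
})

test_that("point-level correct-forward round trip is the identity", {
  prof <- distortion_profile(k = c(-0.12, 0.02, -0.001), cx = 48, cy = 44,
                             r_norm = 66)
  set.seed(5)
  pts <- cbind(x = runif(200, 2, 98), y = runif(200, 2, 82))
  rt <- correct_distortion(forward_distort(pts, prof), prof)
  expect_lt(max(abs(rt - pts)), 1e-3)
})

test_that("image correction undoes forward distortion to interpolation level", {
  img <- small_scene()$texture[1:84, 1:100, ]
  prof <- test_profile()
  rt <- correct_distortion(forward_distort(img, prof), prof)
  # score inside the valid region (borders lose pixels to the fill value)
  rr <- sqrt(outer((1:84 - prof$cy)^2, rep(1, 100)) +
               outer(rep(1, 84), (1:100 - prof$cx)^2))
  valid <- rr < 38
  err <- abs(rt - img)
  mean_err <- mean(vapply(1:3, function(ch) mean(err[, , ch][valid]),
                          numeric(1)))
  expect_lt(mean_err, 2 / 255)
})

test_that("distorted grid lines are straight again after correction", {
  # horizontal and vertical lines on a synthetic grid
  h <- 84; w <- 100
  img <- matrix(1, h, w)
  rows <- seq(12, 72, 12); cols <- seq(10, 90, 16)
  img[rows, ] <- 0
  img[, cols] <- 0
  prof <- test_profile(w, h)
  rt <- correct_distortion(forward_distort(img, prof, fill = 1), prof,
                           fill = 1)
  # fit each dark row in the central region; max deviation from straight
  for (r in rows) {
    prof_cols <- 25:75
    centres <- vapply(prof_cols, function(cc) {
      colv <- 1 - rt[(r - 3):(r + 3), cc]
      if (sum(colv) < 0.2) return(NA_real_)
      sum(((r - 3):(r + 3)) * colv) / sum(colv)
    }, numeric(1))
    centres <- centres[!is.na(centres)]
    expect_lt(max(abs(centres - median(centres))), 0.5)
  }
})

test_that("non-monotone profiles are rejected", {
  expect_error(
    distortion_profile(k = c(-0.5, 0, 0), cx = 50, cy = 40, r_norm = 50,
                       r_max = 60),
    "monotone"
  )
  # monotone within r_max passes even if it would fold further out
  expect_s3_class(
    distortion_profile(k = c(-0.2, 0, 0), cx = 50, cy = 40, r_norm = 50,
                       r_max = 50),
    "distortion_profile"
  )
})

test_that("dot-grid image calibration recovers the profile", {
  g <- render_dot_grid(9, 7, 14, 2.5)
  true <- distortion_profile(k = c(-0.15, 0.02, 0),
                             cx = (ncol(g$image) + 1) / 2,
                             cy = (nrow(g$image) + 1) / 2, r_norm = 80)
  distorted <- forward_distort(g$image, true, fill = 1)
  fit <- calibrate_from_grid(distorted, g$points, r_norm = 80)
  expect_lt(abs(fit$k[1] - true$k[1]) / abs(true$k[1]), 0.05)
  expect_lt(fit$rms_px, 0.2)
  # centroid detection alone is sub-pixel accurate on the undistorted target
  det <- detect_grid_points(g$image)
  expect_equal(nrow(det), nrow(g$points))
  ord <- order(round(det[, 2]), det[, 1])
  expect_lt(max(abs(det[ord, ] - g$points)), 0.15)
})
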