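# Synthetic tube scenes and degraded snap rendering.

test_that("scene generation is deterministic and dimensionally consistent", {
  a <- tube_scene(tube_len_mm = 60, seed = 3)
  b <- tube_scene(tube_len_mm = 60, seed = 3)
  expect_identical(a$texture, b$texture)
  c <- tube_scene(tube_len_mm = 60, seed = 4)
  expect_false(identical(a$texture, c$texture))
  # width times scale is the circumference, within one pixel
  expect_lt(abs(ncol(a$texture) * a$mm_per_px - pi * a$tube_id_mm),
            a$mm_per_px)
  expect_error(tube_scene(tube_len_mm = 0.5, mm_per_px = 1), "small")
})

test_that("roots brighten the scene and their pixel fraction grows with count", {
  soil_only <- tube_scene(tube_len_mm = 60, n_roots = 0, seed = 9)
  lum0 <- luminance(soil_only$texture)
  thr <- max(lum0)           # soil never exceeds this by construction
  fracs <- vapply(c(0, 2, 5, 10), function(n) {
    sc <- tube_scene(tube_len_mm = 60, n_roots = n, seed = 9)
    mean(luminance(sc$texture) > thr + 0.02)
  }, numeric(1))
  expect_equal(fracs[1], 0)
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[4], fracs[2])
})

test_that("an undegraded snap equals a direct bilinear resample of its window", {
  scene <- small_scene(); plan <- small_plan(); cam <- small_camera()
  sn <- render_snap(scene, cam, angle_deg = 72, depth_mm = 15)
  # independent resample: same geometry, computed directly here
  w_s <- ncol(scene$texture)
  ang <- 72 - cam$fov_deg / 2 + (seq_len(cam$sensor_w_px) - 0.5) *
    cam$fov_deg / cam$sensor_w_px
  cols <- (ang / 360 * w_s + 0.5 - 0.5) %% w_s + 0.5
  dep <- 15 + (seq_len(cam$sensor_h_px) - 0.5) *
    cam$frame_h_mm / cam$sensor_h_px
  rows <- dep / scene$mm_per_px + 0.5
  ref <- array(0, c(cam$sensor_h_px, cam$sensor_w_px, 3))
  for (ch in 1:3) {
    band <- cbind(scene$texture[, w_s, ch], scene$texture[, , ch],
                  scene$texture[, 1, ch])
    ref[, , ch] <- matrix(
      bilinear_sample(band, rep(rows, times = length(cols)),
                      rep(cols + 1, each = length(rows))),
      length(rows), length(cols)
    )
  }
  expect_lt(max(abs(sn$pixels - ref)), 1 / 255 + 1e-9)
})

test_that("snaps wrap seamlessly across the angular seam", {
  scene <- small_scene(); cam <- small_camera()
  sn <- render_snap(scene, cam, angle_deg = 350, depth_mm = 10)
  # same view rendered from a scene rolled by half a turn
  w_s <- ncol(scene$texture)
  shift <- w_s %/% 2
  rolled <- scene
  rolled$texture <- scene$texture[, c((shift + 1):w_s, 1:shift), , drop = FALSE]
  sn2 <- render_snap(rolled, cam, angle_deg = (350 - shift * 360 / w_s) %% 360,
                     depth_mm = 10)
  expect_lt(mean(abs(sn$pixels - sn2$pixels)), 2 / 255)
  expect_lt(max(abs(sn$pixels - sn2$pixels)), 8 / 255)
})

test_that("depths outside the tube are rejected", {
  scene <- small_scene(); cam <- small_camera()
  expect_error(render_snap(scene, cam, 0, -1), "outside")
  expect_error(render_snap(scene, cam, 0, scene$tube_len_mm - 5), "outside")
})

test_that("reflection streaks change exactly the configured streak region", {
  scene <- small_scene(); plan <- small_plan()
  clean_cam <- small_camera()
  refl_cam <- camera_for_scene(scene, plan,
                               reflection = list(n_streaks = 2))
  set.seed(21); clean <- render_snap(scene, clean_cam, 36, 5)
  set.seed(21); streaked <- render_snap(scene, refl_cam, 36, 5)
  mask <- attr(streaked$pixels, "reflection_mask")
  expect_true(is.logical(mask))
  diff <- apply(abs(streaked$pixels - clean$pixels), c(1, 2), max)
  expect_true(all(diff[!mask] <= 1 / 255 + 1e-9))   # quantization only
  expect_gt(mean(diff[mask] > 2 / 255), 0.8)        # streak really changed
})

test_that("zero-jitter snaps preserve the window's mean intensity", {
  scene <- small_scene(); cam <- small_camera()
  sn <- render_snap(scene, cam, 144, 10)
  # mean of the source window, computed via the scene directly
  w_s <- ncol(scene$texture)
  ang <- (144 + c(-30, 30)) / 360 * w_s
  rows <- round(10 / scene$mm_per_px + 0.5):round(38 / scene$mm_per_px)
  cols0 <- (floor(ang[1]):ceiling(ang[2]) - 1) %% w_s + 1
  src_mean <- mean(luminance(scene$texture[rows, cols0, , drop = FALSE]))
  expect_lt(abs(mean(luminance(sn$pixels)) - src_mean) / src_mean, 0.01)
})

test_that("acquire produces the planned snap grid deterministically", {
  snaps <- small_snaps()
  plan <- small_plan()
  expect_equal(nrow(snaps), plan$n_strips * plan$snaps_per_rotation)
  expect_setequal(unique(snaps$strip_idx), 0:(plan$n_strips - 1))
  expect_setequal(unique(snaps$angle_idx), 0:9)
  expect_equal(sort(unique(snaps$angle_deg)), seq(0, 324, 36))
  expect_equal(sort(unique(snaps$depth_mm)), c(0, 15, 30))
  # byte-identical reproducibility
  again <- acquire(small_scene(), plan, small_camera(), seed = 7)
  expect_identical(snaps$pixels, again$pixels)
  # full-scale plan: 660 snaps for a 1000 mm tube (geometry only)
  expect_identical(total_images(acquisition_plan()), 660L)
})

test_that("a multispectral acquisition renders one snap per band", {
  scene <- small_scene(); plan <- small_plan()
  cam <- small_camera()
  bands <- names(default_band_gains())
  one_strip <- acquisition_plan(tube_len_mm = 15, step_mm = 15)
  ms <- acquire(scene, one_strip, cam, seed = 2, bands = bands)
  expect_equal(nrow(ms), 10 * length(bands))
  expect_setequal(unique(ms$band_nm), bands)
  expect_setequal(as.integer(unique(ms$band_nm)),
                  c(850, 700, 630, 610, 590, 555, 525, 475, 465, 395))
  # band snaps are single-band images scaled by the band gain
  expect_true(is.matrix(ms$pixels[[1]]))
  m850 <- mean(ms$pixels[[which(ms$band_nm == "850")[1]]])
  m395 <- mean(ms$pixels[[which(ms$band_nm == "395")[1]]])
  expect_gt(m850, m395)
})

test_that("undistorted snap footprints tile and cover the scene", {
  # zero overlap: 6 snaps of 60 degrees tile 360 exactly
  plan0 <- acquisition_plan(angular_overlap_frac = 0, tube_len_mm = 15,
                            step_mm = 15)
  expect_identical(plan0$snaps_per_rotation, 6L)
  centres0 <- (0:5) * 60
  # consecutive window edges abut exactly: upper edge of one is the lower
  # edge of the next
  expect_equal((centres0 + 30) %% 360, (c(centres0[-1], centres0[1]) - 30) %% 360)
  # 40% overlap: full coverage, and the doubly covered angular fraction
  # equals the excess coverage (n * fov - 360) / 360 = 2/3
  plan <- small_plan()
  n <- plan$snaps_per_rotation
  centres <- (0:(n - 1)) * 360 / n
  test_angles <- seq(0.25, 359.75, 0.5)
  cover_count <- vapply(test_angles, function(a) {
    d <- abs(((a - centres + 180) %% 360) - 180)
    sum(d <= plan$fov_deg / 2)
  }, numeric(1))
  expect_true(all(cover_count >= 1))
  expect_equal(mean(cover_count >= 2), (n * plan$fov_deg - 360) / 360,
               tolerance = 0.01)
})
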