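# Pairwise registration, strip assembly and panorama stacking.

test_that("register_pair recovers a constructed shift exactly", {
  set.seed(41)
  big <- matrix(runif(80 * 120), 80, 120)
  a <- big[6:65, 1:70]
  for (true_shift in list(c(40, 3), c(38, -2), c(41, 0))) {
    b <- big[(6 + true_shift[2]):(65 + true_shift[2]),
             (1 + true_shift[1]):(70 + true_shift[1])]
    reg <- register_pair(a, b, prior_shift = c(40, 0), search_px = 3)
    expect_equal(reg$shift, true_shift)
    expect_gt(reg$score, 0.99)
  }
})

test_that("register_pair respects search radius and flat overlaps", {
  set.seed(42)
  a <- matrix(runif(50 * 60), 50, 60)
  b <- a
  # zero search returns the prior verbatim
  reg0 <- register_pair(a, b, prior_shift = c(5, 1), search_px = 0)
  expect_equal(reg0$shift, c(5L, 1L))
  expect_false(reg0$refined)
  # flat overlap: prior with score zero and a warning
  flat_a <- matrix(0.5, 50, 60); flat_b <- matrix(0.5, 50, 60)
  expect_warning(regf <- register_pair(flat_a, flat_b, c(30, 0), 2), "Flat")
  expect_equal(regf$shift, c(30L, 0L))
  expect_equal(regf$score, 0)
})

test_that("refined shifts equal the geometric prior on clean renders", {
  cropped <- crop_usable(small_snaps(), guard_px = 6)
  strip <- cropped[cropped$strip_idx == 1, ]
  crop_w <- strip$crop_w[1]
  n <- nrow(strip)
  for (j in seq_len(n)) {
    reg <- register_pair(strip$pixels[[j]], strip$pixels[[(j %% n) + 1]],
                         prior_shift = c(crop_w, 0), search_px = 2)
    expect_equal(reg$shift, c(crop_w, 0L))
  }
})

test_that("a clean strip stitches into the ground-truth band", {
  scene <- small_scene(); plan <- small_plan(); cam <- small_camera()
  cropped <- crop_usable(small_snaps(), guard_px = 0)
  strip <- stitch_strip(cropped[cropped$strip_idx == 0, ], search_px = 0)
  expect_equal(ncol(luminance(strip$pixels)),
               plan$snaps_per_rotation * strip$crop_w)
  expect_equal(strip$closure_residual_px, 0)
  gt <- panorama_ground_truth(scene, plan, cam,
                              dim(luminance(strip$pixels)), n_strips = 1)
  expect_gte(ncc(strip$pixels, gt), 0.995)
})

test_that("single snaps and broken strips are handled explicitly", {
  plan0 <- acquisition_plan(angular_overlap_frac = 0, fov_deg = 180,
                            tube_len_mm = 28, step_mm = 28)
  # a one-snap strip is returned as-is
  scene <- small_scene()
  cam0 <- camera_for_scene(scene, plan0)
  snaps0 <- acquire(scene, plan0, cam0, seed = 2)
  one <- crop_usable(snaps0[snaps0$angle_idx == 0, ], plan = plan0,
                     camera = cam0)
  one$angle_idx <- 0L
  st <- stitch_strip(one[1, ], search_px = 0)
  expect_images_equal(st$pixels, one$pixels[[1]])
  # a missing angle_idx is reported by index
  cropped <- crop_usable(small_snaps(), guard_px = 0)
  strip <- cropped[cropped$strip_idx == 0, ]
  broken <- strip[strip$angle_idx != 4, ]
  expect_error(stitch_strip(broken), "missing angle_idx \\{4\\}")
  # an empty list of strips cannot be stacked
  expect_error(stitch_panorama(list()), "Empty")
})

test_that("strip width is conserved regardless of refinement", {
  scene <- small_scene(); plan <- small_plan()
  cam <- camera_for_scene(scene, plan, noise_sd = 4 / 255,
                          exposure_jitter_sd = 0.05)
  snaps <- acquire(scene, plan, cam, seed = 31)
  cropped <- crop_usable(snaps, plan = plan, camera = cam, guard_px = 6)
  for (search in c(0, 2)) {
    strip <- stitch_strip(cropped[cropped$strip_idx == 0, ],
                          search_px = search)
    expect_equal(ncol(luminance(strip$pixels)),
                 plan$snaps_per_rotation * strip$crop_w)
  }
})

test_that("stitching is deterministic", {
  cropped <- crop_usable(small_snaps(), guard_px = 6)
  strips1 <- lapply(split(cropped, cropped$strip_idx), stitch_strip)
  strips2 <- lapply(split(cropped, cropped$strip_idx), stitch_strip)
  p1 <- stitch_panorama(strips1)
  p2 <- stitch_panorama(strips2)
  expect_identical(p1$pixels, p2$pixels)
  expect_identical(p1$provenance, p2$provenance)
})

test_that("a clean 3-strip panorama reproduces the scene", {
  scene <- small_scene(); plan <- small_plan(); cam <- small_camera()
  cropped <- crop_usable(small_snaps(), guard_px = 6)
  strips <- lapply(split(cropped, cropped$strip_idx), stitch_strip)
  pano <- stitch_panorama(strips, plan = plan)
  d <- dim(luminance(pano$pixels))
  expect_equal(d[1], plan$n_strips * strips[[1]]$crop_h)
  gt <- panorama_ground_truth(scene, plan, cam, d, pano$n_strips)
  expect_gte(ncc(pano$pixels, gt), 0.99)
  expect_equal(pano$mm_per_px, plan$step_mm / strips[[1]]$crop_h)
})

test_that("round-trip quality degrades monotonically with sensor noise", {
  scene <- small_scene(); plan <- small_plan()
  noise_levels <- c(0, 0.02, 0.06, 0.15)
  sims <- vapply(noise_levels, function(ns) {
    cam <- camera_for_scene(scene, plan, noise_sd = ns)
    snaps <- acquire(scene, plan, cam, seed = 55)
    cropped <- crop_usable(snaps, plan = plan, camera = cam, guard_px = 0)
    strips <- lapply(split(cropped, cropped$strip_idx), stitch_strip,
                     search_px = 0)
    pano <- stitch_panorama(strips, search_px = 0, plan = plan)
    gt <- panorama_ground_truth(scene, plan, cam,
                                dim(luminance(pano$pixels)), pano$n_strips)
    ncc(pano$pixels, gt)
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
})
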