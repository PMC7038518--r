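# Scan-geometry and power-budget arithmetic.

test_that("snaps_per_rotation covers a rotation with the requested overlap", {
  cases <- list(
    list(fov = 60, ov = 0.4, want = 10L),
    list(fov = 60, ov = 0.0, want = 6L),
    list(fov = 90, ov = 0.5, want = 8L)
  )
  for (cs in cases) {
    expect_identical(snaps_per_rotation(cs$fov, cs$ov), cs$want)
  }
  expect_error(snaps_per_rotation(0, 0.4), "fov")
  expect_error(snaps_per_rotation(60, 1), "overlap")
  expect_error(snaps_per_rotation(-10, 0.2), "fov")
})

test_that("snap count is monotone in FOV and overlap, and overlap is realized", {
  fovs <- c(20, 35, 60, 90, 120, 180)
  for (ov in c(0, 0.2, 0.4, 0.6)) {
    n <- vapply(fovs, snaps_per_rotation, integer(1), overlap_frac = ov)
    expect_true(all(diff(n) <= 0))  # wider lens, fewer snaps
  }
  for (fov in c(45, 60, 100)) {
    n <- vapply(c(0, 0.1, 0.25, 0.4, 0.6, 0.8), function(ov)
      snaps_per_rotation(fov, ov), integer(1))
    expect_true(all(diff(n) >= 0))  # more overlap, more snaps
  }
  # realized angular overlap always meets the request
  for (fov in c(45, 60, 100)) {
    for (ov in c(0, 0.2, 0.4, 0.55)) {
      n <- snaps_per_rotation(fov, ov)
      expect_gte(1 - 360 / (n * fov), ov - 1e-12)
    }
  }
})

test_that("strip counts and totals reproduce the reference scans", {
  expect_identical(strips_for_length(1000, 15), 66L)
  expect_identical(strips_for_length(15, 15), 1L)
  expect_identical(strips_for_length(320, 15), 21L)
  expect_identical(total_images(66L, 10L), 660L)
  expect_identical(total_images(21L, 11L), 231L)
  expect_identical(total_images(0L, 10L), 0L)
  plan <- acquisition_plan()
  expect_identical(total_images(plan), 660L)
  expect_identical(plan$snaps_per_rotation, 10L)
  expect_identical(plan$n_strips, 66L)
})

test_that("manual coverage arithmetic matches frame/circumference geometry", {
  got <- manual_coverage(34, 24, 63.5, 1000, vertical_count_override = 40)
  expect_identical(got$angular_count, 6L)  # ceil(pi * 63.5 / 34) = ceil(5.87)
  expect_identical(got$vertical_count, 40L)
  expect_identical(got$total, 240L)
  # circumference exactly one frame wide
  one <- manual_coverage(pi * 63.5, 24, 63.5, 1000)
  expect_identical(one$angular_count, 1L)
  # derived vertical count rounds tube_len / frame_h
  expect_identical(manual_coverage(34, 24, 63.5, 1000)$vertical_count, 42L)
  # a 20 s/positioning manual session for 464 pictures takes ~2.6 h
  expect_equal(manual_session_time(464, 20), 9280)
})

test_that("strip overlap fraction follows step and frame height", {
  expect_equal(strip_overlap_fraction(28, 15), 13 / 28)
  expect_equal(round(strip_overlap_fraction(28, 15), 4), 0.4643)
  expect_gte(strip_overlap_fraction(28, 15), 0.4)  # design target
  expect_equal(strip_overlap_fraction(28, 28), 0)
  expect_equal(strip_overlap_fraction(28, 14), 0.5)
})

test_that("per-cycle energy sums component loads exactly", {
  loads <- prototype_loads()
  per_comp <- loads$power_w * loads$active_s / 3600
  expect_equal(per_comp, c(0.726, 1.65, 0.275, 0.242, 3.5), tolerance = 1e-12)
  expect_equal(energy_per_cycle(loads), 6.393, tolerance = 1e-9)
  expect_equal(energy_per_cycle(loads[0, ]), 0)
  expect_equal(energy_per_cycle(component_loads("x", 1, 3600)), 1)
  expect_equal(peak_power(loads), 14.6)
})

test_that("battery and panel sizing follow the budget chain", {
  expect_equal(daily_energy(6.393, 12), 76.716)
  expect_equal(daily_energy(6.393, 12, paper_rounding = TRUE), 77)
  expect_equal(system_daily_energy(77, 0.8), 96.25)
  expect_equal(battery_wh(96.25, 2, 0.8), 240.625)
  expect_equal(battery_wh(96.25, 2, 0.8, paper_rounding = TRUE), 241)
  expect_equal(battery_ah(241, 12, "nearest"), 20)
  expect_equal(panel_w(241, 0.75, 8, paper_rounding = TRUE), 40)
  # minimum-capacity contract with ceiling rounding
  for (wh in c(241, 96.25, 517.3)) {
    for (v in c(6, 12, 24)) {
      expect_gte(battery_ah(wh, v, "ceiling") * v, wh)
    }
  }
  expect_error(battery_wh(96, 2, 1.2), "dod")
  expect_error(system_daily_energy(77, 0), "conversion_eff")
})

test_that("the full budget object reproduces the quoted sizing figures", {
  b <- energy_budget(paper_rounding = TRUE, n_transfer_images = 660)
  g <- glance(b)
  expect_equal(g$per_cycle_wh, 6.393, tolerance = 1e-9)
  expect_equal(g$daily_wh, 77)
  expect_equal(g$battery_wh, 241)
  expect_equal(g$battery_ah, 20)
  expect_equal(g$panel_w, 40)
  expect_equal(g$peak_w, 14.6)
  expect_equal(g$transfer_s, 600)      # 10 minutes
  # exact mode keeps full precision
  ex <- glance(energy_budget())
  expect_equal(ex$daily_wh, 76.716)
  expect_equal(ex$battery_wh, 76.716 / 0.8 * 2 / 0.8)
  td <- tidy(b)
  expect_equal(sum(td$energy_wh), 6.393, tolerance = 1e-9)
})

test_that("transfer time rounds payload to whole megabytes first", {
  expect_equal(transfer_time(310, 660, 3, 0.1), 205 * 8 * 1.1 / 3)
  expect_equal(round(transfer_time(310, 660, 3, 0.1), 1), 601.3)
  expect_equal(transfer_time(310, 660, 3, 0.1, paper_rounding = TRUE), 600)
  expect_equal(transfer_time(1000, 1, 8, 0), 1)
  expect_equal(round(transfer_time(310, 100, 3, 0.1), 1), 90.9)
})

test_that("acquisition time scales with strips and steps", {
  plan <- acquisition_plan()
  t_full <- acquisition_time(plan, s_per_strip = 3.5, s_per_step = 2.9)
  expect_equal(t_full, 66 * 3.5 + 65 * 2.9)
  expect_lt(abs(t_full - 420), 10)    # about seven minutes for a full tube
  one <- acquisition_plan(tube_len_mm = 15, step_mm = 15)
  expect_equal(acquisition_time(one, s_per_strip = 3.5), 3.5)
})

test_that("plan construction rejects inconsistent geometry", {
  expect_error(acquisition_plan(step_mm = 30, frame_h_mm = 28), "step_mm")
  p <- acquisition_plan()
  expect_gte(p$snaps_per_rotation, ceiling(360 / p$fov_deg))
  expect_lte(p$n_strips * p$step_mm, p$tube_len_mm + p$step_mm)
  g <- glance(p)
  expect_identical(g$total_images, 660L)
  expect_equal(nrow(tidy(p)), 11)
})
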