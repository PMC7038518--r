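# Shared fixtures, built once per test run and memoized. Sizes are kept
# small (a few strips of a short tube) so the whole suite runs in seconds.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(build), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A 3-strip test plan on the standard 63.5 mm tube.
small_plan <- function() {
  fixture("small_plan", acquisition_plan(tube_len_mm = 3 * 15, step_mm = 15))
}

small_scene <- function() {
  fixture("small_scene",
          tube_scene(tube_len_mm = 3 * 15 + 28 + 5, seed = 101))
}

small_camera <- function() {
  fixture("small_camera", camera_for_scene(small_scene(), small_plan()))
}

# Clean acquisition: no degradations at all.
small_snaps <- function() {
  fixture("small_snaps",
          acquire(small_scene(), small_plan(), small_camera(), seed = 7))
}

# The 5-strip scene used by the end-to-end round-trip checks.
e2e_plan <- function() {
  fixture("e2e_plan", acquisition_plan(tube_len_mm = 5 * 15, step_mm = 15))
}

e2e_scene <- function() {
  fixture("e2e_scene", tube_scene(tube_len_mm = 5 * 15 + 28 + 5, seed = 11))
}

# A deterministic mid-strength barrel profile for warp tests.
test_profile <- function(w = 100, h = 84) {
  distortion_profile(k = c(-0.08, 0.01, 0), cx = (w + 1) / 2, cy = (h + 1) / 2,
                     r_norm = sqrt(w^2 + h^2) / 2)
}

expect_images_equal <- function(a, b, tol = 0) {
  expect_equal(dim(a), dim(b))
  expect_lte(max(abs(a - b)), tol)
}
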