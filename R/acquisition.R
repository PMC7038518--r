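# Scan-geometry planning and power-budget arithmetic for an automated
# in-tube rotating camera. All operations are closed form; the
# `paper_rounding` flags reproduce the integer bookkeeping a field engineer
# would write down (whole Wh, whole Ah, whole minutes).

check_fraction <- function(x, name, open_top = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 &&
    (if (open_top) x < 1 else x <= 1)
  if (!ok) abort(sprintf("`%s` must be a fraction in (0, 1%s].", name,
                         if (open_top) ")" else ""))
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

#' Snaps needed per 360-degree rotation
#'
#' Number of equally spaced snapshots required to cover a full rotation with
#' a lens of the given field of view and a requested angular overlap between
#' adjacent snaps: `ceil(360 / (fov * (1 - overlap)))`. A 60 degree lens needs
#' 6 snaps with no overlap and 10 snaps at 40% overlap.
#'
#' @param fov_deg Horizontal field of view of the lens, degrees, in (0, 180].
#' @param overlap_frac Requested angular overlap between adjacent snaps,
#'   fraction in `[0, 1)`.
#' @return Integer snap count.
#' @export
snaps_per_rotation <- function(fov_deg, overlap_frac) {
  if (!is.numeric(fov_deg) || fov_deg <= 0 || fov_deg > 180) {
    abort("`fov_deg` must be in (0, 180].")
  }
  if (!is.numeric(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1) {
    abort("`overlap_frac` must be in [0, 1).")
  }
  as.integer(ceiling(360 / (fov_deg * (1 - overlap_frac))))
}

#' Number of 360-degree strips along the tube
#'
#' @param tube_len_mm Imaged tube length, mm.
#' @param step_mm Vertical step between strips, mm.
#' @return Integer strip count, `floor(tube_len_mm / step_mm)`.
#' @export
strips_for_length <- function(tube_len_mm, step_mm) {
  check_positive(tube_len_mm, "tube_len_mm")
  check_positive(step_mm, "step_mm")
  as.integer(floor(tube_len_mm / step_mm))
}

#' Overlap fraction between consecutive strips
#'
#' Vertical overlap implied by stepping `step_mm` between snaps whose
#' footprint is `frame_h_mm` tall: `(frame_h_mm - step_mm) / frame_h_mm`.
#'
#' @param frame_h_mm Vertical footprint of one snap on the tube wall, mm.
#' @param step_mm Vertical step between strips, mm.
#' @return Overlap fraction.
#' @export
strip_overlap_fraction <- function(frame_h_mm, step_mm) {
  check_positive(frame_h_mm, "frame_h_mm")
  check_positive(step_mm, "step_mm")
  (frame_h_mm - step_mm) / frame_h_mm
}

#' Build an acquisition plan
#'
#' Collects the scan geometry of one full tube acquisition and derives snap
#' and strip counts. Defaults are the prototype configuration: 60 degree
#' lens, 40% angular overlap, 35 x 28 mm snap footprint, 63.5 mm ID tube,
#' 1000 mm imaged length, 15 mm vertical step.
#'
#' @param fov_deg Lens field of view, degrees.
#' @param angular_overlap_frac Requested angular overlap fraction in `[0, 1)`.
#' @param frame_w_mm,frame_h_mm Footprint of one snap on the tube wall, mm.
#' @param tube_id_mm Tube inner diameter, mm.
#' @param tube_len_mm Imaged tube length, mm.
#' @param step_mm Vertical step between strips, mm (must not exceed
#'   `frame_h_mm`, or strips would not overlap vertically).
#' @return An `acquisition_plan` object: the inputs plus
#'   `snaps_per_rotation`, `n_strips`, `total_images`,
#'   `strip_overlap_frac` and the realized angular overlap.
#' @export
acquisition_plan <- function(fov_deg = 60, angular_overlap_frac = 0.4,
                             frame_w_mm = 35, frame_h_mm = 28,
                             tube_id_mm = 63.5, tube_len_mm = 1000,
                             step_mm = 15) {
  n_ang <- snaps_per_rotation(fov_deg, angular_overlap_frac)
  check_positive(c(frame_w_mm, frame_h_mm, tube_id_mm, tube_len_mm),
                 "frame/tube dimensions")
  if (step_mm > frame_h_mm) {
    abort("`step_mm` must not exceed `frame_h_mm` (strips must overlap or abut).")
  }
  n_strips <- strips_for_length(tube_len_mm, step_mm)
  plan <- structure(list(
    fov_deg = fov_deg,
    angular_overlap_frac = angular_overlap_frac,
    frame_w_mm = frame_w_mm,
    frame_h_mm = frame_h_mm,
    tube_id_mm = tube_id_mm,
    tube_len_mm = tube_len_mm,
    step_mm = step_mm,
    snaps_per_rotation = n_ang,
    n_strips = n_strips,
    strip_overlap_frac = strip_overlap_fraction(frame_h_mm, step_mm),
    realized_angular_overlap = 1 - 360 / (n_ang * fov_deg)
  ), class = "acquisition_plan")
  stopifnot(n_ang >= ceiling(360 / fov_deg),
            n_strips * step_mm <= tube_len_mm + step_mm)
  plan
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf(
    "<acquisition_plan> %g deg FOV, %.0f%% overlap: %d snaps/rotation\n",
    x$fov_deg, 100 * x$angular_overlap_frac, x$snaps_per_rotation
  ))
  cat(sprintf(
    "  tube %g mm ID x %g mm; step %g mm -> %d strips, %d images\n",
    x$tube_id_mm, x$tube_len_mm, x$step_mm, x$n_strips, total_images(x)
  ))
  cat(sprintf("  strip overlap %.1f%%, realized angular overlap %.1f%%\n",
              100 * x$strip_overlap_frac, 100 * x$realized_angular_overlap))
  invisible(x)
}

#' Total images in a scan
#'
#' @param plan An [acquisition_plan()], or a strip count.
#' @param snaps_per_rotation Snap count per strip when `plan` is a number.
#' @return `n_strips * snaps_per_rotation`.
#' @export
total_images <- function(plan, snaps_per_rotation = NULL) {
  if (inherits(plan, "acquisition_plan")) {
    return(as.integer(plan$n_strips * plan$snaps_per_rotation))
  }
  if (is.null(snaps_per_rotation)) {
    abort("Provide an acquisition_plan or both counts.")
  }
  if (plan < 0 || snaps_per_rotation < 0) abort("Counts must be non-negative.")
  as.integer(plan * snaps_per_rotation)
}

#' @export
tidy.acquisition_plan <- function(x, ...) {
  tibble::tibble(field = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}

#' @export
glance.acquisition_plan <- function(x, ...) {
  tibble::tibble(
    snaps_per_rotation = x$snaps_per_rotation,
    n_strips = x$n_strips,
    total_images = total_images(x),
    strip_overlap_frac = x$strip_overlap_frac,
    realized_angular_overlap = x$realized_angular_overlap
  )
}

#' Manual full-coverage picture count
#'
#' How many non-overlapping pictures a human operator needs for full
#' 360-degree coverage of a tube: the angular count is the minimum number of
#' frames of width `frame_w_mm` covering the circumference
#' (`ceil(pi * tube_id_mm / frame_w_mm)`); the vertical count is
#' `round(tube_len_mm / frame_h_mm)` unless overridden. Explicit overrides
#' exist because published session protocols sometimes fix the vertical
#' position count by convention rather than by frame arithmetic.
#'
#' @param frame_w_mm,frame_h_mm Picture footprint on the tube wall, mm.
#' @param tube_id_mm Tube inner diameter, mm.
#' @param tube_len_mm Tube length, mm.
#' @param vertical_count_override,angular_count_override Optional explicit
#'   counts replacing the derived ones.
#' @return A one-row tibble with `angular_count`, `vertical_count`, `total`.
#' @export
manual_coverage <- function(frame_w_mm, frame_h_mm, tube_id_mm, tube_len_mm,
                            vertical_count_override = NULL,
                            angular_count_override = NULL) {
  check_positive(c(frame_w_mm, frame_h_mm, tube_id_mm, tube_len_mm),
                 "dimensions")
  angular <- if (!is.null(angular_count_override)) {
    as.integer(angular_count_override)
  } else {
    as.integer(ceiling(pi * tube_id_mm / frame_w_mm))
  }
  vertical <- if (!is.null(vertical_count_override)) {
    as.integer(vertical_count_override)
  } else {
    as.integer(round(tube_len_mm / frame_h_mm))
  }
  tibble::tibble(angular_count = angular, vertical_count = vertical,
                 total = angular * vertical)
}

#' Time for a manual imaging session
#'
#' @param n_pictures Number of pictures (positionings).
#' @param s_per_position Seconds per manual positioning (default 20 s for an
#'   experienced operator).
#' @return Total seconds.
#' @export
manual_session_time <- function(n_pictures, s_per_position = 20) {
  check_positive(s_per_position, "s_per_position")
  n_pictures * s_per_position
}

#' Automated acquisition time for a full tube
#'
#' `n_strips * s_per_strip + (n_strips - 1) * s_per_step`. Defaults (3.5 s
#' per rotation, 2.9 s per vertical step) reflect the prototype locomotive:
#' a rotation takes 3-4 s and a full 1000 mm tube roughly seven minutes.
#'
#' @param plan An [acquisition_plan()].
#' @param s_per_strip Seconds for one full rotation of snaps.
#' @param s_per_step Seconds for one vertical repositioning.
#' @return Total seconds.
#' @export
acquisition_time <- function(plan, s_per_strip = 3.5, s_per_step = 2.9) {
  n <- plan$n_strips
  if (n < 1) abort("Plan has no strips.")
  n * s_per_strip + (n - 1) * s_per_step
}

# ---- Energy ----------------------------------------------------------------

#' Component power loads of the reference prototype
#'
#' Measured average power, active seconds per imaging cycle, and peak power
#' for the five loads of the prototype tube imager (camera, vertical-travel
#' motor, rotation motor, LED light source, controller with single-board
#' computer). The controller's average draw (1.75 W) is below its 5 W peak.
#'
#' @return A `component_loads` tibble with columns `name`, `power_w`,
#'   `active_s`, `peak_w`.
#' @export
prototype_loads <- function() {
  component_loads(
    name = c("camera", "motor_travel", "motor_rotation", "light_source",
             "controller_sbc"),
    power_w = c(1.2, 3, 5, 0.4, 1.75),
    active_s = c(2178, 1980, 198, 2178, 7200),
    peak_w = c(1.2, 3, 5, 0.4, 5)
  )
}

#' Build a component load table
#'
#' @param name Component labels.
#' @param power_w Average active power, W.
#' @param active_s Active seconds per imaging cycle.
#' @param peak_w Peak power, W (defaults to `power_w`; may exceed it for
#'   bursty loads).
#' @return A `component_loads` tibble.
#' @export
component_loads <- function(name, power_w, active_s, peak_w = power_w) {
  if (any(power_w < 0) || any(active_s < 0) || any(peak_w < 0)) {
    abort("Powers and active times must be non-negative.")
  }
  out <- tibble::tibble(name = as.character(name), power_w = power_w,
                        active_s = active_s, peak_w = peak_w)
  class(out) <- c("component_loads", class(out))
  out
}

#' Energy used per imaging cycle
#'
#' @param components A [component_loads()] tibble (or any data frame with
#'   `power_w` and `active_s` columns).
#' @return Watt-hours per cycle, `sum(power_w * active_s) / 3600`.
#' @export
energy_per_cycle <- function(components) {
  if (nrow(components) == 0) return(0)
  sum(components$power_w * components$active_s) / 3600
}

#' Peak system power
#'
#' @param components A [component_loads()] tibble.
#' @return Sum of component peak powers, W.
#' @export
peak_power <- function(components) sum(components$peak_w)

#' Daily energy requirement
#'
#' @param per_cycle_wh Energy per imaging cycle, Wh.
#' @param images_per_day Imaging cycles per day.
#' @param paper_rounding Round the result to a whole Wh, as a field budget
#'   sheet would.
#' @return Wh per day.
#' @export
daily_energy <- function(per_cycle_wh, images_per_day, paper_rounding = FALSE) {
  check_positive(per_cycle_wh, "per_cycle_wh")
  check_positive(images_per_day, "images_per_day")
  x <- per_cycle_wh * images_per_day
  if (paper_rounding) round(x) else x
}

#' Daily energy at the system input, after conversion losses
#'
#' @param daily_wh Load-side daily energy, Wh.
#' @param conversion_eff Power-conversion efficiency, fraction in (0, 1].
#' @return Wh per day drawn from the supply.
#' @export
system_daily_energy <- function(daily_wh, conversion_eff) {
  check_positive(daily_wh, "daily_wh")
  check_fraction(conversion_eff, "conversion_eff")
  daily_wh / conversion_eff
}

#' Battery capacity for a given autonomy
#'
#' `daily_wh * days_autonomy / dod`.
#'
#' @param system_daily_wh Supply-side daily energy, Wh.
#' @param days_autonomy Days the system must run without charging.
#' @param dod Permitted battery depth of discharge, fraction in (0, 1].
#' @param paper_rounding Round to a whole Wh.
#' @return Battery capacity, Wh.
#' @export
battery_wh <- function(system_daily_wh, days_autonomy, dod,
                       paper_rounding = FALSE) {
  check_positive(system_daily_wh, "system_daily_wh")
  check_positive(days_autonomy, "days_autonomy")
  check_fraction(dod, "dod")
  x <- system_daily_wh * days_autonomy / dod
  if (paper_rounding) round(x) else x
}

#' Battery capacity in amp-hours
#'
#' @param battery_wh Battery capacity, Wh.
#' @param battery_v Battery voltage, V.
#' @param rounding `"none"` (exact), `"nearest"` (whole Ah, budget-sheet
#'   style) or `"ceiling"` (smallest whole Ah whose energy meets or exceeds
#'   the requested Wh).
#' @return Capacity, Ah.
#' @export
battery_ah <- function(battery_wh, battery_v,
                       rounding = c("none", "nearest", "ceiling")) {
  check_positive(battery_wh, "battery_wh")
  check_positive(battery_v, "battery_v")
  rounding <- match.arg(rounding)
  x <- battery_wh / battery_v
  switch(rounding, none = x, nearest = round(x), ceiling = ceiling(x))
}

#' Solar panel capacity
#'
#' `battery_wh / (charge_eff * charge_h)`.
#'
#' @param battery_wh Battery capacity to recharge, Wh.
#' @param charge_eff Total charging efficiency, fraction in (0, 1].
#' @param charge_h Daily charging hours.
#' @param paper_rounding Round to a whole W.
#' @return Panel capacity, W.
#' @export
panel_w <- function(battery_wh, charge_eff, charge_h, paper_rounding = FALSE) {
  check_positive(battery_wh, "battery_wh")
  check_fraction(charge_eff, "charge_eff")
  check_positive(charge_h, "charge_h")
  x <- battery_wh / (charge_eff * charge_h)
  if (paper_rounding) round(x) else x
}

#' Wireless transfer time for a scan
#'
#' Total payload is first rounded to whole megabytes
#' (`round(n_images * kb_per_image / 1000)`), then
#' `seconds = MB * 8 * (1 + overhead_frac) / link_mbps`.
#'
#' @param kb_per_image Average image file size, kB.
#' @param n_images Number of images.
#' @param link_mbps Link data rate, Mbit/s.
#' @param overhead_frac Protocol overhead as a fraction of payload.
#' @param paper_rounding Round the result to the nearest whole minute
#'   (returned in seconds).
#' @return Transfer time in seconds.
#' @export
transfer_time <- function(kb_per_image, n_images, link_mbps,
                          overhead_frac = 0.1, paper_rounding = FALSE) {
  check_positive(c(kb_per_image, n_images, link_mbps), "transfer parameters")
  if (overhead_frac < 0) abort("`overhead_frac` must be non-negative.")
  mb <- round(n_images * kb_per_image / 1000)
  s <- mb * 8 * (1 + overhead_frac) / link_mbps
  if (paper_rounding) round(s / 60) * 60 else s
}

#' Size the full power system for an imaging schedule
#'
#' Chains [energy_per_cycle()] through [panel_w()] for one configuration.
#' With `paper_rounding = TRUE` intermediate daily energy is rounded to a
#' whole Wh before conversion-loss scaling (the supply-side value itself is
#' carried unrounded into battery sizing), and final battery/panel figures
#' are rounded to whole units - reproducing how such budgets are quoted.
#'
#' @param components A [component_loads()] tibble.
#' @param images_per_day Imaging cycles per day.
#' @param conversion_eff System power-conversion efficiency.
#' @param days_autonomy Days of battery autonomy.
#' @param dod Battery depth of discharge.
#' @param battery_v Battery voltage, V.
#' @param charge_eff Solar charging efficiency.
#' @param charge_h Daily charging hours.
#' @param kb_per_image,n_transfer_images,link_mbps,overhead_frac Transfer
#'   scenario (set `kb_per_image = NULL` to skip). One imaging cycle scans
#'   the whole tube, so the default transfer payload is the 660 snaps of a
#'   full 1000 mm scan.
#' @param paper_rounding Apply budget-sheet rounding throughout.
#' @return An `energy_budget` object.
#' @export
energy_budget <- function(components = prototype_loads(), images_per_day = 12,
                          conversion_eff = 0.8, days_autonomy = 2, dod = 0.8,
                          battery_v = 12, charge_eff = 0.75, charge_h = 8,
                          kb_per_image = 310, n_transfer_images = 660,
                          link_mbps = 3, overhead_frac = 0.1,
                          paper_rounding = FALSE) {
  per_cycle <- energy_per_cycle(components)
  daily <- daily_energy(per_cycle, images_per_day, paper_rounding)
  sys_daily <- system_daily_energy(daily, conversion_eff)
  batt_wh <- battery_wh(sys_daily, days_autonomy, dod, paper_rounding)
  batt_ah <- battery_ah(batt_wh, battery_v,
                        if (paper_rounding) "nearest" else "none")
  pan_w <- panel_w(batt_wh, charge_eff, charge_h, paper_rounding)
  transfer_s <- if (!is.null(kb_per_image)) {
    transfer_time(kb_per_image, n_transfer_images, link_mbps, overhead_frac,
                  paper_rounding)
  } else {
    NA_real_
  }
  structure(list(
    components = components,
    images_per_day = images_per_day,
    conversion_eff = conversion_eff,
    days_autonomy = days_autonomy,
    dod = dod,
    battery_v = battery_v,
    charge_eff = charge_eff,
    charge_h = charge_h,
    paper_rounding = paper_rounding,
    per_cycle_wh = per_cycle,
    daily_wh = daily,
    system_daily_wh = sys_daily,
    battery_wh = batt_wh,
    battery_ah = batt_ah,
    panel_w = pan_w,
    peak_w = peak_power(components),
    transfer_s = transfer_s
  ), class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf("<energy_budget>%s\n",
              if (x$paper_rounding) " (budget-sheet rounding)" else ""))
  cat(sprintf("  per cycle %.3f Wh x %g/day -> %.3g Wh/day (%.4g Wh at supply)\n",
              x$per_cycle_wh, x$images_per_day, x$daily_wh, x$system_daily_wh))
  cat(sprintf("  battery %.4g Wh = %.3g Ah @ %g V; panel %.3g W; peak %.3g W\n",
              x$battery_wh, x$battery_ah, x$battery_v, x$panel_w, x$peak_w))
  if (!is.na(x$transfer_s)) {
    cat(sprintf("  transfer %.4g s (%.3g min)\n", x$transfer_s, x$transfer_s / 60))
  }
  invisible(x)
}

#' @describeIn energy_budget Per-component energy table (Wh per cycle).
#' @param x An `energy_budget`.
#' @param ... Unused.
#' @export
tidy.energy_budget <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$components),
                energy_wh = .data$power_w * .data$active_s / 3600)
}

#' @describeIn energy_budget One-row summary of derived sizing figures.
#' @export
glance.energy_budget <- function(x, ...) {
  tibble::tibble(
    per_cycle_wh = x$per_cycle_wh, daily_wh = x$daily_wh,
    system_daily_wh = x$system_daily_wh, battery_wh = x$battery_wh,
    battery_ah = x$battery_ah, panel_w = x$panel_w, peak_w = x$peak_w,
    transfer_s = x$transfer_s
  )
}

#' @export
autoplot.energy_budget <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$name, .data$energy_wh),
                                  y = .data$energy_wh)) +
    ggplot2::geom_col(fill = "#5b8c5a") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Energy per imaging cycle (Wh)",
                  title = sprintf("Total %.3f Wh per cycle", object$per_cycle_wh)) +
    ggplot2::theme_minimal()
}
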