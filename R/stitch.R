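# Strip and panorama assembly. Camera positions are known from the
# locomotive to sub-pixel precision, so stitching is geometry-prior
# translational registration: each seam is refined by normalized
# cross-correlation within a small search window around the geometric
# prior, the 360-degree closure error is distributed uniformly across the
# seams, and overlapping guard margins are blended with linear feathering.

#' Refine the relative shift of two overlapping images
#'
#' Searches integer translations within `search_px` of the geometric prior
#' for the one maximizing the normalized cross-correlation of the overlap.
#' Ties are broken towards the prior (then row-major), so the result is
#' deterministic.
#'
#' Because the mechanical prior is accurate to a fraction of a pixel, a
#' refined shift is only accepted when the overlap is informative: its
#' correlation must reach `min_score` and beat the prior's by `margin`;
#' otherwise the prior is kept.
#'
#' @param a,b Images; `b`'s top-left corner sits at offset
#'   `shift = c(dx, dy)` (columns, rows; 0-based) from `a`'s top-left.
#' @param prior_shift Geometric prior `c(dx, dy)`.
#' @param search_px Search radius around the prior; `0` returns the prior.
#' @param min_score Minimum NCC for a refined shift to be trusted.
#' @param margin How much a refined shift must beat the prior's score by.
#' @param mask_a,mask_b Optional logical matrices flagging unreliable pixels
#'   (e.g. inpainted reflection fills); flagged pixels are excluded from the
#'   correlation so fabricated texture cannot steer the shift.
#' @return List with `shift` (c(dx, dy)), `score` (NCC in the overlap) and
#'   `refined` (logical).
#' @export
register_pair <- function(a, b, prior_shift, search_px = 2L,
                          min_score = 0.5, margin = 0.02,
                          mask_a = NULL, mask_b = NULL) {
  a <- as_image(a, "a"); b <- as_image(b, "b")
  prior_shift <- as.integer(round(prior_shift))
  la <- luminance(a); lb <- luminance(b)
  ov <- overlap_ncc(la, lb, prior_shift[1], prior_shift[2], mask_a, mask_b)
  if (search_px <= 0) {
    return(list(shift = prior_shift, score = if (is.finite(ov)) ov else 0,
                refined = FALSE))
  }
  if (is.finite(ov) && ov == 0 && flat_overlap(la, lb, prior_shift)) {
    warn("Flat (zero-variance) overlap; returning the geometric prior.")
    return(list(shift = prior_shift, score = 0, refined = FALSE))
  }
  best <- prior_shift; best_score <- -Inf; best_dist <- Inf
  for (dy in -search_px:search_px) {
    for (dx in -search_px:search_px) {
      s <- prior_shift + c(dx, dy)
      sc <- overlap_ncc(la, lb, s[1], s[2], mask_a, mask_b)
      if (!is.finite(sc)) next
      d <- abs(dx) + abs(dy)
      if (sc > best_score + 1e-12 ||
          (abs(sc - best_score) <= 1e-12 && d < best_dist)) {
        best <- s; best_score <- sc; best_dist <- d
      }
    }
  }
  if (!is.finite(best_score)) {
    warn("No overlap within the search window; returning the prior.")
    return(list(shift = prior_shift, score = 0, refined = FALSE))
  }
  if (best_score == 0 && flat_overlap(la, lb, best)) {
    warn("Flat (zero-variance) overlap; returning the geometric prior.")
    return(list(shift = prior_shift, score = 0, refined = FALSE))
  }
  prior_score <- if (is.finite(ov)) ov else 0
  if (!identical(best, prior_shift) &&
      (best_score < min_score || best_score < prior_score + margin)) {
    return(list(shift = prior_shift, score = prior_score, refined = FALSE))
  }
  list(shift = best, score = best_score, refined = TRUE)
}

# Remove a least-squares plane from a patch. Correlating detrended patches
# makes the peak robust to smooth shading (vignetting residues, inpainted
# fills) that would otherwise bias it, without the boundary artifacts a
# high-pass filter would add on narrow overlap bands.
detrend_plane <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h * w < 6L) return(m - mean(m))
  x <- rep(seq_len(w), each = h); y <- rep(seq_len(h), times = w)
  matrix(stats::lm.fit(cbind(1, x, y), as.vector(m))$residuals, h, w)
}

overlap_region <- function(la, lb, dx, dy) {
  ha <- nrow(la); wa <- ncol(la); hb <- nrow(lb); wb <- ncol(lb)
  r0 <- max(1L, dy + 1L); r1 <- min(ha, dy + hb)
  c0 <- max(1L, dx + 1L); c1 <- min(wa, dx + wb)
  if (r0 > r1 || c0 > c1) return(NULL)
  list(a = la[r0:r1, c0:c1, drop = FALSE],
       b = lb[(r0:r1) - dy, (c0:c1) - dx, drop = FALSE])
}

overlap_ncc <- function(la, lb, dx, dy, ma = NULL, mb = NULL) {
  ov <- overlap_region(la, lb, dx, dy)
  if (is.null(ov) || length(ov$a) < 4L) return(-Inf)
  valid <- NULL
  if (!is.null(ma) || !is.null(mb)) {
    om <- overlap_region(
      if (is.null(ma)) matrix(FALSE, nrow(la), ncol(la)) else ma,
      if (is.null(mb)) matrix(FALSE, nrow(lb), ncol(lb)) else mb,
      dx, dy
    )
    valid <- !(om$a | om$b)
    if (sum(valid) < 12L) return(0)
  }
  a <- ov$a; b <- ov$b
  h <- nrow(a); w <- ncol(a)
  x <- rep(seq_len(w), each = h); y <- rep(seq_len(h), times = w)
  if (!is.null(valid)) {
    keep <- which(valid)
    A <- cbind(1, x[keep], y[keep])
    if (sd(a[keep]) == 0 || sd(b[keep]) == 0) return(0)
    ra <- stats::lm.fit(A, a[keep])$residuals
    rb <- stats::lm.fit(A, b[keep])$residuals
  } else {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    ra <- detrend_plane(a); rb <- detrend_plane(b)
  }
  if (sd(ra) == 0 || sd(rb) == 0) return(0)
  cor(as.vector(ra), as.vector(rb))
}

flat_overlap <- function(la, lb, shift) {
  ov <- overlap_region(la, lb, shift[1], shift[2])
  !is.null(ov) && (sd(ov$a) == 0 || sd(ov$b) == 0)
}

# Distribute an integer residual uniformly over n seams.
distribute_residual <- function(offsets, expected_total) {
  n <- length(offsets)
  resid <- sum(offsets) - expected_total
  if (resid == 0 || n == 0) return(offsets)
  base <- resid %/% n
  extra <- resid - base * n
  adj <- rep(base, n)
  if (extra > 0) adj[seq_len(extra)] <- adj[seq_len(extra)] + 1L
  offsets - adj
}

feather_profile <- function(len, guard) {
  if (guard <= 0) return(rep(1, len))
  ramp <- 2L * guard
  i <- seq_len(len)
  pmin((i - 0.5) / ramp, 1, (len - i + 0.5) / ramp)
}

#' Stitch one 360-degree strip
#'
#' Places the cropped snaps of one strip left-to-right at their refined
#' shifts, distributes the wraparound closure error uniformly across the
#' seams (so the output width is exactly `n * crop_w` regardless of
#' refinement) and feather-blends the overlapping guard margins.
#'
#' @param snaps Cropped snap rows of one strip (see [crop_usable()]); must
#'   contain every `angle_idx` from 0 to n-1 exactly once, single band.
#' @param search_px Seam refinement search radius; `0` trusts the geometric
#'   prior.
#' @return A `strip_panorama`: list with `pixels`
#'   (`(crop_h + 2 guard_y) x (n crop_w)`), `strip_idx`, `depth_mm`,
#'   `px_per_deg`, `closure_residual_px`, `seam_scores` and the crop
#'   geometry.
#' @export
stitch_strip <- function(snaps, search_px = 2L) {
  if (nrow(snaps) == 0L) abort("Empty snap set.")
  if (length(unique(snaps$band_nm)) > 1L) {
    abort("Stitch one band at a time.")
  }
  n <- nrow(snaps)
  want <- 0:(n - 1)
  have <- sort(snaps$angle_idx)
  if (!identical(as.integer(have), as.integer(want))) {
    missing <- setdiff(want, snaps$angle_idx)
    dup <- unique(snaps$angle_idx[duplicated(snaps$angle_idx)])
    abort(sprintf(
      "Strip is not a complete rotation: missing angle_idx {%s}%s.",
      paste(missing, collapse = ", "),
      if (length(dup)) sprintf(", duplicated {%s}", paste(dup, collapse = ", "))
      else ""
    ))
  }
  snaps <- snaps[order(snaps$angle_idx), ]
  crop_w <- snaps$crop_w[1]
  crop_h <- snaps$crop_h[1]
  imgs <- snaps$pixels
  w_keep <- ncol(luminance(imgs[[1]]))
  h_keep <- nrow(luminance(imgs[[1]]))
  gx <- (w_keep - crop_w) %/% 2L
  gy <- (h_keep - crop_h) %/% 2L
  W <- n * crop_w

  if (n == 1L) {
    return(new_strip_panorama(imgs[[1]], snaps, W = w_keep, gx = gx, gy = gy,
                              closure = 0, seams = tibble::tibble()))
  }

  masks <- if ("mask" %in% names(snaps)) snaps$mask else
    rep(list(NULL), n)
  # seam j: offset of snap j relative to snap j-1 (snap n wraps to snap 0)
  offsets <- matrix(0L, n, 2L)
  scores <- numeric(n)
  for (j in seq_len(n)) {
    jb <- (j %% n) + 1L
    if (search_px > 0 && gx > 0) {
      reg <- register_pair(imgs[[j]], imgs[[jb]], prior_shift = c(crop_w, 0L),
                           search_px = search_px,
                           mask_a = masks[[j]], mask_b = masks[[jb]])
      offsets[j, ] <- reg$shift
      scores[j] <- reg$score
    } else {
      offsets[j, ] <- c(crop_w, 0L)
      scores[j] <- NA_real_
    }
  }
  closure_x <- sum(offsets[, 1]) - W
  closure_y <- sum(offsets[, 2])
  offsets[, 1] <- distribute_residual(offsets[, 1], W)
  offsets[, 2] <- distribute_residual(offsets[, 2], 0L)

  x <- c(0L, cumsum(offsets[seq_len(n - 1L), 1]))  - gx
  y <- c(0L, cumsum(offsets[seq_len(n - 1L), 2]))  - gy

  wx <- feather_profile(w_keep, gx)
  canvas <- compose_wrapped(imgs, x, y, W = W, H = h_keep,
                            wx = wx, wy = rep(1, h_keep), y_anchor = -gy)
  strip_mask <- NULL
  if (any(!vapply(masks, is.null, logical(1)))) {
    mask_imgs <- lapply(seq_len(n), function(j) {
      if (is.null(masks[[j]])) matrix(0, h_keep, w_keep)
      else masks[[j]] * 1
    })
    mfrac <- compose_wrapped(mask_imgs, x, y, W = W, H = h_keep,
                             wx = wx, wy = rep(1, h_keep), y_anchor = -gy)
    strip_mask <- mfrac > 0.2
  }
  out <- new_strip_panorama(canvas, snaps, W = W, gx = gx, gy = gy,
                            closure = closure_x,
                            seams = tibble::tibble(seam = seq_len(n),
                                                   dx = offsets[, 1],
                                                   dy = offsets[, 2],
                                                   score = scores),
                            closure_y = closure_y)
  out$mask <- strip_mask
  out
}

new_strip_panorama <- function(pixels, snaps, W, gx, gy, closure, seams,
                               closure_y = 0) {
  structure(list(
    pixels = pixels, strip_idx = snaps$strip_idx[1],
    depth_mm = snaps$depth_mm[1], px_per_deg = W / 360,
    closure_residual_px = closure, closure_residual_y_px = closure_y,
    seam_scores = seams, crop_w = snaps$crop_w[1], crop_h = snaps$crop_h[1],
    guard = c(gx, gy), band_nm = snaps$band_nm[1]
  ), class = "strip_panorama")
}

#' @export
print.strip_panorama <- function(x, ...) {
  d <- dim(luminance(x$pixels))
  cat(sprintf(
    "<strip_panorama> strip %s at %.0f mm: %d x %d px (%.3g px/deg), closure %+d px\n",
    x$strip_idx, x$depth_mm, d[1], d[2], x$px_per_deg,
    as.integer(x$closure_residual_px)
  ))
  invisible(x)
}

# Accumulate images onto a horizontally wrapped canvas with a horizontal
# feather profile, then normalize by total weight. Vertical feathering
# between strips is handled separately in compose_stacked().
compose_wrapped <- function(imgs, x, y, W, H, wx, wy, y_anchor = 0L) {
  nch <- n_channels(imgs[[1]])
  acc <- array(0, c(H, W, nch))
  wsum <- matrix(0, H, W)
  for (j in seq_along(imgs)) {
    img <- imgs[[j]]
    h <- nrow(luminance(img)); w <- ncol(luminance(img))
    cols <- ((x[j] + seq_len(w) - 1L) %% W) + 1L
    rows_canvas <- y[j] - y_anchor + seq_len(h)
    keep <- which(rows_canvas >= 1L & rows_canvas <= H)
    if (!length(keep)) next
    rr <- rows_canvas[keep]
    wgt <- outer(rep(1, length(keep)), wx)
    for (ch in seq_len(nch)) {
      band <- if (nch == 1L) img else img[, , ch]
      acc[rr, cols, ch] <- acc[rr, cols, ch] + band[keep, , drop = FALSE] * wgt
    }
    wsum[rr, cols] <- wsum[rr, cols] + wgt
  }
  wsum[wsum == 0] <- 1
  for (ch in seq_len(nch)) acc[, , ch] <- acc[, , ch] / wsum
  if (nch == 1L) acc[, , 1] else acc
}

#' Stitch strips into the full tube panorama
#'
#' Stacks strip panoramas by depth with vertical refinement registration in
#' the strip-overlap bands and a per-strip horizontal (angular) alignment
#' chained from the first strip; vertical guard margins are feather-blended.
#' The output height is exactly `n_strips * crop_h`.
#'
#' @param strips List of [stitch_strip()] results, in depth order.
#' @param search_px Refinement search radius (`0` trusts the geometry).
#' @param mm_per_px Vertical scale recorded in the result; defaults to
#'   `step_mm / crop_h` inferred from the strip spacing when `plan` given.
#' @param plan Optional [acquisition_plan()] used for the scale metadata.
#' @return A `tube_panorama`: list with `pixels`
#'   (`n_strips * crop_h x strip width`), `mm_per_px`, `tube_len_mm`,
#'   `px_per_deg`, per-strip alignment table and a provenance digest.
#' @export
stitch_panorama <- function(strips, search_px = 2L, mm_per_px = NULL,
                            plan = NULL) {
  if (length(strips) == 0L) abort("Empty strip list.")
  if (!all(vapply(strips, inherits, logical(1), "strip_panorama"))) {
    abort("`strips` must be a list of strip_panorama objects.")
  }
  ord <- order(vapply(strips, function(s) s$depth_mm, numeric(1)))
  strips <- strips[ord]
  n <- length(strips)
  W <- ncol(luminance(strips[[1]]$pixels))
  crop_h <- strips[[1]]$crop_h
  gy <- strips[[1]]$guard[2]
  H <- n * crop_h

  dx_chain <- integer(n)
  dy_off <- integer(n)   # deviation of strip i's top from nominal
  scores <- rep(NA_real_, n)
  if (n > 1L && search_px > 0 && gy > 0) {
    for (i in 2:n) {
      reg <- register_pair(strips[[i - 1]]$pixels, strips[[i]]$pixels,
                           prior_shift = c(0L, crop_h), search_px = search_px,
                           mask_a = strips[[i - 1]]$mask,
                           mask_b = strips[[i]]$mask)
      dx_chain[i] <- dx_chain[i - 1] + reg$shift[1]
      dy_off[i] <- dy_off[i - 1] + (reg$shift[2] - crop_h)
      scores[i] <- reg$score
    }
  }

  h_keep <- nrow(luminance(strips[[1]]$pixels))
  imgs <- lapply(strips, function(s) s$pixels)
  x <- dx_chain
  y <- (seq_len(n) - 1L) * crop_h + dy_off
  wy <- feather_profile(h_keep, gy)
  canvas <- compose_stacked(imgs, x, y, W = W, H = H, wy = wy, y_anchor = gy)

  step_mm <- if (n > 1L) strips[[2]]$depth_mm - strips[[1]]$depth_mm else
    if (!is.null(plan)) plan$step_mm else crop_h
  mmpp <- if (!is.null(mm_per_px)) mm_per_px else step_mm / crop_h
  structure(list(
    pixels = canvas,
    mm_per_px = mmpp,
    tube_len_mm = n * step_mm,
    px_per_deg = W / 360,
    n_strips = n,
    alignment = tibble::tibble(strip = seq_len(n) - 1L, dx = dx_chain,
                               dy = dy_off, score = scores),
    provenance = rlang::hash(list(
      lapply(strips, function(s) s$seam_scores), x, y, dim(canvas)
    ))
  ), class = "tube_panorama")
}

# Vertical stacking with horizontal wrap for the per-strip dx offsets.
compose_stacked <- function(imgs, x, y, W, H, wy, y_anchor = 0L) {
  nch <- n_channels(imgs[[1]])
  acc <- array(0, c(H, W, nch))
  wsum <- matrix(0, H, W)
  for (j in seq_along(imgs)) {
    img <- imgs[[j]]
    h <- nrow(luminance(img)); w <- ncol(luminance(img))
    cols <- ((x[j] + seq_len(w) - 1L) %% W) + 1L
    rows_canvas <- y[j] - y_anchor + seq_len(h)
    keep <- which(rows_canvas >= 1L & rows_canvas <= H)
    if (!length(keep)) next
    wvec <- wy[keep]
    rr <- rows_canvas[keep]
    for (ch in seq_len(nch)) {
      band <- if (nch == 1L) img else img[, , ch]
      acc[rr, cols, ch] <- acc[rr, cols, ch] + band[keep, , drop = FALSE] * wvec
    }
    wsum[rr, cols] <- wsum[rr, cols] + wvec
  }
  wsum[wsum == 0] <- 1
  for (ch in seq_len(nch)) acc[, , ch] <- acc[, , ch] / wsum
  if (nch == 1L) acc[, , 1] else acc
}

#' @export
print.tube_panorama <- function(x, ...) {
  d <- dim(luminance(x$pixels))
  cat(sprintf(
    "<tube_panorama> %d x %d px, %d strips, %.3g mm/px, %.3g px/deg\n",
    d[1], d[2], x$n_strips, x$mm_per_px, x$px_per_deg
  ))
  invisible(x)
}

#' @export
glance.tube_panorama <- function(x, ...) {
  d <- dim(luminance(x$pixels))
  tibble::tibble(height_px = d[1], width_px = d[2], n_strips = x$n_strips,
                 mm_per_px = x$mm_per_px, px_per_deg = x$px_per_deg,
                 provenance = x$provenance)
}

#' @export
autoplot.tube_panorama <- function(object, ...) {
  plot_raster(object$pixels, title = sprintf(
    "Reconstructed tube panorama (%d strips, %.2f mm/px)",
    object$n_strips, object$mm_per_px
  ))
}

#' @export
autoplot.strip_panorama <- function(object, ...) {
  plot_raster(object$pixels, title = sprintf(
    "360-degree strip %s at %.0f mm depth", object$strip_idx, object$depth_mm
  ))
}

# Shared raster plot used by the autoplot methods.
plot_raster <- function(img, title = NULL) {
  img <- clamp01(as_image(img, "img"))
  h <- nrow(luminance(img)); w <- ncol(luminance(img))
  if (n_channels(img) == 1L) {
    col <- grDevices::gray(as.vector(img))
  } else {
    col <- grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                          as.vector(img[, , 3]))
  }
  d <- tibble::tibble(
    x = rep(seq_len(w), each = h),
    y = rep(rev(seq_len(h)), times = w),
    fill = col
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(fill = d$fill) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(size = 10))
}
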