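# Specular reflection removal. Light-source reflections on the tube wall
# are bright, desaturated streaks whose hue collapses into a narrow band
# distinct from soil and root hues, so they separate cleanly in the hue
# plane of HSV space: detect by (wraparound-aware) hue thresholding with
# optional value/saturation gates, then fill the masked pixels.

#' Convert an RGB image to HSV
#'
#' H, S, V all in `[0, 1]`; hue is circular (0 and 1 are both red).
#'
#' @param img H x W x 3 RGB array in `[0, 1]`.
#' @return H x W x 3 array with channels hue, saturation, value.
#' @export
to_hsv <- function(img) {
  img <- as_image(img, "img")
  if (n_channels(img) != 3L) abort("`img` must be a 3-channel RGB image.")
  d <- dim(img)
  m <- grDevices::rgb2hsv(r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
                          b = as.vector(img[, , 3]), maxColorValue = 1)
  out <- array(0, d)
  out[, , 1] <- m[1, ]
  out[, , 2] <- m[2, ]
  out[, , 3] <- m[3, ]
  out
}

#' Convert an HSV image back to RGB
#'
#' Vectorized inverse of [to_hsv()]; round-trip error is below one 8-bit
#' intensity step.
#'
#' @param hsv_img H x W x 3 array of hue, saturation, value in `[0, 1]`.
#' @return H x W x 3 RGB array.
#' @export
from_hsv <- function(hsv_img) {
  hsv_img <- as_image(hsv_img, "hsv_img")
  if (n_channels(hsv_img) != 3L) abort("`hsv_img` must have 3 channels.")
  h <- as.vector(hsv_img[, , 1]) %% 1
  s <- as.vector(hsv_img[, , 2])
  v <- as.vector(hsv_img[, , 3])
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, dim(hsv_img))
  out[, , 1] <- r
  out[, , 2] <- g
  out[, , 3] <- b
  out
}

#' Hue-band membership with wraparound
#'
#' @param h Hue values in `[0, 1)`.
#' @param lo,hi Band bounds; if `lo > hi` the band crosses 0 (e.g. reds).
#' @return Logical vector.
#' @export
hue_in_band <- function(h, lo, hi) {
  h <- h %% 1
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

# Circular histogram-based band finder: the artifact hue is the isolated
# secondary mode of the hue histogram restricted to bright pixels.
auto_hue_band <- function(h, v, v_min, n_bins = 64L, min_sep_bins = 8L,
                          rel_height = 0.25) {
  hh <- h[v >= v_min] %% 1
  if (length(hh) < 16L) return(NULL)
  bins <- floor(hh * n_bins) + 1L
  counts <- tabulate(bins, nbins = n_bins)
  # circular smoothing, kernel (1, 2, 1) / 4
  sm <- (counts + 0.5 * (c(counts[-1], counts[1]) +
                           c(counts[n_bins], counts[-n_bins]))) / 2
  primary <- which.max(sm)
  circ_dist <- function(a, b) pmin(abs(a - b), n_bins - abs(a - b))
  is_peak <- sm >= pmax(c(sm[-1], sm[1]), c(sm[n_bins], sm[-n_bins]))
  cand <- which(is_peak & circ_dist(seq_len(n_bins), primary) >= min_sep_bins)
  cand <- cand[sm[cand] > 0]
  if (length(cand) == 0L) return(NULL)
  secondary <- cand[which.max(sm[cand])]
  # grow the band around the secondary mode while the histogram stays high
  lo_bin <- secondary; hi_bin <- secondary
  lim <- rel_height * sm[secondary]
  for (step in seq_len(min_sep_bins - 1L)) {
    nxt <- (hi_bin %% n_bins) + 1L
    if (sm[nxt] >= lim && circ_dist(nxt, primary) >= 2) hi_bin <- nxt else break
  }
  for (step in seq_len(min_sep_bins - 1L)) {
    prv <- ((lo_bin - 2L) %% n_bins) + 1L
    if (sm[prv] >= lim && circ_dist(prv, primary) >= 2) lo_bin <- prv else break
  }
  c(lo = (lo_bin - 1) / n_bins, hi = hi_bin / n_bins)
}

#' Detect specular reflection streaks
#'
#' Flags pixels whose hue lies in the artifact band, optionally gated by
#' minimum value and maximum saturation, then consolidates streaks by
#' morphological closing.
#'
#' @param img H x W x 3 RGB image.
#' @param policy `"auto"` picks the artifact band as the isolated secondary
#'   mode of the hue histogram of bright pixels; `"fixed"` uses `hue_band`.
#' @param hue_band Length-2 `c(lo, hi)` hue bounds (may wrap: `lo > hi`);
#'   required for `policy = "fixed"`.
#' @param v_min Minimum value (brightness) gate; reflections are bright.
#' @param s_max Maximum saturation gate; `1` disables it.
#' @param close_radius Radius (px) of the disc used for morphological
#'   closing; `0` disables closing.
#' @return A `reflection_mask`: list with `mask` (logical matrix),
#'   `coverage_frac` and `threshold_used`.
#' @export
detect_reflections <- function(img, policy = c("auto", "fixed"),
                               hue_band = NULL, v_min = 0.5, s_max = 1,
                               close_radius = 2L) {
  img <- as_image(img, "img")
  if (n_channels(img) != 3L) {
    abort(paste("Reflection detection needs a 3-channel image;",
                "skip this stage for single-band data."))
  }
  policy <- match.arg(policy)
  hsv <- to_hsv(img)
  h <- hsv[, , 1]; s <- hsv[, , 2]; v <- hsv[, , 3]
  band <- if (policy == "fixed") {
    if (is.null(hue_band) || length(hue_band) != 2L) {
      abort("`policy = \"fixed\"` requires `hue_band = c(lo, hi)`.")
    }
    c(lo = hue_band[1], hi = hue_band[2])
  } else {
    auto_hue_band(h, v, v_min)
  }
  if (is.null(band)) {
    mask <- matrix(FALSE, nrow(h), ncol(h))
  } else {
    mask <- matrix(hue_in_band(as.vector(h), band["lo"], band["hi"]),
                   nrow(h), ncol(h)) & v >= v_min & s <= s_max
    if (close_radius > 0 && any(mask)) {
      brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
      mask <- EBImage::closing(mask * 1, brush) > 0.5
    }
  }
  coverage <- mean(mask)
  if (coverage >= 1) warn("Reflection mask covers the whole frame.")
  structure(list(mask = mask, coverage_frac = coverage,
                 threshold_used = list(policy = policy, hue_band = band,
                                       v_min = v_min, s_max = s_max,
                                       close_radius = close_radius)),
            class = "reflection_mask")
}

#' @export
print.reflection_mask <- function(x, ...) {
  b <- x$threshold_used$hue_band
  cat(sprintf("<reflection_mask> %.2f%% of frame flagged (%s policy%s)\n",
              100 * x$coverage_frac, x$threshold_used$policy,
              if (is.null(b)) ", no artifact band found"
              else sprintf(", hue band [%.3f, %.3f]", b[1], b[2])))
  invisible(x)
}

#' @export
tidy.reflection_mask <- function(x, ...) {
  b <- x$threshold_used$hue_band
  tibble::tibble(
    coverage_frac = x$coverage_frac,
    policy = x$threshold_used$policy,
    hue_lo = if (is.null(b)) NA_real_ else unname(b[1]),
    hue_hi = if (is.null(b)) NA_real_ else unname(b[2]),
    v_min = x$threshold_used$v_min,
    s_max = x$threshold_used$s_max
  )
}

# One Jacobi pass: replace each target pixel by the mean of its known
# 4-neighbours; returns NA where no neighbour is known.
neighbour_mean <- function(band, known) {
  h <- nrow(band); w <- ncol(band)
  val <- matrix(0, h, w); cnt <- matrix(0, h, w)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (s in shifts) {
    src_r <- seq_len(h) - s[1]; src_c <- seq_len(w) - s[2]
    ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
    v <- matrix(0, h, w); k <- matrix(FALSE, h, w)
    v[ok_r, ok_c] <- band[src_r[ok_r], src_c[ok_c]]
    k[ok_r, ok_c] <- known[src_r[ok_r], src_c[ok_c]]
    val <- val + v * k
    cnt <- cnt + k
  }
  out <- val / cnt
  out[cnt == 0] <- NA_real_
  out
}

fill_interpolate_band <- function(band, mask, smooth_iter = 10L) {
  known <- !mask
  out <- band
  # inward diffusion: fill mask pixels layer by layer from known neighbours
  repeat {
    if (all(known)) break
    nm <- neighbour_mean(out, known)
    frontier <- !known & !is.na(nm)
    if (!any(frontier)) break
    out[frontier] <- nm[frontier]
    known <- known | frontier
  }
  # fixed number of smoothing sweeps inside the original mask
  for (i in seq_len(smooth_iter)) {
    nm <- neighbour_mean(out, matrix(TRUE, nrow(out), ncol(out)))
    upd <- mask & !is.na(nm)
    out[upd] <- nm[upd]
  }
  out
}

# Windowed circular median of unmasked hues around each masked pixel.
local_median_hue <- function(h, mask, radius = 3L) {
  idx <- which(mask, arr.ind = TRUE)
  nr <- nrow(h); nc <- ncol(h)
  out <- h
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    rad <- radius
    repeat {
      rows <- max(1, r - rad):min(nr, r + rad)
      cols <- max(1, c - rad):min(nc, c + rad)
      vals <- h[rows, cols][!mask[rows, cols]]
      if (length(vals) > 0 || rad > max(nr, nc)) break
      rad <- rad * 2L
    }
    if (length(vals) == 0) next
    # rotate so the circular mean sits at 0.5, take the ordinary median there
    ang <- atan2(mean(sin(2 * pi * vals)), mean(cos(2 * pi * vals))) / (2 * pi)
    out[r, c] <- (median((vals - ang + 0.5) %% 1) + ang - 0.5) %% 1
  }
  out
}

#' Remove masked reflections from an image
#'
#' Pixels outside the mask are returned bit-identical; masked pixels are
#' replaced according to the fill policy.
#'
#' @param img H x W x 3 RGB image (or single-band matrix with
#'   `fill = "interpolate"`).
#' @param mask A [detect_reflections()] result or a logical matrix.
#' @param fill `"interpolate"`: inward nearest-valid diffusion with a fixed
#'   number of smoothing sweeps; `"clamp_hue"`: replace hue with the local
#'   median hue of unmasked neighbours, keeping S and V.
#' @param smooth_iter Smoothing sweeps for `"interpolate"`.
#' @param hue_radius Neighbourhood radius for `"clamp_hue"`.
#' @return Image with reflections removed.
#' @export
remove_reflections <- function(img, mask, fill = c("interpolate", "clamp_hue"),
                               smooth_iter = 10L, hue_radius = 3L) {
  img <- as_image(img, "img")
  fill <- match.arg(fill)
  if (inherits(mask, "reflection_mask")) mask <- mask$mask
  if (!is.logical(mask) || !identical(dim(mask), dim(img)[1:2])) {
    abort("`mask` must be a logical matrix matching the image frame.")
  }
  if (!any(mask)) return(img)
  if (fill == "interpolate") {
    if (n_channels(img) == 1L) return(fill_interpolate_band(img, mask, smooth_iter))
    out <- img
    for (ch in 1:3) {
      out[, , ch] <- fill_interpolate_band(img[, , ch], mask, smooth_iter)
    }
    out
  } else {
    if (n_channels(img) != 3L) abort("`clamp_hue` needs an RGB image.")
    hsv <- to_hsv(img)
    hsv[, , 1] <- local_median_hue(hsv[, , 1], mask, radius = hue_radius)
    out <- from_hsv(hsv)
    # guarantee bit-identity outside the mask despite colourspace round-trip
    for (ch in 1:3) {
      band <- out[, , ch]; band[!mask] <- img[, , ch][!mask]
      out[, , ch] <- band
    }
    out
  }
}
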