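# Time-luminance curves, delay-time (time-to-peak) estimation and the
# per-pixel perfusion colour map.

#' Define a region of interest
#'
#' Either a pixel mask or a polygon in (x = column, y = row) coordinates;
#' polygons are rasterised by an even-odd point-in-polygon test.
#'
#' @param id Character identifier.
#' @param mask Logical H x W matrix, or `NULL` when `polygon` is given.
#' @param polygon n x 2 matrix of (x, y) vertices.
#' @param shape Frame shape `c(H, W)` (required with `polygon`).
#' @param label Optional free-text label.
#' @return An `roi` list with a rasterised `mask`.
#' @export
roi <- function(id, mask = NULL, polygon = NULL, shape = NULL, label = "") {
  if (is.null(mask)) {
    if (is.null(polygon) || is.null(shape)) {
      stop("supply either a mask, or a polygon plus frame shape")
    }
    mask <- polygon_mask(polygon, shape)
  }
  if (!any(mask)) stop("ROI is empty")
  structure(list(id = as.character(id), mask = mask, label = label),
            class = "roi")
}

# Even-odd rasterisation of a polygon given as (x, y) vertices.
polygon_mask <- function(polygon, shape) {
  polygon <- matrix(polygon, ncol = 2)
  H <- shape[1]; W <- shape[2]
  gx <- rep(seq_len(W), each = H)
  gy <- rep(seq_len(H), times = W)
  n <- nrow(polygon)
  inside <- rep(FALSE, H * W)
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    crosses <- ((yi > gy) != (yj > gy)) &
      (gx < (xj - xi) * (gy - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, H, W)
}

#' Time-luminance curve of a region of interest
#'
#' Mean brightness over the ROI pixels at each frame, against time in seconds
#' (`frame_index / fps`, first frame at t = 0).
#'
#' @param video An `icg_video`.
#' @param roi An [roi()] or a logical mask.
#' @return A `luminance_curve` data frame with columns `time` and `value`.
#' @export
luminance_curve <- function(video, roi) {
  mask <- if (inherits(roi, "roi")) roi$mask else roi
  if (!any(mask)) stop("ROI is empty")
  d <- dim(video$frames)
  if (!all(dim(mask) == d[1:2])) stop("ROI outside frame bounds")
  fr <- matrix(video$frames, d[1] * d[2], d[3])
  vals <- colMeans(fr[which(mask), , drop = FALSE])
  structure(data.frame(time = (seq_len(d[3]) - 1) / video$fps, value = vals),
            class = c("luminance_curve", "data.frame"))
}

# Centred moving average along rows of a (n_series x T) matrix, with the
# window shrinking symmetrically near the ends. width = 1 is a no-op.
smooth_rows <- function(m, width) {
  if (width <= 1) return(m)
  half <- floor(width / 2)
  nt <- ncol(m)
  out <- m
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  for (t in seq_len(nt)) {
    lo <- max(1, t - half); hi <- min(nt, t + half)
    out[, t] <- (cs[, hi + 1] - cs[, lo]) / (hi - lo + 1)
  }
  out
}

# First-attained-maximum time (seconds) per row of a value matrix.
ttp_rows <- function(values, fps, smooth_width) {
  sm <- smooth_rows(values, smooth_width)
  idx <- max.col(sm, ties.method = "first")
  (idx - 1) / fps
}

#' Delay time (time-to-peak) of a luminance curve
#'
#' Time at which the (optionally smoothed) curve first attains its maximum,
#' measured from the first frame. Ties take the earliest frame. A flat curve
#' returns 0 with a warning.
#'
#' @param curve A [luminance_curve()] (or data frame with `time`, `value`).
#' @param smooth_width Centred moving-average window in frames (default 5,
#'   i.e. 0.2 s at 25 fps); 1 disables smoothing.
#' @return Delay time in seconds.
#' @export
delay_time <- function(curve, smooth_width = 5) {
  if (nrow(curve) < 2) stop("need at least two samples")
  v <- matrix(curve$value, nrow = 1)
  if (diff(range(v)) == 0) {
    warning("flat curve: delay time undefined, returning 0")
    return(0)
  }
  idx <- max.col(smooth_rows(v, smooth_width), ties.method = "first")
  curve$time[idx]
}

#' Red-to-blue-purple perfusion colourbar
#'
#' Ordered colour ramp used by [perfusion_color_map()]: early-arriving
#' (small time-to-peak) tissue is red, late-arriving tissue blue-purple.
#'
#' @param n Number of ramp entries.
#' @return n x 3 matrix of RGB values in \[0, 1\].
#' @export
perfusion_colorbar <- function(n = 256) {
  cols <- grDevices::rainbow(n, start = 0, end = 0.78)
  t(grDevices::col2rgb(cols)) / 255
}

#' Per-pixel time-to-peak perfusion colour map
#'
#' Computes each vessel pixel's time to first-attained maximum brightness
#' (exactly as [delay_time()] does for a single-pixel ROI) and renders it on
#' the red-to-blue-purple ramp, linearly scaled between the 1st and 99th
#' percentiles of time-to-peak within the mask. Background pixels are black.
#'
#' @param video An `icg_video` with at least 2 frames.
#' @param mask Logical vessel mask.
#' @param smooth_width Temporal smoothing window in frames (see [delay_time()]).
#' @param colorbar Colour ramp matrix from [perfusion_colorbar()].
#' @return A `perfusion_map` list: `ttp` (H x W matrix, `NA` off-mask), `rgb`
#'   (H x W x 3 array), `position` (H x W matrix of ramp positions in
#'   \[0, 1\]), and `colorbar`.
#' @export
perfusion_color_map <- function(video, mask, smooth_width = 5,
                                colorbar = perfusion_colorbar()) {
  d <- dim(video$frames)
  if (d[3] < 2) stop("need at least two frames")
  if (!any(mask)) stop("empty mask")
  pix <- which(mask)
  fr <- matrix(video$frames, d[1] * d[2], d[3])
  ttp_vals <- ttp_rows(fr[pix, , drop = FALSE], video$fps, smooth_width)

  q <- stats::quantile(ttp_vals, c(0.01, 0.99), names = FALSE)
  pos <- if (q[2] > q[1]) pmin(1, pmax(0, (ttp_vals - q[1]) / (q[2] - q[1]))) else
    rep(0, length(ttp_vals))
  n <- nrow(colorbar)
  ci <- pmin(n, pmax(1, round(pos * (n - 1)) + 1))

  ttp <- matrix(NA_real_, d[1], d[2]); ttp[pix] <- ttp_vals
  posm <- matrix(NA_real_, d[1], d[2]); posm[pix] <- pos
  rgb <- array(0, dim = c(d[1], d[2], 3))
  for (ch in 1:3) {
    plane <- matrix(0, d[1], d[2])
    plane[pix] <- colorbar[ci, ch]
    rgb[, , ch] <- plane
  }
  structure(list(ttp = ttp, rgb = rgb, position = posm, colorbar = colorbar),
            class = "perfusion_map")
}

#' Look up a colour's relative position on a colourbar
#'
#' Finds the ramp entry nearest to `rgb_value` in Euclidean RGB distance and
#' returns its relative position in \[0, 1\] — the digital analogue of reading
#' a perfusion colour against the printed colour bar. Ties take the earliest
#' position and are flagged.
#'
#' @param rgb_value Length-3 RGB vector in \[0, 1\].
#' @param colorbar n x 3 ramp matrix ([perfusion_colorbar()]).
#' @return Position in \[0, 1\], with attribute `ambiguous` (logical).
#' @export
colorbar_lookup <- function(rgb_value, colorbar = perfusion_colorbar()) {
  d2 <- colSums((t(colorbar) - as.numeric(rgb_value))^2)
  i <- which.min(d2)
  ambiguous <- sum(abs(d2 - d2[i]) < 1e-12) > 1
  structure((i - 1) / (nrow(colorbar) - 1), ambiguous = ambiguous)
}
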