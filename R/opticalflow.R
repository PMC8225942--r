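# Pyramid Horn-Schunck optical flow and per-vessel flow-direction
# classification.

#' Horn-Schunck solver parameters
#'
#' @param lambda Smoothness coefficient (default 2): larger values give
#'   smoother, more globally coherent flow fields.
#' @param energy_tol Convergence threshold on the difference between the
#'   energy functional at two consecutive iterations (default 0.1, applied to
#'   the energy summed over pixels with intensities on the \[0, 1\] scale).
#' @param max_iterations Iteration safeguard per pyramid level (default 200).
#' @param pyramid_levels Number of Gaussian pyramid levels (default 4).
#' @return An `hs_params` list.
#' @export
hs_params <- function(lambda = 2, energy_tol = 0.1, max_iterations = 200,
                      pyramid_levels = 4) {
  if (lambda <= 0 || energy_tol <= 0 || pyramid_levels < 1) {
    stop("lambda and energy_tol must be positive, pyramid_levels >= 1")
  }
  structure(list(lambda = lambda, energy_tol = energy_tol,
                 max_iterations = max_iterations,
                 pyramid_levels = pyramid_levels), class = "hs_params")
}

#' Gaussian image pyramid
#'
#' Level 1 is the original frame; each further level is Gaussian-smoothed and
#' downsampled by 2. If the frame is too small for the requested depth, fewer
#' levels are returned with a warning.
#'
#' @param frame Numeric matrix.
#' @param levels Number of levels (default 4).
#' @param sigma Smoothing sigma before each downsampling.
#' @return List of matrices, finest first.
#' @export
gaussian_pyramid <- function(frame, levels = 4, sigma = 1) {
  frame <- as.matrix(frame)
  out <- list(frame)
  for (l in seq_len(levels - 1)) {
    cur <- out[[l]]
    if (min(dim(cur)) < 8) {
      warning(sprintf("frame too small for %d pyramid levels; returning %d",
                      levels, l))
      break
    }
    sm <- gauss_smooth(cur, sigma)
    out[[l + 1]] <- sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2)]
  }
  out
}

# Separable Gaussian smoothing with replicated borders (constant-preserving).
gauss_smooth <- function(img, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), , drop = FALSE]
  conv1 <- function(m) {
    # along rows (dimension 1)
    mp <- pad(m, r)
    acc <- 0
    for (i in seq_along(k)) acc <- acc + k[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
    acc
  }
  t(conv1(t(conv1(img))))
}

# Average-filter for the Horn-Schunck neighbourhood mean (weights 1/6 for the
# 4-neighbours, 1/12 for the diagonals), replicated borders.
hs_local_mean <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ri <- function(i) pmin(pmax(i, 1L), H)
  ci <- function(j) pmin(pmax(j, 1L), W)
  up <- m[ri(seq_len(H) - 1L), , drop = FALSE]
  dn <- m[ri(seq_len(H) + 1L), , drop = FALSE]
  lf <- m[, ci(seq_len(W) - 1L), drop = FALSE]
  rt <- m[, ci(seq_len(W) + 1L), drop = FALSE]
  ul <- up[, ci(seq_len(W) - 1L), drop = FALSE]
  ur <- up[, ci(seq_len(W) + 1L), drop = FALSE]
  dl <- dn[, ci(seq_len(W) - 1L), drop = FALSE]
  dr <- dn[, ci(seq_len(W) + 1L), drop = FALSE]
  (up + dn + lf + rt) / 6 + (ul + ur + dl + dr) / 12
}

# Classical 2x2x2 Horn-Schunck derivative stencil on a frame pair.
hs_gradients <- function(I1, I2) {
  H <- nrow(I1); W <- ncol(I1)
  sh <- function(m, dr, dc) {
    m[pmin(pmax(seq_len(H) + dr, 1L), H), pmin(pmax(seq_len(W) + dc, 1L), W),
      drop = FALSE]
  }
  Ix <- ((sh(I1, 0, 1) - I1) + (sh(I1, 1, 1) - sh(I1, 1, 0)) +
           (sh(I2, 0, 1) - I2) + (sh(I2, 1, 1) - sh(I2, 1, 0))) / 4
  Iy <- ((sh(I1, 1, 0) - I1) + (sh(I1, 1, 1) - sh(I1, 0, 1)) +
           (sh(I2, 1, 0) - I2) + (sh(I2, 1, 1) - sh(I2, 0, 1))) / 4
  It <- ((I2 - I1) + (sh(I2, 0, 1) - sh(I1, 0, 1)) +
           (sh(I2, 1, 0) - sh(I1, 1, 0)) + (sh(I2, 1, 1) - sh(I1, 1, 1))) / 4
  list(Ix = Ix, Iy = Iy, It = It)
}

# Energy functional: sum over pixels of the data residual squared plus
# lambda times the squared flow gradients.
hs_energy <- function(u, v, Ix, Iy, It, lambda) {
  gx <- function(m) cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE]) - m
  gy <- function(m) rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE]) - m
  data_term <- (Ix * u + Iy * v + It)^2
  smooth_term <- gx(u)^2 + gy(u)^2 + gx(v)^2 + gy(v)^2
  sum(data_term + lambda * smooth_term)
}

# Single-level Horn-Schunck iteration from an initial flow.
hs_solve_level <- function(I1, I2, params, u0 = NULL, v0 = NULL) {
  g <- hs_gradients(I1, I2)
  if (any(!is.finite(g$Ix)) || any(!is.finite(g$Iy)) || any(!is.finite(g$It))) {
    stop("non-finite image gradients: check input frames")
  }
  denom <- params$lambda^2 + g$Ix^2 + g$Iy^2
  u <- if (is.null(u0)) matrix(0, nrow(I1), ncol(I1)) else u0
  v <- if (is.null(v0)) matrix(0, nrow(I1), ncol(I1)) else v0
  energy <- numeric(0)
  e_prev <- Inf
  iters <- 0L
  for (k in seq_len(params$max_iterations)) {
    ub <- hs_local_mean(u)
    vb <- hs_local_mean(v)
    common <- (g$Ix * ub + g$Iy * vb + g$It) / denom
    u <- ub - g$Ix * common
    v <- vb - g$Iy * common
    e <- hs_energy(u, v, g$Ix, g$Iy, g$It, params$lambda)
    energy <- c(energy, e)
    iters <- k
    if (is.finite(e_prev) && abs(e_prev - e) < params$energy_tol) break
    e_prev <- e
  }
  list(u = u, v = v, energy = energy, iterations = iters)
}

# Bilinear warp of an image by a flow field: sample I at (x + u, y + v).
warp_by_flow <- function(img, u, v) {
  H <- nrow(img); W <- ncol(img)
  x <- rep(seq_len(W), each = H) + as.vector(u)
  y <- rep(seq_len(H), times = W) + as.vector(v)
  x <- pmin(pmax(x, 1), W); y <- pmin(pmax(y, 1), H)
  x0 <- pmin(floor(x), W - 1); y0 <- pmin(floor(y), H - 1)
  fx <- x - x0; fy <- y - y0
  g <- function(r, c) img[cbind(r, c)]
  vals <- (1 - fx) * (1 - fy) * g(y0, x0) + fx * (1 - fy) * g(y0, x0 + 1) +
    (1 - fx) * fy * g(y0 + 1, x0) + fx * fy * g(y0 + 1, x0 + 1)
  matrix(vals, H, W)
}

upsample_flow <- function(m, shape) {
  2 * resize_bilinear(m, shape)
}

resize_bilinear <- function(img, shape) {
  H <- nrow(img); W <- ncol(img)
  oh <- shape[1]; ow <- shape[2]
  sy <- (seq_len(oh) - 0.5) * H / oh + 0.5
  sx <- (seq_len(ow) - 0.5) * W / ow + 0.5
  sy <- pmin(pmax(sy, 1), H); sx <- pmin(pmax(sx, 1), W)
  y0 <- pmin(floor(sy), H - 1); x0 <- pmin(floor(sx), W - 1)
  fy <- sy - y0; fx <- sx - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x0 + 1, drop = FALSE]
  c_ <- img[y0 + 1, x0, drop = FALSE]; d <- img[y0 + 1, x0 + 1, drop = FALSE]
  fy <- matrix(fy, oh, ow); fx <- matrix(fx, oh, ow, byrow = TRUE)
  (1 - fy) * ((1 - fx) * a + fx * b) + fy * ((1 - fx) * c_ + fx * d)
}

#' Horn-Schunck optical flow between two frames
#'
#' Coarse-to-fine variational optical flow under a brightness-constancy data
#' term and a global smoothness penalty weighted by `lambda`. Intensities are
#' used on the native 8-bit (0-255) scale, on which the default `lambda = 2`
#' balances the two terms; unit-scale input is rescaled to it. Flow is solved
#' at the coarsest level of
#' a Gaussian pyramid from a zero initial field, upsampled, used to warp the
#' second frame at the next level, and refined, down to full resolution. At
#' each level the Jacobi-style update iterates until the energy functional
#' changes by less than `energy_tol` between consecutive iterations (or
#' `max_iterations` is hit).
#'
#' @param frame_t,frame_t1 Numeric matrices (same shape): consecutive frames.
#' @param params [hs_params()].
#' @return A `flow_field` list: `u` (x/column velocity, px/frame), `v`
#'   (y/row velocity), `energy_trace` (final level), `iterations_used`
#'   (per level).
#' @export
hs_flow <- function(frame_t, frame_t1, params = hs_params()) {
  I1 <- as.matrix(frame_t); I2 <- as.matrix(frame_t1)
  if (!all(dim(I1) == dim(I2))) stop("frames must have the same shape")
  # work on the native 8-bit scale: lambda = 2 balances data and smoothness
  # terms for gradients of 8-bit imagery; unit-scale input is rescaled
  if (max(I1, I2) <= 1) { I1 <- I1 * 255; I2 <- I2 * 255 }

  p1 <- gaussian_pyramid(I1, params$pyramid_levels)
  p2 <- gaussian_pyramid(I2, params$pyramid_levels)
  nl <- min(length(p1), length(p2))
  u <- NULL; v <- NULL
  energy <- numeric(0); iters <- integer(0)
  for (l in nl:1) {
    a <- p1[[l]]; b <- p2[[l]]
    if (is.null(u)) {
      u <- matrix(0, nrow(a), ncol(a)); v <- matrix(0, nrow(a), ncol(a))
      b_eff <- b
    } else {
      u <- upsample_flow(u, dim(a)); v <- upsample_flow(v, dim(a))
      b_eff <- warp_by_flow(b, u, v)
    }
    sol <- hs_solve_level(a, b_eff, params)
    u <- u + sol$u; v <- v + sol$v
    energy <- sol$energy; iters <- c(iters, sol$iterations)
  }
  structure(list(u = u, v = v, energy_trace = energy,
                 iterations_used = iters), class = "flow_field")
}

#' Blood-flow direction label
#'
#' @param category One of `"forward"`, `"reverse"`, `"middle_to_both_sides"`,
#'   `"indeterminate"`.
#' @param confidence Fraction of voting pixels agreeing with the verdict.
#' @return A `direction_label` list.
#' @export
direction_label <- function(category, confidence = NA_real_) {
  category <- match.arg(category, c("forward", "reverse",
                                    "middle_to_both_sides", "indeterminate"))
  if (!is.na(confidence) && (confidence < 0 || confidence > 1)) {
    stop("confidence must lie in [0, 1]")
  }
  structure(list(category = category, confidence = confidence),
            class = "direction_label")
}

#' @export
print.direction_label <- function(x, ...) {
  cat(sprintf("flow direction: %s (confidence %.2f)\n", x$category,
              x$confidence))
  invisible(x)
}

#' Direction-classification tuning parameters
#'
#' @param vote_threshold Mean-sign threshold beyond which the aggregate vote
#'   is called forward/reverse (default 0.3).
#' @param n_bins Arc-length bins for the divergence (middle-to-both-sides)
#'   profile test.
#' @param magnitude_quantile Per-frame-pair quantile of flow magnitude below
#'   which pixels do not vote (default 0.1).
#' @param max_pairs Cap on the number of frame pairs analysed (pairs are
#'   taken evenly across the middle window of the video).
#' @param window Fractional window of the wash-in (by frame-mean brightness
#'   range) whose central half is analysed; `c(0.1, 0.9)` reproduces the
#'   10 \%/90 \% crossings rule.
#' @return A `direction_config` list.
#' @export
#' @param frame_step Frame distance between the two frames of each analysed
#'   pair (default 2): the wash-in front moves less than a pixel per frame, so
#'   a small step raises the motion signal relative to sensor noise while
#'   staying within the pyramid's displacement range.
#' @param smooth_frames Temporal moving-average window (frames) applied to
#'   the video before flow computation, suppressing uncorrelated sensor noise
#'   without moving the wash-in front (default 5).
direction_config <- function(vote_threshold = 0.3, n_bins = 10,
                             magnitude_quantile = 0.1, max_pairs = 12,
                             window = c(0.1, 0.9), frame_step = 2,
                             smooth_frames = 5) {
  structure(list(vote_threshold = vote_threshold, n_bins = n_bins,
                 magnitude_quantile = magnitude_quantile,
                 max_pairs = max_pairs, window = window,
                 frame_step = as.integer(frame_step),
                 smooth_frames = as.integer(smooth_frames)),
            class = "direction_config")
}

# Frames spanning the middle of the wash-in: the central 50% (by index) of
# the interval between the first crossing of 10% and the last crossing of
# 90% of the frame-mean brightness range.
middle_frame_window <- function(video, mask = NULL, window = c(0.1, 0.9)) {
  d <- dim(video$frames)
  fr <- matrix(video$frames, d[1] * d[2], d[3])
  m <- if (is.null(mask)) colMeans(fr) else colMeans(fr[which(mask), , drop = FALSE])
  lo <- min(m) + window[1] * diff(range(m))
  hi <- min(m) + window[2] * diff(range(m))
  i0 <- which(m >= lo)[1]
  i1 <- rev(which(m <= hi))[1]
  if (is.na(i0) || is.na(i1) || i1 <= i0) return(c(1L, d[3]))
  span <- i1 - i0
  c(i0 + floor(0.25 * span), i0 + ceiling(0.75 * span))
}

# Unit tangents along an ordered centreline path ((row, col) matrix),
# by central differences, in (x, y) = (col, row) components.
centerline_tangents <- function(path) {
  n <- nrow(path)
  nxt <- pmin(seq_len(n) + 2L, n)
  prv <- pmax(seq_len(n) - 2L, 1L)
  dx <- path[nxt, 2] - path[prv, 2]
  dy <- path[nxt, 1] - path[prv, 1]
  len <- sqrt(dx^2 + dy^2); len[len == 0] <- 1
  cbind(tx = dx / len, ty = dy / len)
}

#' Classify the blood-flow direction of a vessel
#'
#' Runs Horn-Schunck flow on consecutive frame pairs from the middle of the
#' wash-in (where the brightness change, and hence the directional signal, is
#' strongest), projects each vessel pixel's flow vector onto the local
#' centreline tangent, and aggregates the signed projections into one of four
#' verdicts. Pixels whose flow magnitude falls below a per-pair floor (the
#' `magnitude_quantile` of in-mask magnitudes) do not vote. With `s` the mean
#' vote sign: forward when `s > vote_threshold`, reverse when
#' `s < -vote_threshold`; before that, if the arc-length profile of the mean
#' vote changes sign exactly once, from negative to positive, with both halves
#' strong, the pattern is dye entering in the middle and leaving towards both
#' ends (`middle_to_both_sides`). Anything else is `indeterminate`.
#'
#' @param video An `icg_video`.
#' @param mask Logical vessel mask.
#' @param centerline Ordered (row, col) matrix; when `NULL` the mask is
#'   skeletonised and its longest path traced (orientation then follows the
#'   detected endpoint order, so forward/reverse are relative to it).
#' @param params [hs_params()].
#' @param config [direction_config()].
#' @return A [direction_label()] with attributes `profile` (per-bin mean
#'   vote), `mean_sign`, and `n_pairs`.
#' @export
vessel_flow_direction <- function(video, mask, centerline = NULL,
                                  params = hs_params(),
                                  config = direction_config()) {
  if (!any(mask)) stop("empty vessel mask")
  if (is.null(centerline)) centerline <- trace_centerline(mask)
  d <- dim(video$frames)

  # temporal denoising: centred moving average along the frame axis
  frames <- video$frames
  if (config$smooth_frames > 1) {
    fr <- matrix(as.numeric(frames), d[1] * d[2], d[3])
    frames <- array(smooth_rows(fr, config$smooth_frames), dim = d)
  }

  win <- middle_frame_window(video, mask, config$window)
  step <- max(1L, config$frame_step)
  last_start <- max(win[1], win[2] - step)
  pair_starts <- win[1]:last_start
  if (length(pair_starts) > config$max_pairs) {
    pair_starts <- unique(round(seq(win[1], last_start,
                                    length.out = config$max_pairs)))
  }

  pix <- which(mask, arr.ind = TRUE)
  nn <- nearest_point(pix, centerline)
  tang <- centerline_tangents(centerline)
  tx <- tang[nn, 1]; ty <- tang[nn, 2]
  arc <- c(0, cumsum(sqrt(rowSums(diff(centerline)^2))))
  pix_arc <- arc[nn]
  bins <- cut(pix_arc, breaks = seq(min(arc), max(arc) + 1e-9,
                                    length.out = config$n_bins + 1L),
              include.lowest = TRUE, labels = FALSE)
  lin <- (pix[, 2] - 1L) * d[1] + pix[, 1]

  votes <- numeric(0); weights <- numeric(0)
  bin_sum <- numeric(config$n_bins); bin_n <- numeric(config$n_bins)
  for (f in pair_starts) {
    fl <- hs_flow(frames[, , f], frames[, , f + step], params)
    u <- fl$u[lin]; v <- fl$v[lin]
    mag <- sqrt(u^2 + v^2)
    floor_mag <- stats::quantile(mag, config$magnitude_quantile, names = FALSE)
    voting <- mag > floor_mag & mag > 1e-9
    if (!any(voting)) next
    s <- sign(u[voting] * tx[voting] + v[voting] * ty[voting])
    w <- mag[voting]
    votes <- c(votes, s); weights <- c(weights, w)
    bs <- tapply(s * w, bins[voting], sum)
    bn <- tapply(w, bins[voting], sum)
    ii <- as.integer(names(bs))
    bin_sum[ii] <- bin_sum[ii] + as.numeric(bs)
    bin_n[ii] <- bin_n[ii] + as.numeric(bn)
  }

  if (length(votes) == 0) {
    return(direction_label("indeterminate", 0))
  }
  s_mean <- sum(votes * weights) / sum(weights)
  profile <- ifelse(bin_n > 0, bin_sum / pmax(bin_n, 1), NA_real_)
  ok <- which(!is.na(profile))
  label <- NULL
  # middle-to-both-sides: single - -> + sign change with strong halves
  if (length(ok) >= 4) {
    pr <- profile[ok]
    sgn <- sign(pr)
    changes <- which(diff(sgn[sgn != 0]) != 0)
    nz <- which(sgn != 0)
    if (length(changes) == 1) {
      cp <- nz[changes[1]]
      left <- pr[seq_len(cp)]; right <- pr[(cp + 1):length(pr)]
      if (mean(left) < -config$vote_threshold &&
          mean(right) > config$vote_threshold) {
        expected <- c(rep(-1, cp), rep(1, length(pr) - cp))
        conf <- mean(sign(pr) == expected)
        label <- direction_label("middle_to_both_sides", conf)
      }
    }
  }
  if (is.null(label)) {
    if (s_mean > config$vote_threshold) {
      label <- direction_label("forward", sum(weights[votes > 0]) / sum(weights))
    } else if (s_mean < -config$vote_threshold) {
      label <- direction_label("reverse", sum(weights[votes < 0]) / sum(weights))
    } else {
      label <- direction_label("indeterminate", 1 - abs(s_mean))
    }
  }
  attr(label, "profile") <- profile
  attr(label, "mean_sign") <- s_mean
  attr(label, "n_pairs") <- length(pair_starts)
  label
}

#' Did the flow direction change between two acquisitions?
#'
#' @param pre,post [direction_label()] objects (or category strings).
#' @return `"changed"`, `"unchanged"`, or `"indeterminate"` when either input
#'   is indeterminate.
#' @export
direction_change <- function(pre, post) {
  a <- if (inherits(pre, "direction_label")) pre$category else pre
  b <- if (inherits(post, "direction_label")) post$category else post
  if (a == "indeterminate" || b == "indeterminate") return("indeterminate")
  if (a == b) "unchanged" else "changed"
}

#' Skeletonise a binary mask and trace its longest path
#'
#' Zhang-Suen thinning followed by a double breadth-first search for the
#' longest 8-connected path, giving an ordered centreline for masks generated
#' outside the synthetic module.
#'
#' @param mask Logical matrix.
#' @return Ordered n x 2 (row, col) matrix.
#' @export
trace_centerline <- function(mask) {
  sk <- zhang_suen(mask)
  pts <- which(sk, arr.ind = TRUE)
  if (nrow(pts) < 2) stop("mask too thin to trace a centreline")
  key <- paste(pts[, 1], pts[, 2])
  idx_of <- stats::setNames(seq_len(nrow(pts)), key)
  nbr <- function(i) {
    r <- pts[i, 1]; c <- pts[i, 2]
    cand <- paste(rep(r + -1:1, times = 3), rep(c + -1:1, each = 3))
    hit <- idx_of[cand]
    hit <- hit[!is.na(hit)]
    hit[hit != i]
  }
  bfs_far <- function(start) {
    dist <- rep(-1L, nrow(pts)); prev <- rep(0L, nrow(pts))
    dist[start] <- 0L
    q <- start
    while (length(q)) {
      i <- q[1]; q <- q[-1]
      for (j in nbr(i)) if (dist[j] < 0) {
        dist[j] <- dist[i] + 1L; prev[j] <- i; q <- c(q, j)
      }
    }
    list(far = which.max(dist), dist = dist, prev = prev)
  }
  a <- bfs_far(1L)
  b <- bfs_far(a$far)
  path <- integer(0); i <- b$far
  while (i != 0L) { path <- c(path, i); i <- b$prev[i] }
  pts[path, , drop = FALSE]
}

# Zhang-Suen binary thinning.
zhang_suen <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  H <- nrow(img); W <- ncol(img)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- img
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- list()
      for (k in 1:8) {
        dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)[k]
        dc <- c(0, 1, 1, 1, 0, -1, -1, -1)[k]
        p[[k]] <- pad[2:(H + 1) + dr, 2:(W + 1) + dc]
      }
      P <- pad[2:(H + 1), 2:(W + 1)]
      B <- Reduce(`+`, p)
      seqp <- c(p, p[1])
      A <- Reduce(`+`, lapply(1:8, function(k) (seqp[[k]] == 0) * (seqp[[k + 1]] == 1)))
      if (phase == 1) {
        cond <- P == 1 & B >= 2 & B <= 6 & A == 1 &
          (p[[1]] * p[[3]] * p[[5]] == 0) & (p[[3]] * p[[5]] * p[[7]] == 0)
      } else {
        cond <- P == 1 & B >= 2 & B <= 6 & A == 1 &
          (p[[1]] * p[[3]] * p[[7]] == 0) & (p[[1]] * p[[5]] * p[[7]] == 0)
      }
      if (any(cond)) {
        P[cond] <- 0L
        pad[2:(H + 1), 2:(W + 1)] <- P
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(H + 1), 2:(W + 1)] == 1L
}
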