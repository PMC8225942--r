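# Run code with a private RNG state so generators are deterministic for a
# given seed without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic vessel tree
#'
#' Draws a branching vessel phantom on a blank raster: one main (recipient)
#' vessel crossing the frame plus side branches of varying calibre, emulating
#' the cortical vessel trees seen in ICG angiography, where vessels of very
#' different diameters coexist. Branch centrelines are smooth random paths,
#' monotone in the column direction so that each path is simple (never
#' self-intersecting), and rasterised with a slowly tapering radius.
#'
#' @param seed Integer seed; identical seeds give identical trees.
#' @param shape Integer vector `c(H, W)`, both at least 64.
#' @param n_branches Total number of branches including the main vessel (>= 1).
#' @return A `vessel_tree` list: `mask` (H x W logical), `recipient_mask`
#'   (logical, the main vessel only, a subset of `mask`), `centerlines` (list
#'   per branch with `path` (n x 2 matrix of (row, col)), `radius`, `parent`,
#'   `attach` index into the parent path), and `shape`.
#' @examples
#' tree <- generate_vessel_tree(1, c(128, 128), 3)
#' sum(tree$mask)
#' @export
generate_vessel_tree <- function(seed, shape = c(128, 128), n_branches = 3) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (H < 64 || W < 64) stop("shape too small: need at least 64 x 64")
  if (n_branches < 1) stop("need at least one branch")

  with_seed(seed, {
    branches <- list()
    # main vessel: left -> right, heading constrained so col is increasing
    y0 <- stats::runif(1, 0.3 * H, 0.7 * H)
    main <- walk_path(start = c(y0, 3), heading = stats::runif(1, -0.3, 0.3),
                      n_steps = ceiling((W - 6) / 0.7), H = H, W = W,
                      max_heading = 0.9, wobble = 0.12)
    branches[[1]] <- list(path = main, radius = stats::runif(1, 2.6, 3.4),
                          parent = 0L, attach = NA_integer_)

    k <- 2L
    while (k <= n_branches) {
      parent <- sample.int(min(length(branches), k - 1L), 1L)
      pp <- branches[[parent]]$path
      at <- sample(seq(floor(nrow(pp) * 0.2), ceiling(nrow(pp) * 0.8)), 1L)
      tangent <- atan2(pp[min(at + 5L, nrow(pp)), 1] - pp[max(at - 5L, 1L), 1],
                       pp[min(at + 5L, nrow(pp)), 2] - pp[max(at - 5L, 1L), 2])
      side <- sample(c(-1, 1), 1L)
      child <- walk_path(start = pp[at, ], heading = tangent + side * stats::runif(1, 0.5, 0.9),
                         n_steps = ceiling(stats::runif(1, 0.25, 0.5) * min(H, W) / 0.7),
                         H = H, W = W, max_heading = 1.25, wobble = 0.15)
      if (nrow(child) < 10) next
      branches[[k]] <- list(path = child,
                            radius = stats::runif(1, 1.0, 2.0),
                            parent = parent, attach = at)
      k <- k + 1L
    }

    mask <- matrix(FALSE, H, W)
    for (b in branches) mask <- mask | rasterize_path(b$path, b$radius, H, W)
    recipient <- rasterize_path(branches[[1]]$path, branches[[1]]$radius, H, W)

    structure(list(mask = mask, recipient_mask = recipient & mask,
                   centerlines = branches, shape = c(H, W)),
              class = "vessel_tree")
  })
}

# Smooth random path with small heading increments; steps of 0.7 px are
# rounded to pixels, so consecutive pixels differ by at most one in each
# coordinate (8-connected). Headings are clamped so the column coordinate is
# strictly increasing along the walk, which makes the path simple.
walk_path <- function(start, heading, n_steps, H, W, max_heading, wobble) {
  pos <- start
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- pos
  h <- heading
  for (i in seq_len(n_steps)) {
    h <- h + stats::rnorm(1, 0, wobble)
    h <- max(-max_heading, min(max_heading, h))
    # gentle pull back towards the vertical middle to stay in frame
    if (pos[1] < 0.15 * H) h <- h + 0.08
    if (pos[1] > 0.85 * H) h <- h - 0.08
    pos <- pos + 0.7 * c(sin(h), cos(h))
    if (pos[1] < 2 || pos[1] > H - 1 || pos[2] < 2 || pos[2] > W - 1) break
    pts[i + 1L, ] <- pos
  }
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  px <- round(pts)
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px[keep, , drop = FALSE]
}

rasterize_path <- function(path, radius, H, W) {
  mask <- matrix(FALSE, H, W)
  n <- nrow(path)
  # taper towards the distal tip
  r <- radius * (1 - 0.4 * (seq_len(n) - 1) / max(1, n - 1))
  rmax <- ceiling(max(r))
  off <- expand.grid(dr = -rmax:rmax, dc = -rmax:rmax)
  for (i in seq_len(n)) {
    sel <- off$dr^2 + off$dc^2 <= r[i]^2
    rr <- path[i, 1] + off$dr[sel]
    cc <- path[i, 2] + off$dc[sel]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

#' Wash-in dynamics specification for a synthetic ICG video
#'
#' Describes the dark-to-bright fluorescence wash-in of a vessel tree: each
#' vessel pixel follows a logistic brightness ramp
#' `baseline + (peak - baseline) * sigmoid((t - arrival) / rise_time)`,
#' which has a well-defined plateau for stable-frame selection. The arrival
#' time field either is supplied directly (`arrival_map`) or is derived from a
#' named direction pattern along the tree's centreline arc-length.
#'
#' @param direction One of `"forward"` (arrival increases with arc-length),
#'   `"reverse"`, or `"middle_to_both_sides"` (V-shaped arrival from an
#'   anastomosis point on the main vessel).
#' @param arrival_start,arrival_span Seconds: dye reaches the proximal end at
#'   `arrival_start` and the distal end `arrival_span` later.
#' @param anastomosis Fractional arc position (0-1) of the inflow point for
#'   the middle-to-both-sides pattern.
#' @param rise_time Seconds for the logistic ramp scale.
#' @param peak_brightness,baseline 8-bit intensity units (0-255).
#' @param noise_sd Additive Gaussian sensor noise, intensity units.
#' @param fps Frames per second (25 for the target acquisition).
#' @param duration Video length in seconds.
#' @param arrival_map Optional H x W matrix of per-pixel arrival times (s),
#'   overriding the direction pattern.
#' @return A `wash_in_spec` list.
#' @export
wash_in_spec <- function(direction = "forward", arrival_start = 1,
                         arrival_span = 6, anastomosis = 0.5,
                         rise_time = 0.8, peak_brightness = 180, baseline = 20,
                         noise_sd = 2, fps = 25, duration = 10,
                         arrival_map = NULL) {
  direction <- match.arg(direction, c("forward", "reverse", "middle_to_both_sides"))
  if (fps <= 0) stop("fps must be positive")
  if (baseline >= peak_brightness) stop("baseline must be below peak_brightness")
  if (!is.null(arrival_map) && any(arrival_map < 0, na.rm = TRUE)) {
    stop("arrival times must be nonnegative")
  }
  structure(list(direction = direction, arrival_start = arrival_start,
                 arrival_span = arrival_span, anastomosis = anastomosis,
                 rise_time = rise_time, peak_brightness = peak_brightness,
                 baseline = baseline, noise_sd = noise_sd, fps = fps,
                 duration = duration, arrival_map = arrival_map),
            class = "wash_in_spec")
}

#' Time from dye arrival to (quantised) peak brightness
#'
#' On the logistic wash-in model the 8-bit brightness first reaches its
#' rounded maximum when the sigmoid comes within half an intensity unit of the
#' plateau, i.e. `rise_time * logit(1 - 0.5 / (peak - baseline))` seconds
#' after `arrival`. Ground truth for time-to-peak self-consistency checks.
#'
#' @param spec A [wash_in_spec()].
#' @return Seconds.
#' @export
rise_to_peak <- function(spec) {
  delta <- spec$peak_brightness - spec$baseline
  spec$rise_time * stats::qlogis(1 - 0.5 / delta)
}

# Arc-length coordinate (in px, with child branches offset by their
# attachment arc) for each vessel pixel, by nearest centreline point.
vessel_arc_coords <- function(tree) {
  paths <- list(); arcs <- list()
  base_arc <- numeric(length(tree$centerlines))
  for (i in seq_along(tree$centerlines)) {
    b <- tree$centerlines[[i]]
    step <- sqrt(rowSums(diff(b$path)^2))
    arc_local <- c(0, cumsum(step))
    base_arc[i] <- if (b$parent == 0L) 0 else {
      pb <- tree$centerlines[[b$parent]]
      pstep <- sqrt(rowSums(diff(pb$path)^2))
      base_arc[b$parent] + c(0, cumsum(pstep))[b$attach]
    }
    paths[[i]] <- b$path
    arcs[[i]] <- base_arc[i] + arc_local
  }
  all_pts <- do.call(rbind, paths)
  all_arc <- unlist(arcs)
  idx <- which(tree$mask, arr.ind = TRUE)
  nn <- nearest_point(idx, all_pts)
  list(pixels = idx, arc = all_arc[nn],
       main_arc = arcs[[1]], main_path = paths[[1]])
}

# For each query row (r, c) return the index of the nearest reference row.
# Brute force in blocks; problem sizes here are a few thousand pixels.
nearest_point <- function(query, ref) {
  out <- integer(nrow(query))
  block <- 2048L
  r2 <- rowSums(ref^2)
  for (s in seq(1L, nrow(query), by = block)) {
    e <- min(s + block - 1L, nrow(query))
    q <- query[s:e, , drop = FALSE]
    d <- outer(rowSums(q^2), r2, "+") - 2 * q %*% t(ref)
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

# Per-pixel arrival map (seconds) implementing the three direction patterns.
build_arrival_map <- function(tree, spec) {
  if (!is.null(spec$arrival_map)) {
    am <- spec$arrival_map
    if (!all(dim(am) == tree$shape)) stop("arrival_map shape mismatch")
    return(am)
  }
  vc <- vessel_arc_coords(tree)
  a <- vc$arc
  rng <- range(a)
  frac <- if (diff(rng) > 0) (a - rng[1]) / diff(rng) else rep(0, length(a))
  rel <- switch(spec$direction,
    forward = frac,
    reverse = 1 - frac,
    middle_to_both_sides = {
      m <- spec$anastomosis
      abs(frac - m) / max(m, 1 - m)
    })
  am <- matrix(NA_real_, tree$shape[1], tree$shape[2])
  am[vc$pixels] <- spec$arrival_start + spec$arrival_span * rel
  am
}

#' Generate a synthetic ICG angiography video with ground truth
#'
#' Renders the dark-to-bright wash-in of `tree` under `spec`: vessel pixels
#' follow the logistic ramp from `baseline` to `peak_brightness` starting at
#' their arrival time, background pixels stay at baseline, additive Gaussian
#' noise is applied, and frames are quantised to 8-bit (0-255).
#'
#' @param tree A [generate_vessel_tree()] result.
#' @param spec A [wash_in_spec()].
#' @param seed Integer seed for the sensor noise (bit-identical output for
#'   identical seed and spec).
#' @return List with `video` (an `icg_video`: integer array H x W x T plus
#'   `fps`) and `truth` (a `ground_truth` list: `arrival_map`, `direction`,
#'   `masks`, `spec`).
#' @export
generate_icg_video <- function(tree, spec, seed = 1) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(spec, "wash_in_spec"))
  if (!any(tree$mask)) stop("empty vessel mask")
  n_frames <- round(spec$duration * spec$fps)
  if (n_frames < 2) stop("duration * fps must give at least 2 frames")

  am <- build_arrival_map(tree, spec)
  H <- tree$shape[1]; W <- tree$shape[2]
  vessel <- which(tree$mask)
  arrival <- am[vessel]
  times <- (seq_len(n_frames) - 1) / spec$fps

  frames <- with_seed(seed, {
    out <- array(spec$baseline, dim = c(H, W, n_frames))
    for (f in seq_len(n_frames)) {
      z <- (times[f] - arrival) / spec$rise_time
      fr <- out[, , f]
      fr[vessel] <- spec$baseline +
        (spec$peak_brightness - spec$baseline) * stats::plogis(z)
      if (spec$noise_sd > 0) fr <- fr + stats::rnorm(H * W, 0, spec$noise_sd)
      out[, , f] <- fr
    }
    out
  })
  frames <- round(frames)
  frames[frames < 0] <- 0; frames[frames > 255] <- 255
  storage.mode(frames) <- "integer"

  video <- icg_video(frames, fps = spec$fps)
  truth <- structure(list(arrival_map = am, direction = spec$direction,
                          masks = list(all = tree$mask,
                                       recipient = tree$recipient_mask),
                          spec = spec), class = "ground_truth")
  list(video = video, truth = truth)
}

#' Construct an ICG video object
#'
#' @param frames Numeric or integer array H x W x T of 8-bit intensities.
#' @param fps Frames per second.
#' @return An `icg_video` list with elements `frames` and `fps`.
#' @export
icg_video <- function(frames, fps = 25) {
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3L) stop("frames must be an H x W x T array")
  if (fps <= 0) stop("fps must be positive")
  structure(list(frames = frames, fps = fps), class = "icg_video")
}

#' @export
print.icg_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("ICG video: %d x %d px, %d frames @ %g fps (%.2f s)\n",
              d[1], d[2], d[3], x$fps, d[3] / x$fps))
  invisible(x)
}

#' Number of frames in a video
#' @param video An `icg_video`.
#' @return Integer frame count.
#' @export
n_frames <- function(video) dim(video$frames)[3]

#' Similarity transform as a homography matrix
#'
#' Builds the 3 x 3 matrix of a rotation/scale/translation about the centre of
#' an H x W frame, in (x = column, y = row) coordinates, normalised so the
#' last element is 1.
#'
#' @param rotation Degrees, counter-clockwise in image coordinates.
#' @param scale Isotropic scale factor.
#' @param translation Length-2 numeric `c(dx, dy)` in pixels.
#' @param shape Frame shape `c(H, W)` fixing the rotation centre.
#' @return A `homography` 3 x 3 matrix.
#' @export
similarity_homography <- function(rotation = 0, scale = 1,
                                  translation = c(0, 0), shape) {
  th <- rotation * pi / 180
  cx <- (shape[2] + 1) / 2; cy <- (shape[1] + 1) / 2
  R <- scale * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE)
  t <- c(cx + translation[1], cy + translation[2]) - R %*% c(cx, cy)
  H <- rbind(cbind(R, t), c(0, 0, 1))
  as_homography(H)
}

#' @rdname similarity_homography
#' @param H A 3 x 3 matrix with nonzero last element.
#' @export
as_homography <- function(H) {
  H <- as.matrix(H)
  if (!all(dim(H) == c(3, 3))) stop("homography must be 3 x 3")
  if (abs(H[3, 3]) < 1e-12) stop("homography last element must be nonzero")
  H <- H / H[3, 3]
  if (abs(det(H)) < 1e-12) stop("homography must be invertible")
  structure(H, class = c("homography", "matrix"))
}

#' Apply a homography to (x, y) points
#'
#' @param H A `homography`.
#' @param xy n x 2 matrix of (x, y) positions.
#' @return n x 2 matrix of transformed positions.
#' @export
apply_homography <- function(H, xy) {
  xy <- matrix(xy, ncol = 2)
  p <- cbind(xy, 1) %*% t(unclass(H))
  p[, 1:2, drop = FALSE] / p[, 3]
}

#' Warp an image by a homography
#'
#' Inverse-maps every output pixel through `H` and samples the input, with
#' nearest-neighbour or bilinear interpolation; out-of-frame regions take
#' `fill`. `H` maps input (x, y) to output (x, y), pixel centres at integer
#' coordinates.
#'
#' @param img Numeric matrix (or logical mask).
#' @param H A `homography` (input -> output frame).
#' @param shape Output shape `c(H, W)`; defaults to the input shape.
#' @param interp `"nearest"` or `"bilinear"`.
#' @param fill Fill value outside the input frame.
#' @return Matrix of shape `shape`; logical input gives logical output under
#'   nearest-neighbour interpolation.
#' @export
warp_image <- function(img, H, shape = dim(img), interp = c("nearest", "bilinear"),
                       fill = 0) {
  interp <- match.arg(interp)
  was_logical <- is.logical(img)
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  Hi <- solve(unclass(H))
  out_h <- shape[1]; out_w <- shape[2]
  grid <- cbind(x = rep(seq_len(out_w), each = out_h),
                y = rep(seq_len(out_h), times = out_w), 1)
  src <- grid %*% t(Hi)
  sx <- src[, 1] / src[, 3]; sy <- src[, 2] / src[, 3]
  vals <- if (interp == "nearest") {
    rx <- round(sx); ry <- round(sy)
    ok <- rx >= 1 & rx <= ncol(img) & ry >= 1 & ry <= nrow(img)
    v <- rep(fill, length(sx))
    v[ok] <- img[cbind(ry[ok], rx[ok])]
    v
  } else {
    ok <- sx >= 1 & sx <= ncol(img) & sy >= 1 & sy <= nrow(img)
    x0 <- pmin(floor(sx), ncol(img) - 1); y0 <- pmin(floor(sy), nrow(img) - 1)
    fx <- sx - x0; fy <- sy - y0
    v <- rep(fill, length(sx))
    g <- function(r, c) img[cbind(r, c)]
    i <- which(ok)
    v[i] <- (1 - fx[i]) * (1 - fy[i]) * g(y0[i], x0[i]) +
      fx[i] * (1 - fy[i]) * g(y0[i], x0[i] + 1) +
      (1 - fx[i]) * fy[i] * g(y0[i] + 1, x0[i]) +
      fx[i] * fy[i] * g(y0[i] + 1, x0[i] + 1)
    v
  }
  out <- matrix(vals, out_h, out_w)
  if (was_logical && interp == "nearest") out <- out > 0.5
  out
}

#' Generate a registered preoperative/postoperative video pair
#'
#' The "postoperative" acquisition is the same vessel tree seen under a known
#' similarity transform (microscope repositioning, zoom) with its own,
#' independent wash-in dynamics — e.g. forward flow before bypass and
#' middle-to-both-sides flow after. The true homography mapping preoperative
#' to postoperative coordinates is returned as ground truth.
#'
#' @param tree A [generate_vessel_tree()] result (preoperative geometry).
#' @param spec_pre,spec_post [wash_in_spec()] objects for the two videos.
#' @param transform List with `rotation` (degrees, |rotation| <= 45), `scale`
#'   (in \[0.5, 2\]), `translation` (`c(dx, dy)` px).
#' @param seed Integer seed for the two videos' sensor noise.
#' @return List with `pre`, `post` (both `icg_video`) and `truth`: a
#'   `ground_truth_pair` holding `true_homography`, per-video directions,
#'   arrival maps and masks.
#' @export
generate_pre_post_pair <- function(tree, spec_pre, spec_post,
                                   transform = list(rotation = 0, scale = 1,
                                                    translation = c(0, 0)),
                                   seed = 1) {
  rot <- transform$rotation %||% 0
  sc <- transform$scale %||% 1
  tr <- transform$translation %||% c(0, 0)
  if (abs(rot) > 45) stop("|rotation| must be <= 45 degrees")
  if (sc < 0.5 || sc > 2) stop("scale must lie in [0.5, 2]")

  H <- similarity_homography(rot, sc, tr, tree$shape)
  post_mask <- warp_image(tree$mask, H, tree$shape, "nearest")
  if (sum(post_mask) < 0.1 * sum(tree$mask)) {
    stop("transform maps the vessel (almost) fully outside the frame")
  }
  post_recip <- warp_image(tree$recipient_mask, H, tree$shape, "nearest")
  post_lines <- lapply(tree$centerlines, function(b) {
    xy <- apply_homography(H, b$path[, c(2, 1)])
    p <- round(xy[, c(2, 1)])
    keep <- p[, 1] >= 1 & p[, 1] <= tree$shape[1] &
      p[, 2] >= 1 & p[, 2] <= tree$shape[2]
    b$path <- p[keep, , drop = FALSE]
    b
  })
  post_tree <- structure(list(mask = post_mask, recipient_mask = post_recip & post_mask,
                              centerlines = post_lines, shape = tree$shape),
                         class = "vessel_tree")

  # arrival pattern laid out on the pre geometry, then carried through the
  # transform so post arrival(p) = arrival_pre_pattern(H^-1 p)
  am_post_on_pre <- build_arrival_map(tree, spec_post)
  am_post <- warp_image(ifelse(is.na(am_post_on_pre), -1, am_post_on_pre),
                        H, tree$shape, "nearest", fill = -1)
  am_post[am_post < 0] <- NA_real_
  am_post[!post_mask] <- NA_real_
  am_post[post_mask & is.na(am_post)] <- mean(am_post, na.rm = TRUE)
  spec_post_full <- spec_post
  spec_post_full$arrival_map <- am_post

  pre <- generate_icg_video(tree, spec_pre, seed = seed)
  post <- generate_icg_video(post_tree, spec_post_full, seed = seed + 1L)

  truth <- structure(list(
    true_homography = H,
    direction = list(pre = spec_pre$direction, post = spec_post$direction),
    arrival_map = list(pre = pre$truth$arrival_map, post = am_post),
    masks = list(pre = list(all = tree$mask, recipient = tree$recipient_mask),
                 post = list(all = post_mask, recipient = post_tree$recipient_mask)),
    post_tree = post_tree
  ), class = "ground_truth_pair")

  list(pre = pre$video, post = post$video, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
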