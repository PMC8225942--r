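# Preoperative -> postoperative vessel-map registration: ratio-test
# descriptor matching, RANSAC homography estimation, and the overlap /
# correspondence-count success rule.

#' Match descriptors with Lowe's ratio test
#'
#' For each descriptor in `descA` (the moving image), finds the nearest and
#' second-nearest neighbours in `descB` by Euclidean distance and keeps the
#' match only when `d1 / d2 < ratio`. When `descB` holds a single candidate
#' no second neighbour exists, the ratio is undefined, and the match is
#' rejected.
#'
#' @param descA,descB Descriptor matrices (rows = keypoints, 128 columns).
#' @param ratio Ratio threshold in (0, 1\]; default 0.8.
#' @return A `match_set` data frame with columns `index_moving`,
#'   `index_fixed`, `distance`; each moving keypoint appears at most once.
#' @export
match_ratio_test <- function(descA, descB, ratio = 0.8) {
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  empty <- structure(data.frame(index_moving = integer(0),
                                index_fixed = integer(0),
                                distance = numeric(0)),
                     ratio = ratio, class = c("match_set", "data.frame"))
  if (is.null(descA) || is.null(descB) ||
      nrow(descA) == 0 || nrow(descB) < 2) return(empty)
  # squared Euclidean distances via the inner-product expansion
  d2 <- outer(rowSums(descA^2), rowSums(descB^2), "+") -
    2 * descA %*% t(descB)
  d2[d2 < 0] <- 0
  nn1 <- max.col(-d2, ties.method = "first")
  d1 <- sqrt(d2[cbind(seq_len(nrow(d2)), nn1)])
  d2m <- d2; d2m[cbind(seq_len(nrow(d2)), nn1)] <- Inf
  nn2 <- max.col(-d2m, ties.method = "first")
  dsecond <- sqrt(d2m[cbind(seq_len(nrow(d2m)), nn2)])
  # d2 = 0 forces d1 = 0 too (exact ties): ratio undefined, treated as 1
  keep <- dsecond > 0 & d1 / dsecond < ratio
  structure(data.frame(index_moving = which(keep),
                       index_fixed = nn1[keep],
                       distance = d1[keep]),
            ratio = ratio, class = c("match_set", "data.frame"))
}

# Normalised direct linear transform for >= 4 point correspondences.
dlt_homography <- function(src, dst) {
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums((p - rep(ctr, each = nrow(p)))^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3,
                byrow = TRUE)
    list(p = cbind(p, 1) %*% t(T), T = T)
  }
  a <- norm_pts(src); b <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- a$p[i, ]; x <- b$p[i, 1]; y <- b$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, x * X)
    A[2 * i, ] <- c(0, 0, 0, -X, y * X)
  }
  sv <- svd(A, nu = 0, nv = 9)
  h <- sv$v[, 9]
  Hn <- matrix(h, 3, byrow = TRUE)
  H <- solve(b$T) %*% Hn %*% a$T
  if (abs(H[3, 3]) < 1e-12) return(NULL)
  H / H[3, 3]
}

# Closed-form least-squares similarity fit (rotation + isotropic scale +
# translation; Umeyama's method).
similarity_fit <- function(src, dst) {
  if (nrow(src) < 2) return(NULL)
  mc <- colMeans(src); dc <- colMeans(dst)
  X <- sweep(src, 2, mc); Y <- sweep(dst, 2, dc)
  S <- t(Y) %*% X / nrow(src)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- sum(X^2) / nrow(src)
  if (varx < 1e-12) return(NULL)
  s <- sum(diag(D %*% diag(sv$d))) / varx
  t_ <- dc - s * R %*% mc
  rbind(cbind(s * R, t_), c(0, 0, 1))
}

# Least-squares affine fit (perspective row fixed at (0, 0, 1)).
affine_homography <- function(src, dst) {
  if (nrow(src) < 3) return(NULL)
  A <- cbind(src, 1)
  fit <- tryCatch(qr.solve(A, dst), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  rbind(t(fit), c(0, 0, 1))
}

collinear_set <- function(p, tol = 1e-6) {
  # all points on one line => rank of centred coordinates < 2
  q <- sweep(p, 2, colMeans(p))
  sv <- svd(q, nu = 0, nv = 0)$d
  sv[2] < tol * max(sv[1], 1)
}

#' Estimate a homography from matched keypoints
#'
#' Robust RANSAC fit of a 3 x 3 projective transform mapping moving-image
#' keypoints onto fixed-image keypoints, followed by a normalised-DLT
#' least-squares refit on the inlier set. Needs at least 4 matches;
#' degenerate (collinear) configurations fail.
#'
#' @param matches A [match_ratio_test()] result (or data frame with
#'   `index_moving`, `index_fixed`).
#' @param keypointsA,keypointsB Keypoint data frames with `x`, `y` columns
#'   (moving and fixed image, respectively).
#' @param inlier_thr RANSAC reprojection-error threshold in pixels.
#' @param iterations Number of RANSAC samples.
#' @param seed Seed for the RANSAC sampler (deterministic fit).
#' @param model `"projective"` (8 degrees of freedom), `"affine"` (6; the
#'   perspective row fixed at (0, 0, 1)) or `"similarity"` (4: in-plane
#'   rotation, isotropic zoom, translation). Constrained models extrapolate
#'   far more stably when the matched points cover only part of the frame,
#'   which is the vessel-map situation, and are special cases of the
#'   homography; the similarity is exactly the change a repositioned,
#'   refocused microscope induces.
#' @return A `homography` with attributes `inliers` (row indices of
#'   `matches`) and `rmse` (inlier reprojection RMSE).
#' @export
estimate_homography <- function(matches, keypointsA, keypointsB,
                                inlier_thr = 3, iterations = 2000,
                                seed = 0,
                                model = c("projective", "affine",
                                          "similarity")) {
  model <- match.arg(model)
  fit_fun <- switch(model, projective = dlt_homography,
                    affine = affine_homography, similarity = similarity_fit)
  n <- nrow(matches)
  if (n < 4) stop("need at least 4 matches to estimate a homography")
  src <- cbind(keypointsA$x[matches$index_moving],
               keypointsA$y[matches$index_moving])
  dst <- cbind(keypointsB$x[matches$index_fixed],
               keypointsB$y[matches$index_fixed])
  if (collinear_set(src) || collinear_set(dst)) {
    stop("degenerate configuration: matched points are collinear")
  }

  best_inl <- integer(0)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      s <- sample.int(n, 4)
      if (collinear_set(src[s, , drop = FALSE]) ||
          collinear_set(dst[s, , drop = FALSE])) next
      H <- tryCatch(as_homography(fit_fun(src[s, , drop = FALSE],
                                          dst[s, , drop = FALSE])),
                    error = function(e) NULL)
      if (is.null(H)) next
      pr <- apply_homography(H, src)
      err <- sqrt(rowSums((pr - dst)^2))
      inl <- which(err < inlier_thr)
      if (length(inl) > length(best_inl)) best_inl <- inl
    }
  })
  if (length(best_inl) < 4) {
    stop("RANSAC failed: fewer than 4 consistent matches")
  }
  # iterative least-squares refit with an annealed inlier threshold: the
  # final fit uses only the most precisely localised correspondences
  H <- NULL
  for (thr in c(inlier_thr, 0.75 * inlier_thr, 0.5 * inlier_thr,
                0.4 * inlier_thr)) {
    for (round in 1:10) {
      Hc <- fit_fun(src[best_inl, , drop = FALSE],
                    dst[best_inl, , drop = FALSE])
      if (is.null(Hc)) break
      Hc <- as_homography(Hc)
      H <- Hc
      err <- sqrt(rowSums((apply_homography(H, src) - dst)^2))
      inl <- which(err < thr)
      if (length(inl) < max(4, ceiling(0.25 * length(best_inl))) ||
          identical(inl, best_inl)) break
      best_inl <- inl
    }
  }
  if (is.null(H)) stop("degenerate inlier configuration")
  pr <- apply_homography(H, src[best_inl, , drop = FALSE])
  rmse <- sqrt(mean(rowSums((pr - dst[best_inl, , drop = FALSE])^2)))
  attr(H, "inliers") <- best_inl
  attr(H, "rmse") <- rmse
  H
}

#' Registration success rule
#'
#' A registration counts as successful when the warped moving vessel mask
#' overlaps the fixed vessel mask in at least `overlap_min` of the vessel
#' pixels (overlap fraction = intersection over the smaller vessel area) and
#' at least `min_matches` SIFT correspondences support it.
#'
#' @param warped_mask,fixed_mask Logical masks in the fixed frame.
#' @param matches A match set (or anything with `nrow()`).
#' @param overlap_min Minimum overlap fraction (default 0.35).
#' @param min_matches Minimum number of correspondences (default 10).
#' @return List: `success`, `overlap`, `n_matches`, `n_warped`, `n_fixed`.
#' @export
registration_success <- function(warped_mask, fixed_mask, matches,
                                 overlap_min = 0.35, min_matches = 10) {
  a <- sum(warped_mask); b <- sum(fixed_mask)
  n_matches <- nrow(matches)
  if (a == 0 || b == 0) {
    return(list(success = FALSE, overlap = 0, n_matches = n_matches,
                n_warped = a, n_fixed = b,
                note = "empty vessel mask"))
  }
  overlap <- sum(warped_mask & fixed_mask) / min(a, b)
  list(success = overlap >= overlap_min && n_matches >= min_matches,
       overlap = overlap, n_matches = n_matches, n_warped = a, n_fixed = b)
}

# Polish a similarity transform by maximising the intensity correlation of
# the warped moving image with the fixed image.
refine_similarity <- function(moving, fixed, H0) {
  A <- unclass(H0)[1:2, 1:2]
  s0 <- sqrt(abs(det(A)))
  th0 <- atan2(A[2, 1], A[1, 1])
  t0 <- unclass(H0)[1:2, 3]
  fx_v <- as.vector(fixed)
  build <- function(p) {
    R <- exp(p[2]) * matrix(c(cos(p[1]), -sin(p[1]), sin(p[1]), cos(p[1])),
                            2, byrow = TRUE)
    as_homography(rbind(cbind(R, p[3:4]), c(0, 0, 1)))
  }
  obj <- function(p) {
    w <- warp_image(moving, build(p), dim(fixed), "bilinear")
    v <- stats::var(as.vector(w))
    if (v < 1e-12) return(1)
    -stats::cor(as.vector(w), fx_v)
  }
  fit <- stats::optim(c(th0, log(s0), t0), obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-8))
  H <- build(fit$par)
  attr(H, "inliers") <- attr(H0, "inliers")
  attr(H, "rmse") <- attr(H0, "rmse")
  attr(H, "correlation") <- -fit$value
  H
}

#' Two-colour overlay of a registered image pair
#'
#' Warps the moving image into the fixed frame by `H` and renders the moving
#' image in the red channel and the fixed image in the green channel;
#' out-of-frame regions stay at the background value 0.
#'
#' @param moving,fixed Numeric matrices (intensities in any common range).
#' @param H A `homography` mapping moving to fixed coordinates.
#' @return H x W x 3 RGB array in \[0, 1\].
#' @export
fuse_images <- function(moving, fixed, H) {
  top <- max(max(moving), max(fixed), 1)
  wm <- warp_image(moving / top, H, dim(fixed), "bilinear", fill = 0)
  out <- array(0, dim = c(dim(fixed), 3))
  out[, , 1] <- pmin(pmax(wm, 0), 1)
  out[, , 2] <- pmin(pmax(fixed / top, 0), 1)
  out
}

#' Register a moving vessel mask to a fixed vessel mask
#'
#' The full registration stage: both masks are lightly Gaussian-blurred (so
#' the difference-of-Gaussian detector finds structure on binary input), SIFT
#' keypoints are extracted and matched with the ratio test, a homography is
#' estimated by RANSAC, the moving mask is warped, and the success rule is
#' evaluated.
#'
#' @param moving_mask,fixed_mask Logical vessel masks (moving =
#'   preoperative, fixed = postoperative).
#' @param ratio Ratio-test threshold (default 0.8).
#' @param blur_sigma Pre-detection Gaussian blur in pixels (default 2).
#' @param overlap_min,min_matches Success thresholds (see
#'   [registration_success()]).
#' @param model Transform model passed to [estimate_homography()]; the
#'   default `"similarity"` suits microscope repositioning between
#'   acquisitions.
#' @param refine Intensity-based polish of the keypoint estimate: when the
#'   model is `"similarity"`, its four parameters are re-optimised to
#'   maximise the correlation between the warped moving map and the fixed
#'   map (Nelder-Mead), removing the small localisation bias that blurring
#'   binary masks at a fixed sigma introduces across scale changes.
#' @param seed RANSAC seed.
#' @return List: `homography` (or `NULL` on failure), `matches`,
#'   `keypoints_moving`, `keypoints_fixed`, `warped_mask`, `metrics`
#'   (the [registration_success()] record plus keypoint counts), `overlay`.
#' @export
register_pair <- function(moving_mask, fixed_mask, ratio = 0.8,
                          blur_sigma = 2, overlap_min = 0.35,
                          min_matches = 10, model = "similarity",
                          refine = TRUE, seed = 0) {
  mv <- gauss_smooth(matrix(as.numeric(moving_mask), nrow(moving_mask)),
                     blur_sigma)
  fx <- gauss_smooth(matrix(as.numeric(fixed_mask), nrow(fixed_mask)),
                     blur_sigma)
  # blurred binary maps have strong contrast: a permissive DoG threshold
  # yields a denser, better-spread keypoint set
  sa <- detect_sift(mv, contrast_thr = 0.02)
  sb <- detect_sift(fx, contrast_thr = 0.02)
  matches <- match_ratio_test(sa$descriptors, sb$descriptors, ratio)
  H <- tryCatch(
    estimate_homography(matches, sa$keypoints, sb$keypoints, seed = seed,
                        model = model),
    error = function(e) NULL)
  if (!is.null(H) && refine && model == "similarity") {
    H <- refine_similarity(mv, fx, H)
  }
  warped <- if (is.null(H)) {
    matrix(FALSE, nrow(fixed_mask), ncol(fixed_mask))
  } else {
    warp_image(moving_mask, H, dim(fixed_mask), "nearest")
  }
  metrics <- registration_success(warped, fixed_mask, matches,
                                  overlap_min, min_matches)
  metrics$n_keypoints_moving <- nrow(sa$keypoints)
  metrics$n_keypoints_fixed <- nrow(sb$keypoints)
  if (is.null(H)) metrics$success <- FALSE
  overlay <- if (is.null(H)) NULL else fuse_images(mv, fx, H)
  list(homography = H, matches = matches,
       keypoints_moving = sa$keypoints, keypoints_fixed = sb$keypoints,
       warped_mask = warped, metrics = metrics, overlay = overlay)
}
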