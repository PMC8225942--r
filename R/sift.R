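# Scale-invariant feature transform: difference-of-Gaussian keypoints with
# gradient-orientation histograms and 128-dimensional descriptors. Written
# against the standard formulation (scale-space extrema, subpixel refinement,
# edge rejection, 4x4x8 descriptor grid with trilinear binning).

#' Detect SIFT keypoints and descriptors
#'
#' Difference-of-Gaussian extrema over a Gaussian scale-space pyramid give
#' keypoint locations and scales; a 36-bin gradient-orientation histogram
#' around each keypoint gives one (or more) dominant orientations; the
#' descriptor is the classical 4 x 4 spatial grid of 8-bin orientation
#' histograms, trilinearly interpolated, Gaussian-weighted, L2-normalised
#' with 0.2 clipping. Fully deterministic for a fixed input.
#'
#' @param image Numeric matrix; any range (normalised internally). A blank
#'   (constant) image yields zero keypoints.
#' @param n_scales Scales per octave at which extrema are sought (default 3).
#' @param sigma0 Base blur of the first scale (default 1.6).
#' @param contrast_thr Reject extrema with refined |DoG| below this (on unit
#'   intensity scale; default 0.03).
#' @param edge_thr Principal-curvature ratio threshold for rejecting
#'   edge-like responses (default 10).
#' @param double_size Upsample the image 2x before the first octave to keep
#'   small-scale keypoints (default TRUE).
#' @return List with `keypoints` (data frame: `x`, `y` subpixel position in
#'   input coordinates (x = column, y = row), `scale`, `orientation` degrees,
#'   `response`) and `descriptors` (n x 128 matrix, rows L2-normalised).
#' @export
detect_sift <- function(image, n_scales = 3, sigma0 = 1.6,
                        contrast_thr = 0.03, edge_thr = 10,
                        double_size = TRUE) {
  img <- as.matrix(image) * 1.0
  rng <- range(img)
  empty <- list(keypoints = data.frame(x = numeric(0), y = numeric(0),
                                       scale = numeric(0),
                                       orientation = numeric(0),
                                       response = numeric(0)),
                descriptors = matrix(0, 0, 128))
  if (diff(rng) == 0) return(empty)
  img <- (img - rng[1]) / diff(rng)

  sigma_init <- 0.5
  if (double_size) {
    img <- resize_bilinear(img, dim(img) * 2L)
    sigma_init <- 1.0
  }
  base_scale <- if (double_size) 0.5 else 1.0
  img <- gauss_smooth(img, sqrt(max(sigma0^2 - sigma_init^2, 0.01)))

  k <- 2^(1 / n_scales)
  n_oct <- max(1L, floor(log2(min(dim(img)))) - 3L)
  kps <- list(); descs <- list()

  oct_img <- img
  for (o in seq_len(n_oct)) {
    G <- vector("list", n_scales + 3)
    G[[1]] <- oct_img
    sig_abs <- sigma0 * k^(0:(n_scales + 2))
    for (i in seq_len(n_scales + 2)) {
      inc <- sqrt(sig_abs[i + 1]^2 - sig_abs[i]^2)
      G[[i + 1]] <- gauss_smooth(G[[i]], inc)
    }
    D <- lapply(seq_len(n_scales + 2), function(i) G[[i + 1]] - G[[i]])

    cand <- find_dog_extrema(D, n_scales, 0.5 * contrast_thr)
    if (nrow(cand) > 0) {
      ref <- refine_keypoints(D, cand, n_scales, contrast_thr, edge_thr)
      if (nrow(ref) > 0) {
        grads <- vector("list", length(G))
        for (i in unique(ref$layer)) {
          # gradients of the Gaussian image at the keypoint's scale
          gi <- G[[i + 1]]
          grads[[i]] <- image_gradients(gi)
        }
        res <- describe_keypoints(ref, grads, sig_abs, n_scales)
        if (nrow(res$keypoints) > 0) {
          kp <- res$keypoints
          # octave decimation keeps pixels 1, 3, 5, ...: octave-o index j sits
          # at parent index 2j - 1, so position maps affinely, not linearly
          om <- 2^(o - 1)
          kp$x <- om * kp$x - (om - 1); kp$y <- om * kp$y - (om - 1)
          kp$scale <- kp$scale * om
          if (double_size) {
            # doubled-image index j corresponds to original j / 2 + 1/4
            kp$x <- kp$x / 2 + 0.25; kp$y <- kp$y / 2 + 0.25
            kp$scale <- kp$scale * 0.5
          }
          kps[[length(kps) + 1]] <- kp
          descs[[length(descs) + 1]] <- res$descriptors
        }
      }
    }
    nxt <- G[[n_scales + 1]]  # blur 2*sigma0 relative to octave base
    if (min(dim(nxt)) < 16) break
    oct_img <- nxt[seq(1, nrow(nxt), 2), seq(1, ncol(nxt), 2)]
  }

  if (length(kps) == 0) return(empty)
  keypoints <- do.call(rbind, kps)
  descriptors <- do.call(rbind, descs)
  rownames(descriptors) <- NULL
  list(keypoints = keypoints, descriptors = descriptors)
}

image_gradients <- function(g) {
  H <- nrow(g); W <- ncol(g)
  dx <- (g[, pmin(seq_len(W) + 1, W), drop = FALSE] -
           g[, pmax(seq_len(W) - 1, 1), drop = FALSE]) / 2
  dy <- (g[pmin(seq_len(H) + 1, H), , drop = FALSE] -
           g[pmax(seq_len(H) - 1, 1), , drop = FALSE]) / 2
  list(mag = sqrt(dx^2 + dy^2), ang = atan2(dy, dx))
}

# Strict 26-neighbourhood extrema of the DoG stack, away from borders.
find_dog_extrema <- function(D, n_scales, prefilter) {
  out <- list()
  H <- nrow(D[[1]]); W <- ncol(D[[1]])
  if (H < 10 || W < 10) return(data.frame(r = integer(0), c = integer(0),
                                          layer = integer(0)))
  shift9 <- function(m, with_center = TRUE) {
    res <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (!with_center && dr == 0 && dc == 0) next
      res[[length(res) + 1]] <-
        m[pmin(pmax(seq_len(H) + dr, 1), H), pmin(pmax(seq_len(W) + dc, 1), W),
          drop = FALSE]
    }
    res
  }
  for (l in 2:(n_scales + 1)) {
    cur <- D[[l]]
    nb_prev <- shift9(D[[l - 1]]); nb_next <- shift9(D[[l + 1]])
    nb_cur <- shift9(cur, with_center = FALSE)
    all_nb <- c(nb_prev, nb_next, nb_cur)
    mx <- Reduce(pmax, all_nb); mn <- Reduce(pmin, all_nb)
    is_ext <- (abs(cur) > prefilter) & ((cur > mx) | (cur < mn))
    is_ext[c(1:4, (H - 3):H), ] <- FALSE
    is_ext[, c(1:4, (W - 3):W)] <- FALSE
    if (any(is_ext)) {
      ij <- which(is_ext, arr.ind = TRUE)
      out[[length(out) + 1]] <- data.frame(r = ij[, 1], c = ij[, 2], layer = l)
    }
  }
  if (length(out) == 0) data.frame(r = integer(0), c = integer(0),
                                   layer = integer(0))
  else do.call(rbind, out)
}

# Subpixel/subscale quadratic refinement with contrast and edge rejection.
refine_keypoints <- function(D, cand, n_scales, contrast_thr, edge_thr) {
  H <- nrow(D[[1]]); W <- ncol(D[[1]])
  keep <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand$r[i]; c <- cand$c[i]; l <- cand$layer[i]
    ok <- FALSE; off <- c(0, 0, 0); val <- 0
    for (iter in 1:5) {
      if (r < 2 || r > H - 1 || c < 2 || c > W - 1 ||
          l < 2 || l > n_scales + 1) break
      d0 <- D[[l]]; dm <- D[[l - 1]]; dp <- D[[l + 1]]
      g <- c((d0[r, c + 1] - d0[r, c - 1]) / 2,   # d/dx
             (d0[r + 1, c] - d0[r - 1, c]) / 2,   # d/dy
             (dp[r, c] - dm[r, c]) / 2)           # d/ds
      dxx <- d0[r, c + 1] + d0[r, c - 1] - 2 * d0[r, c]
      dyy <- d0[r + 1, c] + d0[r - 1, c] - 2 * d0[r, c]
      dss <- dp[r, c] + dm[r, c] - 2 * d0[r, c]
      dxy <- (d0[r + 1, c + 1] - d0[r + 1, c - 1] -
                d0[r - 1, c + 1] + d0[r - 1, c - 1]) / 4
      dxs <- (dp[r, c + 1] - dp[r, c - 1] - dm[r, c + 1] + dm[r, c - 1]) / 4
      dys <- (dp[r + 1, c] - dp[r - 1, c] - dm[r + 1, c] + dm[r - 1, c]) / 4
      Hm <- matrix(c(dxx, dxy, dxs, dxy, dyy, dys, dxs, dys, dss), 3)
      sol <- tryCatch(solve(Hm, -g), error = function(e) NULL)
      if (is.null(sol)) break
      off <- sol
      if (all(abs(off) < 0.5)) {
        val <- d0[r, c] + 0.5 * sum(g * off)
        # edge rejection on the 2x2 spatial Hessian
        tr <- dxx + dyy; det2 <- dxx * dyy - dxy^2
        if (abs(val) >= contrast_thr && det2 > 0 &&
            tr^2 / det2 < (edge_thr + 1)^2 / edge_thr) ok <- TRUE
        break
      }
      c <- c + round(off[1]); r <- r + round(off[2]); l <- l + round(off[3])
    }
    if (ok) {
      keep[[length(keep) + 1]] <- data.frame(
        x = c + off[1], y = r + off[2], layer = l, ds = off[3],
        response = val)
    }
  }
  if (length(keep) == 0) {
    data.frame(x = numeric(0), y = numeric(0), layer = integer(0),
               ds = numeric(0), response = numeric(0))
  } else do.call(rbind, keep)
}

# Orientation assignment and descriptor extraction within one octave.
describe_keypoints <- function(ref, grads, sig_abs, n_scales) {
  kp_rows <- list(); desc_rows <- list()
  for (i in seq_len(nrow(ref))) {
    l <- ref$layer[i]
    gr <- grads[[l]]
    H <- nrow(gr$mag); W <- ncol(gr$mag)
    sig_oct <- sig_abs[l] * 2^(ref$ds[i] / n_scales)
    x <- ref$x[i]; y <- ref$y[i]

    oris <- keypoint_orientations(gr, x, y, sig_oct, H, W)
    for (th in oris) {
      d <- sift_descriptor(gr, x, y, sig_oct, th, H, W)
      if (is.null(d)) next
      kp_rows[[length(kp_rows) + 1]] <- data.frame(
        x = x, y = y, scale = sig_oct, orientation = th * 180 / pi,
        response = ref$response[i], layer = l)
      desc_rows[[length(desc_rows) + 1]] <- d
    }
  }
  if (length(kp_rows) == 0) {
    list(keypoints = data.frame(), descriptors = matrix(0, 0, 128))
  } else {
    list(keypoints = do.call(rbind, kp_rows),
         descriptors = do.call(rbind, desc_rows))
  }
}

keypoint_orientations <- function(gr, x, y, sig_oct, H, W) {
  sw <- 1.5 * sig_oct
  rad <- max(2L, round(3 * sw))
  r0 <- max(2, round(y) - rad); r1 <- min(H - 1, round(y) + rad)
  c0 <- max(2, round(x) - rad); c1 <- min(W - 1, round(x) + rad)
  if (r1 <= r0 || c1 <= c0) return(numeric(0))
  rr <- r0:r1; cc <- c0:c1
  dy2 <- (rr - y)^2; dx2 <- (cc - x)^2
  wgt <- exp(-(outer(dy2, dx2, "+")) / (2 * sw^2))
  m <- gr$mag[rr, cc] * wgt
  a <- gr$ang[rr, cc] %% (2 * pi)
  bin <- floor(a / (2 * pi) * 36) %% 36
  h <- as.numeric(rowsum(as.vector(m), as.vector(bin) + 1L,
                         reorder = TRUE))
  hist36 <- numeric(36)
  hist36[sort(unique(as.vector(bin))) + 1L] <- h
  for (pass in 1:2) {
    hist36 <- (c(hist36[36], hist36[-36]) + hist36 +
                 c(hist36[-1], hist36[1])) / 3
  }
  mx <- max(hist36)
  if (mx <= 0) return(numeric(0))
  out <- numeric(0)
  for (b in 1:36) {
    lft <- hist36[if (b == 1) 36 else b - 1]
    rgt <- hist36[if (b == 36) 1 else b + 1]
    if (hist36[b] > lft && hist36[b] >= rgt && hist36[b] >= 0.8 * mx) {
      denom <- lft - 2 * hist36[b] + rgt
      offs <- if (abs(denom) > 1e-12) 0.5 * (lft - rgt) / denom else 0
      out <- c(out, ((b - 1 + offs + 0.5) / 36) * 2 * pi)
    }
  }
  out
}

sift_descriptor <- function(gr, x, y, sig_oct, theta, H, W) {
  d <- 4L; nb <- 8L
  hist_width <- 3 * sig_oct
  rad <- round(hist_width * sqrt(2) * (d + 1) / 2)
  r0 <- max(2, round(y) - rad); r1 <- min(H - 1, round(y) + rad)
  c0 <- max(2, round(x) - rad); c1 <- min(W - 1, round(x) + rad)
  if (r1 - r0 < 2 || c1 - c0 < 2) return(NULL)
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - y, length(rr), length(cc))
  dx <- matrix(cc - x, length(rr), length(cc), byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  # rotate into the keypoint frame and express in subregion units
  xr <- (ct * dx + st * dy) / hist_width
  yr <- (-st * dx + ct * dy) / hist_width
  rbin <- yr + d / 2 - 0.5
  cbin <- xr + d / 2 - 0.5
  inside <- rbin > -1 & rbin < d & cbin > -1 & cbin < d
  if (!any(inside)) return(NULL)
  mag <- gr$mag[rr, cc]
  ang <- (gr$ang[rr, cc] - theta) %% (2 * pi)
  w <- mag * exp(-(xr^2 + yr^2) / (2 * (d / 2)^2))

  rb <- rbin[inside]; cb <- cbin[inside]
  ob <- ang[inside] / (2 * pi) * nb
  wv <- w[inside]
  r_lo <- floor(rb); c_lo <- floor(cb); o_lo <- floor(ob)
  fr <- rb - r_lo; fc <- cb - c_lo; fo <- ob - o_lo

  acc <- numeric(d * d * nb)
  for (dr in 0:1) for (dc in 0:1) for (do_ in 0:1) {
    ri <- r_lo + dr; ci <- c_lo + dc
    oi <- (o_lo + do_) %% nb
    wt <- wv * (if (dr == 1) fr else 1 - fr) *
      (if (dc == 1) fc else 1 - fc) *
      (if (do_ == 1) fo else 1 - fo)
    ok <- ri >= 0 & ri < d & ci >= 0 & ci < d & wt > 0
    if (!any(ok)) next
    idx <- (ri[ok] * d + ci[ok]) * nb + oi[ok] + 1L
    sums <- rowsum(wt[ok], idx)
    acc[as.integer(rownames(sums))] <- acc[as.integer(rownames(sums))] + sums
  }
  nrm <- sqrt(sum(acc^2))
  if (nrm <= 1e-12) return(NULL)
  acc <- pmin(acc / nrm, 0.2)
  acc / sqrt(sum(acc^2))
}
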