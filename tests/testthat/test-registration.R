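test_that("SIFT returns 128-d descriptors, none on blank input", {
  blank <- matrix(0.5, 64, 64)
  res <- detect_sift(blank)
  expect_equal(nrow(res$keypoints), 0)

  tree <- generate_vessel_tree(3, c(128, 128), 4)
  img <- icgflow:::gauss_smooth(matrix(as.numeric(tree$mask), 128), 2)
  s <- detect_sift(img)
  expect_gt(nrow(s$keypoints), 5)
  expect_equal(ncol(s$descriptors), 128)
  # rows are L2-normalised (up to the 0.2 clipping renormalisation)
  expect_equal(unname(sqrt(rowSums(s$descriptors^2))),
               rep(1, nrow(s$descriptors)), tolerance = 1e-9)
  # deterministic
  s2 <- detect_sift(img)
  expect_identical(s$descriptors, s2$descriptors)
})

test_that("rotated vessel maps yield at least 10 ratio-test survivors", {
  tree <- generate_vessel_tree(4, c(192, 192), 5)
  H <- similarity_homography(15, 1, c(0, 0), c(192, 192))
  img <- icgflow:::gauss_smooth(matrix(as.numeric(tree$mask), 192), 2)
  rot <- icgflow:::gauss_smooth(
    matrix(as.numeric(warp_image(tree$mask, H, c(192, 192), "nearest")), 192), 2)
  sa <- detect_sift(img); sb <- detect_sift(rot)
  m <- match_ratio_test(sa$descriptors, sb$descriptors, 0.8)
  expect_gte(nrow(m), 10)
})

test_that("ratio-test matching equals a brute-force scan and honours edge cases", {
  set.seed(5)
  b <- matrix(runif(80 * 128), 80); b <- b / sqrt(rowSums(b^2))
  # half the queries are noisy copies of reference descriptors (matchable),
  # half are unrelated (high-dimensional noise fails the ratio test)
  a <- rbind(b[1:25, ] + matrix(rnorm(25 * 128, 0, 0.02), 25),
             matrix(runif(25 * 128), 25))
  a <- a / sqrt(rowSums(a^2))
  m <- match_ratio_test(a, b, 0.9)

  # brute force oracle
  kept <- list()
  for (i in 1:50) {
    d <- sqrt(colSums((t(b) - a[i, ])^2))
    o <- order(d)
    if (d[o[2]] > 0 && d[o[1]] / d[o[2]] < 0.9) {
      kept[[length(kept) + 1]] <- c(i, o[1], d[o[1]])
    }
  }
  oracle <- do.call(rbind, kept)
  expect_gt(nrow(oracle), 10)
  expect_equal(nrow(m), nrow(oracle))
  expect_equal(m$index_moving, oracle[, 1])
  expect_equal(m$index_fixed, oracle[, 2])
  expect_equal(m$distance, oracle[, 3], tolerance = 1e-12)

  # each moving keypoint at most once
  expect_false(any(duplicated(m$index_moving)))
  # invariance to permutation of descA rows (as a set of matches)
  p <- sample(nrow(a))
  mp <- match_ratio_test(a[p, ], b, 0.9)
  expect_setequal(paste(p[mp$index_moving], mp$index_fixed),
                  paste(m$index_moving, m$index_fixed))

  # exact duplicate with a distant second neighbour -> kept with distance 0
  q <- rbind(b[1, ])
  m1 <- match_ratio_test(q, b, 0.8)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$distance, 0)
  # two equidistant neighbours -> ratio 1 -> rejected
  bb <- rbind(b[1, ], b[1, ])
  expect_equal(nrow(match_ratio_test(q, bb, 0.8)), 0)
  # a single candidate has no second neighbour -> rejected
  expect_equal(nrow(match_ratio_test(q, rbind(b[1, ]), 0.8)), 0)
})

test_that("homography estimation recovers exact transforms from noiseless points", {
  set.seed(7)
  kpA <- data.frame(x = runif(20, 10, 100), y = runif(20, 10, 100))
  H_true <- similarity_homography(10, 1.2, c(5, -3), c(128, 128))
  pB <- apply_homography(H_true, cbind(kpA$x, kpA$y))
  kpB <- data.frame(x = pB[, 1], y = pB[, 2])
  matches <- data.frame(index_moving = 1:20, index_fixed = 1:20)

  H <- estimate_homography(matches, kpA, kpB, seed = 1)
  pred <- apply_homography(H, cbind(kpA$x, kpA$y))
  expect_lt(max(abs(pred - pB)), 1e-6)

  # identity-related points give the identity matrix
  Hi <- estimate_homography(matches, kpA, kpA, seed = 1)
  expect_equal(unclass(Hi), diag(3), tolerance = 1e-6, ignore_attr = TRUE)

  # preconditions
  expect_error(estimate_homography(matches[1:3, ], kpA, kpB), "at least 4")
  kc <- data.frame(x = 1:8, y = 2 * (1:8) + 1)
  expect_error(estimate_homography(data.frame(index_moving = 1:8,
                                              index_fixed = 1:8), kc, kc),
               "collinear")
})

test_that("the success rule fires exactly at the printed thresholds", {
  mk <- function(n, offset = 0) {
    m <- matrix(FALSE, 40, 200)
    m[1, offset + seq_len(n)] <- TRUE
    m
  }
  matches_n <- function(n) data.frame(index_moving = seq_len(n),
                                      index_fixed = seq_len(n))
  # overlap = intersection / min area
  fixed <- mk(100)
  expect_true(registration_success(mk(100, 60), fixed, matches_n(12))$overlap == 0.4)
  expect_true(registration_success(mk(100, 60), fixed, matches_n(12))$success)
  expect_false(registration_success(mk(100, 66), fixed, matches_n(50))$success) # 0.34
  expect_false(registration_success(mk(100, 10), fixed, matches_n(9))$success)  # 9 matches
  expect_true(registration_success(mk(100, 65), fixed, matches_n(10))$success)  # exactly 0.35 / 10
  r <- registration_success(matrix(FALSE, 4, 4), fixed, matches_n(20))
  expect_false(r$success)
})

test_that("image fusion overlays the warped moving image", {
  img <- matrix(runif(64 * 64), 64)
  ov <- fuse_images(img, img, as_homography(diag(3)))
  expect_equal(ov[, , 1], ov[, , 2], tolerance = 1e-9)
  # out-of-frame regions rendered as background
  Ht <- similarity_homography(0, 1, c(30, 0), c(64, 64))
  ov2 <- fuse_images(img, img, Ht)
  expect_true(all(ov2[, 1:20, 1] == 0))
})

test_that("end-to-end registration of a synthetic pair meets the success rule", {
  cs <- registration_case(3)
  r <- register_pair(cs$tree$mask, cs$post, seed = 3)
  expect_true(r$metrics$success)
  expect_gte(r$metrics$overlap, 0.35)
  expect_gte(r$metrics$n_matches, 10)
  expect_gte(dice(r$warped_mask, cs$post), 0.9)
  expect_lt(corner_error(r$homography, cs$truth, cs$size), 2)
})
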