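test_that("vessel tree generation is deterministic, seed-sensitive and well-formed", {
  tree <- generate_vessel_tree(1, c(128, 128), 3)
  tree_again <- generate_vessel_tree(1, c(128, 128), 3)
  tree_other <- generate_vessel_tree(2, c(128, 128), 3)

  expect_identical(tree$mask, tree_again$mask)
  expect_false(identical(tree$mask, tree_other$mask))
  expect_length(tree$centerlines, 3)
  # recipient vessel is a subset of the full vessel mask
  expect_identical(tree$recipient_mask & tree$mask, tree$recipient_mask)
  # centreline pixels lie inside the mask
  for (b in tree$centerlines) {
    expect_true(all(tree$mask[b$path]))
    # consecutive path pixels are 8-connected
    expect_true(all(apply(abs(diff(b$path)), 1, max) == 1))
  }
  expect_error(generate_vessel_tree(1, c(32, 32), 3), "too small")
})

test_that("wash-in rendering follows the logistic model with correct bounds", {
  tree <- generate_vessel_tree(3, c(64, 64), 2)
  sp <- wash_in_spec(noise_sd = 0, duration = 4, rise_time = 0.05,
                     arrival_start = 1, arrival_span = 0.01)
  g <- generate_icg_video(tree, sp, seed = 1)

  expect_equal(dim(g$video$frames)[3], 100)
  expect_true(all(g$video$frames >= 0 & g$video$frames <= 255))
  # noiseless wash-in: frame mean is monotone nondecreasing (step-like here)
  m <- apply(g$video$frames, 3, mean)
  expect_true(all(diff(m) >= 0))
  # background stays at baseline
  bg <- g$video$frames[, , 100][!tree$mask]
  expect_true(all(bg == sp$baseline))
  # ground truth echoes the arrival map on the mask
  expect_true(all(!is.na(g$truth$arrival_map[tree$mask])))
  expect_true(all(is.na(g$truth$arrival_map[!tree$mask])))

  # frame-count arithmetic: 0.08 s at 25 fps -> exactly 2 frames
  g2 <- generate_icg_video(tree, wash_in_spec(duration = 0.08, noise_sd = 0),
                           seed = 1)
  expect_equal(n_frames(g2$video), 2)

  # determinism of the noisy path
  spn <- wash_in_spec(noise_sd = 3, duration = 0.5)
  expect_identical(generate_icg_video(tree, spn, seed = 5)$video$frames,
                   generate_icg_video(tree, spn, seed = 5)$video$frames)
})

test_that("per-pixel brightness peak matches arrival plus rise-to-peak", {
  tree <- generate_vessel_tree(4, c(64, 64), 2)
  sp <- wash_in_spec(noise_sd = 0, duration = 12, arrival_start = 1,
                     arrival_span = 6, rise_time = 0.4)
  g <- generate_icg_video(tree, sp, seed = 1)
  pix <- which(tree$mask)
  fr <- matrix(g$video$frames, prod(dim(g$video$frames)[1:2]))
  first_max <- apply(fr[pix, ], 1, which.max)
  t_peak <- (first_max - 1) / sp$fps
  expected <- g$truth$arrival_map[pix] + rise_to_peak(sp)
  expect_true(all(abs(t_peak - expected) <= 2 / sp$fps))
})

test_that("pre/post pairs carry an exact ground-truth homography", {
  tree <- generate_vessel_tree(1, c(128, 128), 3)
  sp_f <- wash_in_spec(duration = 1, noise_sd = 0)
  sp_m <- wash_in_spec(direction = "middle_to_both_sides", duration = 1,
                       noise_sd = 0)

  # identity transform -> identity homography
  pp0 <- generate_pre_post_pair(tree, sp_f, sp_f,
                                transform = list(rotation = 0, scale = 1,
                                                 translation = c(0, 0)))
  expect_equal(unclass(pp0$truth$true_homography), diag(3), tolerance = 1e-12)

  # apply-and-compare: warping the pre mask by the truth reproduces post
  pp <- generate_pre_post_pair(tree, sp_f, sp_m,
                               transform = list(rotation = 10, scale = 1.2,
                                                translation = c(5, -3)))
  warped <- warp_image(tree$mask, pp$truth$true_homography, c(128, 128),
                       "nearest")
  expect_gte(dice(warped, pp$truth$masks$post$all), 0.99)
  # both directions recorded
  expect_equal(pp$truth$direction$pre, "forward")
  expect_equal(pp$truth$direction$post, "middle_to_both_sides")

  expect_error(generate_pre_post_pair(tree, sp_f, sp_f,
                                      transform = list(rotation = 60, scale = 1,
                                                       translation = c(0, 0))),
               "rotation")
  expect_error(generate_pre_post_pair(tree, sp_f, sp_f,
                                      transform = list(rotation = 0, scale = 1,
                                                       translation = c(1000, 0))),
               "outside")
})

test_that("homography utilities are mutually consistent", {
  H <- similarity_homography(25, 1.3, c(4, -2), c(100, 100))
  pts <- cbind(runif(10, 1, 100), runif(10, 1, 100))
  back <- apply_homography(as_homography(solve(unclass(H))),
                           apply_homography(H, pts))
  expect_equal(back, pts, tolerance = 1e-9)
  expect_error(as_homography(matrix(0, 3, 3)), "nonzero")
})
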