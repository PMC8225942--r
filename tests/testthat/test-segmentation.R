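test_that("network geometry: bottleneck halving, output shapes, softmax contract", {
  cfg <- seg_config(widths = c(4, 8, 16, 32))
  model <- build_multitask_unet(cfg, seed = 2)
  # 64x64 with depth 4 -> bottleneck 4x4 (shapes checked via a forward pass)
  x <- matrix(runif(64 * 64), ncol = 1)
  fwd <- icgflow:::unet_forward(model, x, 64, 64, 1)
  expect_equal(dim(fwd$prob_all), c(64 * 64, 2))
  expect_equal(dim(fwd$prob_receip), c(64 * 64, 2))
  # probabilities in [0,1] summing to 1 per pixel, for both heads, untrained
  for (p in list(fwd$prob_all, fwd$prob_receip)) {
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  }
  expect_error(train_segmenter(model, list(make_seg_sample(1, c(60, 60)))),
               "divisible")
})

test_that("the joint loss matches hand computation and degenerates correctly", {
  mk_pred <- function(pa, pr) list(prob_all = matrix(pa, 1, 1),
                                   prob_receip = matrix(pr, 1, 1))
  mk_samp <- function(la, lr) seg_sample(matrix(0, 1, 1), matrix(la, 1, 1),
                                         matrix(lr, 1, 1))
  # single pixel, p = 0.5 on both true labels, alpha = beta = 1 -> 2 * ln 2
  expect_equal(multitask_loss(mk_pred(0.5, 0.5), mk_samp(TRUE, TRUE)),
               2 * log(2), tolerance = 1e-12)
  # perfect prediction -> 0
  expect_equal(multitask_loss(mk_pred(1, 1), mk_samp(TRUE, TRUE)), 0)
  # alpha = 0 -> only the recipient term remains
  expect_equal(multitask_loss(mk_pred(0.25, 0.5), mk_samp(TRUE, TRUE),
                              alpha = 0, beta = 3),
               3 * -log(0.5), tolerance = 1e-12)
  # invariant to simultaneous flips of image and labels
  s <- make_seg_sample(4)
  pred <- list(prob_all = matrix(runif(64 * 64), 64),
               prob_receip = matrix(runif(64 * 64), 64))
  fl <- function(m) m[, rev(seq_len(ncol(m)))]
  s_f <- seg_sample(fl(s$image), fl(s$label_all), fl(s$label_receip))
  pred_f <- list(prob_all = fl(pred$prob_all), prob_receip = fl(pred$prob_receip))
  expect_equal(multitask_loss(pred, s), multitask_loss(pred_f, s_f))
})

test_that("four-fold augmentation produces the stated views and involutions hold", {
  samples <- lapply(1:3, make_seg_sample)
  aug <- augment_fourfold(samples)
  expect_length(aug, 12)
  s <- samples[[1]]
  expect_identical(aug[[1]]$image, s$image)
  expect_identical(aug[[2]]$image, s$image[, 64:1])
  expect_identical(aug[[3]]$image, s$image[64:1, ])
  expect_identical(aug[[4]]$image, t(s$image))
  # labels flipped identically
  expect_identical(aug[[2]]$label_all, s$label_all[, 64:1])
  # flipping twice returns the original
  expect_identical(aug[[2]]$image[, 64:1], s$image)
  # a symmetric image yields duplicates among the four views
  sym <- seg_sample(diag(64) * 1.0, diag(64) == 1, diag(64) == 1)
  a4 <- augment_fourfold(list(sym))
  expect_identical(a4[[1]]$image, a4[[4]]$image)
})

test_that("Dice and Jaccard follow their formulas and mutual identity", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE      # 100 px
  b <- matrix(FALSE, 20, 20); b[6:15, 1:10] <- TRUE      # 100 px, 50 shared
  expect_equal(dice(a, b), 0.5)
  expect_equal(jaccard(a, b), 1 / 3)
  expect_equal(dice(a, a), 1.0)
  expect_equal(jaccard(a, a), 1.0)
  d0 <- matrix(FALSE, 5, 5); d1 <- matrix(FALSE, 5, 5); d1[5, 5] <- TRUE
  a0 <- matrix(FALSE, 5, 5); a0[1, 1] <- TRUE
  expect_equal(dice(a0, d1), 0.0)
  expect_equal(jaccard(a0, d1), 0.0)
  expect_equal(dice(d0, d0), 1.0)  # both empty
  expect_error(dice(matrix(0.5, 2, 2), matrix(TRUE, 2, 2)), "binary")

  # Dice = 2J / (1 + J) across random mask pairs
  set.seed(31)
  for (i in 1:20) {
    x <- matrix(runif(64) > 0.5, 8); y <- matrix(runif(64) > 0.5, 8)
    J <- jaccard(x, y)
    expect_equal(dice(x, y), 2 * J / (1 + J), tolerance = 1e-12)
    expect_gte(dice(x, y), J)
  }
})

test_that("training follows the learning-rate schedule and reduces the loss", {
  sched <- data.frame(iteration = c(0, 20, 100), rate = c(0.01, 0.001, 0.0001))
  expect_equal(icgflow:::lr_at(0, sched), 0.01)
  expect_equal(icgflow:::lr_at(19, sched), 0.01)
  expect_equal(icgflow:::lr_at(20, sched), 0.001)
  expect_equal(icgflow:::lr_at(100, sched), 0.0001)
  expect_equal(icgflow:::lr_at(149, sched), 0.0001)

  samples <- lapply(1:4, function(i) make_seg_sample(i, c(32, 32), 2))
  cfg <- seg_config(widths = c(4, 8, 16, 32), batch_size = 4,
                    total_iterations = 15)
  model <- build_multitask_unet(cfg, seed = 1)
  trained <- train_segmenter(model, samples, seed = 3)
  expect_length(trained$loss_trace, 15)
  expect_lt(trained$loss_trace[15], trained$loss_trace[1])
  expect_equal(trained$lr_trace[1], 0.01)
  # reproducible trace under a fixed seed
  trained2 <- train_segmenter(model, samples, seed = 3)
  expect_identical(trained$loss_trace, trained2$loss_trace)
})

test_that("a single sample can be memorised", {
  s <- make_seg_sample(9, c(32, 32), 2)
  cfg <- seg_config(batch_size = 8, total_iterations = 150)
  model <- build_multitask_unet(cfg, seed = 1)
  trained <- train_segmenter(model, list(s), seed = 2)
  p <- predict_segmenter(trained, s$image)
  expect_gte(dice(p$mask_all, s$label_all), 0.95)
})

test_that("test-time averaging preserves probability structure", {
  cfg <- seg_config(widths = c(4, 8, 16, 32))
  model <- build_multitask_unet(cfg, seed = 5)
  img <- make_seg_sample(2)$image
  p <- predict_with_tta(model, img)
  expect_true(all(p$prob_all >= 0 & p$prob_all <= 1))
  expect_true(all(p$prob_receip >= 0 & p$prob_receip <= 1))
  expect_equal(dim(p$prob_all), dim(img))
  # non-square input exercises the transpose view and padding path
  img2 <- img[1:48, ]
  p2 <- predict_with_tta(model, img2)
  expect_equal(dim(p2$prob_all), c(48, 64))
})

test_that("stable-frame selection finds the wash-in plateau", {
  # constant video -> first frame
  const <- icg_video(array(10, dim = c(16, 16, 30)))
  expect_equal(select_stable_frame(const), 1L)

  # sigmoid wash-in plateauing well before the end
  tree <- generate_vessel_tree(2, c(64, 64), 2)
  sp <- wash_in_spec(noise_sd = 0, duration = 20, arrival_start = 1,
                     arrival_span = 6, rise_time = 0.5)
  g <- generate_icg_video(tree, sp, seed = 1)
  sf <- select_stable_frame(g$video, tree$mask)
  t_stable <- (sf - 1) / sp$fps
  expect_gte(t_stable, max(g$truth$arrival_map, na.rm = TRUE) - 2)
  expect_lt(sf, n_frames(g$video) - 10)

  # strictly increasing ramp: never stabilises -> last frame with warning
  ramp <- icg_video(array(rep(seq(0, 200, length.out = 40), each = 256),
                          c(16, 16, 40)))
  expect_warning(sf2 <- select_stable_frame(ramp, eps = 0.5), "stabilises")
  expect_equal(sf2, 40)
})
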