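test_that("luminance curves average ROI brightness and compose linearly", {
  tree <- generate_vessel_tree(2, c(64, 64), 2)
  sp <- wash_in_spec(noise_sd = 0, duration = 4)
  g <- generate_icg_video(tree, sp, seed = 1)

  # constant video -> constant curve
  const <- icg_video(array(37, dim = c(8, 8, 10)))
  cv <- luminance_curve(const, matrix(TRUE, 8, 8))
  expect_true(all(cv$value == 37))
  expect_equal(cv$time, (0:9) / 25)

  # single-pixel ROI returns that pixel's raw trace
  m <- matrix(FALSE, 64, 64)
  px <- which(tree$mask, arr.ind = TRUE)[1, ]
  m[px[1], px[2]] <- TRUE
  cv1 <- luminance_curve(g$video, m)
  expect_equal(cv1$value, as.numeric(g$video$frames[px[1], px[2], ]))

  # noiseless sigmoid wash-in tracks the analytic ramp within quantisation
  mask <- tree$mask
  cv2 <- luminance_curve(g$video, mask)
  a <- g$truth$arrival_map[mask]
  analytic <- vapply(cv2$time, function(t) {
    mean(sp$baseline + (sp$peak_brightness - sp$baseline) *
           plogis((t - a) / sp$rise_time))
  }, numeric(1))
  expect_lt(max(abs(cv2$value - analytic)), 1)

  # mean over a union of disjoint ROIs = pixel-count-weighted mean
  m1 <- matrix(FALSE, 64, 64); m1[1:10, 1:10] <- TRUE
  m2 <- matrix(FALSE, 64, 64); m2[40:60, 40:50] <- TRUE
  cu <- luminance_curve(g$video, m1 | m2)
  c1 <- luminance_curve(g$video, m1); c2 <- luminance_curve(g$video, m2)
  w <- c(sum(m1), sum(m2))
  expect_equal(cu$value, (w[1] * c1$value + w[2] * c2$value) / sum(w),
               tolerance = 1e-9)

  expect_error(luminance_curve(g$video, matrix(FALSE, 64, 64)), "empty")
})

test_that("delay time is first-attained-maximum with earliest tie-break", {
  mk <- function(v) structure(data.frame(time = (seq_along(v) - 1) / 25,
                                         value = v),
                              class = c("luminance_curve", "data.frame"))
  v <- rep(0, 60); v[43:60] <- 10          # max first attained at index 43
  expect_equal(delay_time(mk(v), smooth_width = 1), 42 / 25)
  v2 <- rep(0, 80); v2[43] <- 10; v2[61] <- 10   # tie -> earliest
  expect_equal(delay_time(mk(v2), smooth_width = 1), 42 / 25)
  expect_warning(d <- delay_time(mk(rep(5, 10))), "flat")
  expect_equal(d, 0)
})

test_that("delay-time differences recover generator arrival offsets", {
  tree <- generate_vessel_tree(5, c(96, 96), 1)
  path <- tree$centerlines[[1]]$path
  sp <- wash_in_spec(noise_sd = 0, duration = 12, arrival_start = 1,
                     arrival_span = 6)
  g <- generate_icg_video(tree, sp, seed = 1)

  roi_at <- function(frac) {
    i <- max(1, round(frac * nrow(path)))
    m <- matrix(FALSE, 96, 96)
    m[path[i, 1], path[i, 2]] <- TRUE
    m
  }
  # two ROIs whose generator arrivals differ by a known offset
  r1 <- roi_at(0.15); r2 <- roi_at(0.85)
  offset <- g$truth$arrival_map[r2] - g$truth$arrival_map[r1]
  d1 <- delay_time(luminance_curve(g$video, r1))
  d2 <- delay_time(luminance_curve(g$video, r2))
  expect_lt(abs((d2 - d1) - offset), 1 / sp$fps + 1e-9)
})

test_that("perfusion map is monotone in time-to-peak with black background", {
  tree <- generate_vessel_tree(6, c(96, 96), 2)
  sp <- wash_in_spec(noise_sd = 0, duration = 12)
  g <- generate_icg_video(tree, sp, seed = 1)
  map <- perfusion_color_map(g$video, tree$mask)

  # non-vessel pixels black, ttp undefined
  expect_true(all(map$rgb[array(c(!tree$mask), dim(map$rgb))] == 0))
  expect_true(all(is.na(map$ttp[!tree$mask])))

  # pixel ranking by ttp equals ranking by colourbar position (monotone map)
  tv <- map$ttp[tree$mask]; pv <- map$position[tree$mask]
  o <- order(tv)
  expect_true(all(diff(pv[o]) >= -1e-12))
  interior <- tv > quantile(tv, 0.02) & tv < quantile(tv, 0.98)
  expect_equal(suppressWarnings(cor(tv[interior], pv[interior],
                                    method = "spearman")), 1)

  # the map's ttp equals delay_time of the per-pixel curve exactly
  px <- which(tree$mask, arr.ind = TRUE)[10, ]
  m <- matrix(FALSE, 96, 96); m[px[1], px[2]] <- TRUE
  expect_equal(map$ttp[px[1], px[2]],
               delay_time(luminance_curve(g$video, m)))

  # simultaneous peak -> one uniform colour
  const <- icg_video(array(rep(c(0, 200, 200), each = 64), c(8, 8, 3)))
  mp <- perfusion_color_map(const, matrix(TRUE, 8, 8))
  expect_equal(length(unique(mp$position[!is.na(mp$position)])), 1)

  expect_error(perfusion_color_map(icg_video(array(1, c(8, 8, 1))),
                                   matrix(TRUE, 8, 8)), "two frames")
})

test_that("colourbar lookup inverts the ramp", {
  cb <- perfusion_colorbar(64)
  expect_equal(as.numeric(colorbar_lookup(cb[1, ], cb)), 0)
  expect_equal(as.numeric(colorbar_lookup(cb[64, ], cb)), 1)
  for (p in c(0.2, 0.5, 0.8)) {
    col <- cb[round(p * 63) + 1, ]
    expect_lt(abs(as.numeric(colorbar_lookup(col, cb)) - p), 1 / 64)
  }
})

test_that("ROI polygons rasterise sensibly", {
  r <- roi("a", polygon = cbind(c(2, 10, 10, 2), c(2, 2, 10, 10)),
           shape = c(16, 16))
  expect_true(r$mask[5, 5])
  expect_false(r$mask[14, 14])
  expect_error(roi("b", polygon = cbind(1, 1), shape = c(16, 16)), "empty")
})
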