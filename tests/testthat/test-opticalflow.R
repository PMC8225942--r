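test_that("Gaussian pyramid halves resolution and preserves brightness", {
  frame <- matrix(runif(720 * 576, 0, 255), 720, 576)
  pyr <- gaussian_pyramid(frame, 4)
  expect_equal(lapply(pyr, dim),
               list(c(720, 576), c(360, 288), c(180, 144), c(90, 72)))
  # low-pass DC property: mean preserved within 1%
  means <- vapply(pyr, mean, numeric(1))
  expect_true(all(abs(means - means[1]) / means[1] < 0.01))

  # constant frame stays constant at every level
  cp <- gaussian_pyramid(matrix(7, 64, 64), 4)
  for (l in cp) expect_true(all(abs(l - 7) < 1e-9))

  expect_warning(p2 <- gaussian_pyramid(matrix(1, 16, 16), 4), "levels")
  expect_lt(length(p2), 4)
})

test_that("Horn-Schunck flow has a zero fixed point and recovers known shifts", {
  f <- matrix(runif(96 * 96, 0, 255), 96)
  fl0 <- hs_flow(f, f)
  expect_true(all(fl0$u == 0) && all(fl0$v == 0))

  bp <- blob_pair(shift = 2)
  fl <- hs_flow(bp$a, bp$b)
  expect_lt(abs(median(fl$u[bp$mask]) - 2), 0.5)
  expect_lt(abs(median(fl$v[bp$mask])), 0.5)

  # energy trace nonincreasing (Jacobi relaxation on a convex functional)
  expect_true(all(diff(fl$energy_trace) <= 1e-6 * max(abs(fl$energy_trace))))

  # antisymmetry: swapping frame order flips the recovered direction
  flr <- hs_flow(bp$b, bp$a)
  expect_lt(abs(median(flr$u[bp$mask]) + median(fl$u[bp$mask])), 0.3)
})

test_that("larger lambda produces smoother flow fields", {
  bp <- blob_pair(shift = 2)
  v2 <- var(as.vector(hs_flow(bp$a, bp$b, hs_params(lambda = 2))$u))
  v8 <- var(as.vector(hs_flow(bp$a, bp$b, hs_params(lambda = 8))$u))
  expect_lt(v8, v2)
})

test_that("flow direction classification recovers generator truth", {
  for (dir in c("forward", "reverse", "middle_to_both_sides")) {
    tree <- generate_vessel_tree(2, c(128, 128), 3)
    g <- generate_icg_video(tree, wash_in_spec(direction = dir, duration = 10),
                            seed = 30)
    lab <- vessel_flow_direction(g$video, tree$recipient_mask,
                                 tree$centerlines[[1]]$path)
    expect_equal(lab$category, dir)
    expect_gte(lab$confidence, 0.5)
  }
})

test_that("a zero-flow video is indeterminate and empty masks error", {
  const <- icg_video(array(50, dim = c(64, 64, 20)))
  mask <- matrix(FALSE, 64, 64); mask[30:34, 10:50] <- TRUE
  lab <- vessel_flow_direction(const, mask)
  expect_equal(lab$category, "indeterminate")
  expect_error(vessel_flow_direction(const, matrix(FALSE, 64, 64)), "empty")
})

test_that("direction change compares categories and propagates indeterminacy", {
  f <- direction_label("forward"); r <- direction_label("reverse")
  m <- direction_label("middle_to_both_sides")
  i <- direction_label("indeterminate")
  expect_equal(direction_change(f, f), "unchanged")
  expect_equal(direction_change(f, m), "changed")
  expect_equal(direction_change(r, f), "changed")
  expect_equal(direction_change(f, i), "indeterminate")
})

test_that("centreline tracing recovers an ordered path through a bar", {
  mask <- matrix(FALSE, 40, 60)
  mask[18:22, 5:55] <- TRUE
  path <- trace_centerline(mask)
  expect_gte(nrow(path), 40)
  # path spans the bar horizontally and stays inside it
  expect_lt(min(path[, 2]), 10)
  expect_gt(max(path[, 2]), 50)
  expect_true(all(mask[path]))
  expect_true(all(apply(abs(diff(path)), 1, max) == 1))
})
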