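test_that("Cohen's kappa matches hand-computed values and degenerate contracts", {
  # hand check: Po = 108/120, Pe = (82*78 + 38*42)/120^2 -> kappa 0.77528
  k <- cohen_kappa(matrix(c(74, 8, 4, 34), 2))
  expect_equal(k$kappa, (108 / 120 - 7992 / 14400) / (1 - 7992 / 14400),
               tolerance = 1e-12)
  expect_equal(k$interpretation, "substantial")

  # perfect agreement
  expect_equal(cohen_kappa(diag(c(5, 9, 2)))$kappa, 1.0)
  # degenerate marginals: every observation in one cell
  expect_error(cohen_kappa(matrix(c(7, 0, 0, 0), 2)), "degenerate")
  # invariant under simultaneous permutation of rows and columns
  tab <- matrix(c(64, 1, 5, 3, 18, 2, 2, 3, 22), 3)
  p <- c(3, 1, 2)
  expect_equal(cohen_kappa(tab)$kappa, cohen_kappa(tab[p, p])$kappa)
})

test_that("percent agreement is the diagonal fraction and scale-invariant", {
  tab <- matrix(c(64, 1, 5, 3, 18, 2, 2, 3, 22), 3)
  expect_equal(percent_agreement(tab), 104 / 120)
  expect_equal(percent_agreement(tab * 7L), 104 / 120)
  expect_equal(percent_agreement(diag(c(3, 4))), 1.0)
  expect_equal(percent_agreement(matrix(c(0, 2, 3, 0), 2)), 0.0)
})

test_that("contingency_table validates its input", {
  expect_error(contingency_table(matrix(1:6, 2)), "square")
  expect_error(contingency_table(matrix(c(1, -1, 0, 2), 2)), "nonnegative")
  expect_error(contingency_table(matrix(0, 2, 2)), "at least one")
})

test_that("paired t-test agrees with the textbook formula", {
  r <- paired_t_test(c(1, -1, 2, -2))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$mean, 0)

  expect_error(paired_t_test(rep(3, 8)), "sd = 0")
  expect_error(paired_t_test(5), "at least two")

  set.seed(11)
  d <- rnorm(10)
  r <- paired_t_test(d)
  se <- sd(d) / sqrt(10)
  t_manual <- mean(d) / se
  expect_equal(r$t, t_manual, tolerance = 1e-10)
  expect_equal(r$df, 9)
  expect_equal(r$p, 2 * pt(-abs(t_manual), 9), tolerance = 1e-10)
  expect_equal(r$conf_low, mean(d) - qt(0.975, 9) * se, tolerance = 1e-10)
  expect_equal(r$conf_high, mean(d) + qt(0.975, 9) * se, tolerance = 1e-10)
})

test_that("Q-Q normality summary separates normal from skewed samples", {
  # exact normal quantiles correlate perfectly with themselves
  x <- qnorm(ppoints(50))
  expect_equal(normality_check(x)$correlation, 1.0, tolerance = 1e-12)

  set.seed(21)
  qn <- normality_check(rnorm(200))
  qe <- normality_check(rexp(200))
  expect_gte(qn$correlation, 0.99)
  expect_lt(qe$correlation, qn$correlation)

  expect_warning(res <- normality_check(rep(1, 10)), "constant")
  expect_true(is.na(res$correlation))
  expect_error(normality_check(c(1, 2)), "at least 3")
})
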