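#' Build a square contingency table of categorical labels
#'
#' Rows index the first rater/method, columns the second. The table must be
#' square with identically ordered categories on both margins, as required by
#' chance-corrected agreement statistics.
#'
#' @param counts Square numeric matrix of nonnegative integer counts.
#' @param labels Optional character vector of category names, recycled to both
#'   margins. Defaults to existing dimnames or `cat1..catk`.
#' @return A `contingency_table`: an integer matrix with class attribute.
#' @examples
#' contingency_table(matrix(c(74, 8, 4, 34), 2), c("forward", "reverse"))
#' @export
contingency_table <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("contingency table must be square (same categories on both margins)")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (sum(counts) <= 0) stop("contingency table must contain at least one observation")
  if (is.null(labels)) {
    labels <- rownames(counts)
    if (is.null(labels)) labels <- paste0("cat", seq_len(nrow(counts)))
  }
  if (length(labels) != nrow(counts)) stop("need one label per category")
  dimnames(counts) <- list(labels, labels)
  structure(counts, class = c("contingency_table", "matrix"))
}

#' Cohen's kappa for a square agreement table
#'
#' Chance-corrected agreement between two raters over the same categorical
#' scale: kappa = (Po - Pe) / (1 - Pe), where Po is the observed proportion of
#' agreement (diagonal mass) and Pe the agreement expected from the marginal
#' distributions alone. The qualitative interpretation uses the conventional
#' five bands: slight (< 0.2), fair (0.2-0.4), moderate (0.4-0.6), substantial
#' (0.6-0.8) and almost perfect (> 0.8).
#'
#' The standard error is the asymptotic large-sample value (without the
#' hypothesis-test simplification), and `statistic` is kappa / se0 where se0 is
#' the null-hypothesis standard error, i.e. the usual approximate z/T statistic.
#'
#' @param table A [contingency_table()] or square count matrix.
#' @return A `kappa_result` list with elements `kappa`, `p_observed`,
#'   `p_expected`, `se`, `statistic`, `n` and `interpretation`.
#' @examples
#' cohen_kappa(matrix(c(74, 8, 4, 34), 2))
#' @export
cohen_kappa <- function(table) {
  if (!inherits(table, "contingency_table")) table <- contingency_table(table)
  n <- sum(table)
  p <- table / n
  po <- sum(diag(p))
  row_m <- rowSums(p)
  col_m <- colSums(p)
  pe <- sum(row_m * col_m)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    stop("degenerate marginals: expected agreement is 1, kappa undefined")
  }
  kappa <- (po - pe) / (1 - pe)

  # large-sample standard error (Fleiss, Cohen & Everitt asymptotic form)
  k <- nrow(p)
  a <- sum(vapply(seq_len(k), function(i) {
    p[i, i] * (1 - (row_m[i] + col_m[i]) * (1 - kappa))^2
  }, numeric(1)))
  b <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) b <- b + p[i, j] * (col_m[i] + row_m[j])^2
  }
  b <- (1 - kappa)^2 * b
  cvar <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, a + b - cvar)) / ((1 - pe) * sqrt(n))
  # null-hypothesis (kappa = 0) standard error for the approximate T statistic
  se0 <- sqrt(max(0, pe + pe^2 - sum(row_m * col_m * (row_m + col_m)))) /
    ((1 - pe) * sqrt(n))
  statistic <- if (se0 > 0) kappa / se0 else NA_real_

  structure(list(
    kappa = as.numeric(kappa),
    p_observed = as.numeric(po),
    p_expected = as.numeric(pe),
    se = as.numeric(se),
    statistic = as.numeric(statistic),
    n = as.numeric(n),
    interpretation = kappa_band(kappa)
  ), class = "kappa_result")
}

kappa_band <- function(kappa) {
  if (kappa < 0.2) "slight"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "substantial"
  else "almost perfect"
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (%s agreement)\n", x$kappa, x$interpretation))
  cat(sprintf("  observed agreement %.4f, expected %.4f, n = %d\n",
              x$p_observed, x$p_expected, as.integer(x$n)))
  cat(sprintf("  asymptotic se %.3f, approximate T %.3f\n", x$se, x$statistic))
  invisible(x)
}

#' Percent agreement of a square table
#'
#' The raw (not chance-corrected) fraction of concordant observations: the
#' diagonal sum divided by the table total.
#'
#' @inheritParams cohen_kappa
#' @return Numeric fraction in \[0, 1\].
#' @export
percent_agreement <- function(table) {
  if (!inherits(table, "contingency_table")) table <- contingency_table(table)
  n <- sum(table)
  if (n == 0) stop("empty table")
  as.numeric(sum(diag(table)) / n)
}

#' Paired-sample t-test on a vector of differences
#'
#' Two-sided one-sample t-test of mean difference zero, as used to compare two
#' measurements of the same quantity (e.g. delay times from two methods) on the
#' same subjects. Thin wrapper over [stats::t.test()] returning the quantities
#' of interest in a flat list.
#'
#' @param differences Numeric vector of paired differences (method A - method B).
#' @return List with `t`, `df`, `p`, `mean`, `sd`, `se`, `conf_low`, `conf_high`, `n`.
#' @export
paired_t_test <- function(differences) {
  differences <- as.numeric(differences)
  n <- length(differences)
  if (n < 2) stop("need at least two paired differences")
  s <- stats::sd(differences)
  if (s == 0) stop("all differences identical (sd = 0): t statistic undefined")
  fit <- stats::t.test(differences, mu = 0, alternative = "two.sided")
  list(
    t = unname(fit$statistic),
    df = unname(fit$parameter),
    p = fit$p.value,
    mean = mean(differences),
    sd = s,
    se = s / sqrt(n),
    conf_low = fit$conf.int[1],
    conf_high = fit$conf.int[2],
    n = n
  )
}

#' Normal Q-Q summary of a sample
#'
#' Ordered sample quantiles against standard-normal plotting positions
#' (the numerical content of a normal Q-Q plot), plus their Pearson
#' correlation as a scalar normality indicator. Used as the pre-check before
#' a paired t-test.
#'
#' @param differences Numeric vector, length >= 3.
#' @return List with `theoretical`, `sample` (both sorted, equal length),
#'   `correlation`, and `constant` (TRUE when the input is degenerate and the
#'   correlation is undefined).
#' @export
normality_check <- function(differences) {
  x <- sort(as.numeric(differences))
  n <- length(x)
  if (n < 3) stop("need at least 3 values for a Q-Q summary")
  theo <- stats::qnorm(stats::ppoints(n))
  constant <- stats::sd(x) == 0
  correlation <- if (constant) NA_real_ else stats::cor(theo, x)
  if (constant) warning("constant input: Q-Q correlation undefined")
  list(theoretical = theo, sample = x, correlation = correlation,
       constant = constant)
}
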