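#' Two-group Levene test of variance homogeneity
#'
#' Levene's test in its original mean-centered form: the observations are
#' replaced by absolute deviations from their group mean and a one-way
#' ANOVA F-test (here the two-group t-squared identity) is applied to the
#' deviations. The screen uses it as a gate: a feature whose variances
#' differ between groups (p < alpha) is not trusted to a pooled t-test.
#'
#' @param a,b Numeric vectors of observations for the two groups, each with
#'   at least two values.
#' @param center Centering for the deviations: `"mean"` (Levene's original,
#'   the default) or `"median"` (Brown-Forsythe variant).
#' @return A list with `statistic` (the Levene W, an F statistic on 1 and
#'   n - 2 degrees of freedom) and `p.value`. Two groups with no spread at
#'   all are treated as having equal variances (p = 1).
#' @examples
#' levene_test(c(1, 2, 3), c(1, 2, 3))$p.value  # identical groups: 1
#' @export
levene_test <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("levene_test requires at least 2 observations per group")
  }
  if (anyNA(a) || anyNA(b)) stop("levene_test does not accept missing values")
  ctr <- if (center == "mean") mean else stats::median
  za <- abs(a - ctr(a))
  zb <- abs(b - ctr(b))
  n <- length(za) + length(zb)
  gmean <- mean(c(za, zb))
  ssb <- length(za) * (mean(za) - gmean)^2 + length(zb) * (mean(zb) - gmean)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  if (ssw <= 0) {
    if (ssb <= 0) {
      return(list(statistic = 0, p.value = 1))
    }
    # deviations constant within groups but different between them
    return(list(statistic = Inf, p.value = 0))
  }
  w <- (n - 2) * ssb / ssw
  list(statistic = w, p.value = stats::pf(w, 1, n - 2, lower.tail = FALSE))
}

#' Pooled two-sample Student t-test
#'
#' Two-sided equal-variance t-test with n_a + n_b - 2 degrees of freedom.
#' The pooled form (rather than Welch) is appropriate here because the
#' screen first gates features on Levene variance homogeneity.
#'
#' @param a,b Numeric vectors, each with at least two observations.
#' @return List with `t`, `p.value`, `df`, and `degenerate`: `TRUE` when the
#'   pooled variance is zero with unequal means, in which case the feature
#'   cannot be tested and `p.value` is `NA`.
#' @export
student_t_test <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("student_t_test requires at least 2 observations per group")
  }
  if (anyNA(a) || anyNA(b)) stop("student_t_test does not accept missing values")
  na <- length(a)
  nb <- length(b)
  df <- na + nb - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  diff <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (abs(diff) < .Machine$double.eps^0.5) {
      return(list(t = 0, p.value = 1, df = df, degenerate = FALSE))
    }
    return(list(t = NA_real_, p.value = NA_real_, df = df, degenerate = TRUE))
  }
  tval <- diff / sqrt(sp2 * (1 / na + 1 / nb))
  list(
    t = tval,
    p.value = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    df = df, degenerate = FALSE
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1 and returned in the
#' original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on both margins, the two-sided p-value is the sum of
#' hypergeometric point probabilities not exceeding that of the observed
#' table (with a 1e-7 relative tolerance on the comparison) -- the
#' convention under which the cohort-description p-values of the source
#' dataset round to their printed values. The support is enumerated
#' directly, which keeps exhaustive sweeps over many tables fast.
#'
#' @param tab 2x2 matrix (or length-4 vector, column-major) of nonnegative
#'   integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(0, 12, 8, 16), 2)) # ~0.033
#' @export
fisher_exact <- function(tab) {
  tab <- as.vector(tab)
  if (length(tab) != 4) stop("`tab` must be a 2x2 table")
  if (anyNA(tab) || any(tab < 0)) stop("counts must be nonnegative")
  if (any(abs(tab - round(tab)) > 1e-8)) stop("counts must be integers")
  tab <- round(tab)
  a <- tab[1]; c_ <- tab[2]; b <- tab[3]; d <- tab[4]
  r1 <- a + b          # row-1 total (number drawn)
  c1 <- a + c_         # column-1 total ("white balls")
  c2 <- b + d
  if (r1 == 0 || c_ + d == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0, r1 - c2):min(r1, c1)
  dens <- stats::dhyper(support, c1, c2, r1)
  d_obs <- stats::dhyper(a, c1, c2, r1)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value when the combined sample size is at most 20 and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' correction, matching the conventions used for cohort descriptions.
#'
#' @param a,b Numeric vectors, each nonempty.
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && (length(a) + length(b)) <= 20
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  res$p.value
}
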