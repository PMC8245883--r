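#' Pearson correlation with a t-based significance test
#'
#' Computes the sample Pearson correlation and tests it against zero with
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n - 2 df, two-sided. A perfect
#' correlation (|r| = 1) makes the t statistic infinite; its p-value is
#' reported as 0.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, each non-constant.
#' @return An object of class `correlation_test`: list with `r`, `n`,
#'   `t_statistic`, `p_two_sided`.
#' @seealso [pearson_p()] for the test on a pre-computed r.
#' @examples
#' pearson_test(1:10, (1:10) + rnorm(10))
#' @export
pearson_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  pt <- pearson_p(r, n)
  structure(list(r = r, n = n, t_statistic = pt$t_statistic,
                 p_two_sided = pt$p_two_sided),
            class = "correlation_test")
}

#' Significance of a pre-computed Pearson correlation
#'
#' @param r Correlation in \[-1, 1\].
#' @param n Sample size it was computed from (>= 4).
#' @return List with `t_statistic` and `p_two_sided`.
#' @examples
#' pearson_p(0.48, 20)$p_two_sided  # ~0.032
#' @export
pearson_p <- function(r, n) {
  stopifnot(is.numeric(r), length(r) == 1L, abs(r) <= 1,
            is.numeric(n), length(n) == 1L, n >= 4)
  if (abs(r) == 1)
    return(list(t_statistic = sign(r) * Inf, p_two_sided = 0))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(t_statistic = t, p_two_sided = 2 * stats::pt(-abs(t), df = n - 2))
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), t(%d) = %.3f, two-sided p = %.4g\n",
              x$r, x$n, x$n - 2L, x$t_statistic, x$p_two_sided))
  invisible(x)
}

#' Fisher z (variance-stabilizing) transform of a correlation
#'
#' `fisher_z()` is atanh(r); `fisher_z_inverse()` is tanh(z).
#'
#' @param r Correlation with |r| < 1.
#' @param z A Fisher-z value.
#' @return The transformed value.
#' @export
fisher_z <- function(r) {
  stopifnot(is.numeric(r), all(is.finite(r)))
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) {
  stopifnot(is.numeric(z))
  tanh(z)
}

#' Compare two correlations from independent samples (Fisher z test)
#'
#' Tests equality of two correlation coefficients using
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'              {\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' with a two-sided normal p-value. The statistic is antisymmetric: swapping
#' the two correlations flips its sign. This independent-samples form is the
#' conventional reported test even when the underlying samples overlap; for
#' two correlations sharing a variable measured on the same subjects, see
#' [compare_correlations_dependent()].
#'
#' @param r1,r2 Correlations with |r| < 1.
#' @param n1,n2 Sample sizes (>= 4).
#' @return An object of class `corr_comparison`: list with `r1`, `n1`, `r2`,
#'   `n2`, `z_statistic`, `p_two_sided`.
#' @examples
#' compare_correlations(0.90, 20, 0.48, 20)  # z = 2.77, p ~ 0.006
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  stopifnot(is.numeric(n1), is.numeric(n2), n1 >= 4, n2 >= 4)
  z1 <- fisher_z(r1)
  z2 <- fisher_z(r2)
  z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z_statistic = z,
                 p_two_sided = 2 * stats::pnorm(-abs(z))),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf(
    "Fisher z comparison: r1 = %.3f (n = %d) vs r2 = %.3f (n = %d)\n",
    x$r1, x$n1, x$r2, x$n2))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$z_statistic,
              x$p_two_sided))
  invisible(x)
}

#' Compare two dependent correlations sharing one variable
#'
#' Williams' t test (Steiger's recommended statistic) for the hypothesis
#' rho(j,k) = rho(j,h) when all three variables are measured on the same n
#' subjects; requires the third correlation r_kh between the two non-shared
#' variables.
#'
#' @param r_jk,r_jh The two correlations being compared (shared variable j).
#' @param r_kh Correlation between the non-shared variables.
#' @param n Common sample size (>= 5).
#' @return List with `t_statistic`, `df`, `p_two_sided`.
#' @export
compare_correlations_dependent <- function(r_jk, r_jh, r_kh, n) {
  stopifnot(n >= 5, abs(r_jk) < 1, abs(r_jh) < 1, abs(r_kh) < 1)
  detR <- 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh
  rbar <- (r_jk + r_jh) / 2
  t <- (r_jk - r_jh) * sqrt(
    (n - 1) * (1 + r_kh) /
      (2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r_kh)^3))
  list(t_statistic = t, df = n - 3,
       p_two_sided = 2 * stats::pt(-abs(t), df = n - 3))
}

#' One-sample t-test
#'
#' \eqn{t = (\bar{x} - \mu_0)/(s/\sqrt{n})} on n - 1 df, two-sided. Used for
#' testing mean change against zero (is there significant attrition?).
#'
#' @param values Numeric vector, n >= 2.
#' @param mu0 Null mean (default 0).
#' @return List with `t_statistic`, `df`, `p_two_sided`, `mean`, `sd`, `n`.
#' @examples
#' one_sample_t(c(-0.2, -0.19, -0.18))$t_statistic  # -32.9
#' @export
one_sample_t <- function(values, mu0 = 0) {
  stopifnot(is.numeric(values), is.numeric(mu0), length(mu0) == 1L)
  n <- length(values)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0 && m != mu0)
    stop("constant values with mean != mu0: t undefined", call. = FALSE)
  t <- (m - mu0) / (s / sqrt(n))
  list(t_statistic = t, df = n - 1L,
       p_two_sided = 2 * stats::pt(-abs(t), df = n - 1),
       mean = m, sd = s, n = n)
}

#' One-way random-effects intraclass correlation for technical replicates
#'
#' ICC(1,1) from the one-way ANOVA decomposition of a balanced subjects x
#' replicates table:
#' \deqn{ICC = \frac{MS_B - MS_W}{MS_B + (k-1) MS_W},}
#' where MS_B and MS_W are the between- and within-subject mean squares and k
#' the number of replicates per subject. This is the single-measurement
#' reliability of one technical replicate (e.g. one gel lane or one qPCR
#' well).
#'
#' @param replicate_table Numeric matrix or data frame, one row per subject,
#'   one column per replicate; balanced (no missing cells), >= 2 subjects,
#'   >= 2 replicates.
#' @return An object of class `replicate_icc`: list with `icc`,
#'   `n_subjects`, `n_replicates_per_subject`, `ms_between`, `ms_within`.
#' @examples
#' tab <- cbind(c(6, 7, 8), c(6.1, 7.1, 7.9))
#' icc_oneway(tab)$icc
#' @export
icc_oneway <- function(replicate_table) {
  m <- as.matrix(replicate_table)
  if (!is.numeric(m)) stop("replicate table must be numeric", call. = FALSE)
  if (anyNA(m))
    stop("unbalanced replicate table (missing cells); balanced-only by design",
         call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2)
    stop("need >= 2 subjects and >= 2 replicates per subject", call. = FALSE)
  row_means <- rowMeans(m)
  grand <- mean(m)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((m - row_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  structure(list(icc = icc, n_subjects = n, n_replicates_per_subject = k,
                 ms_between = msb, ms_within = msw),
            class = "replicate_icc")
}

#' @export
print.replicate_icc <- function(x, ...) {
  cat(sprintf(
    "One-way ICC(1,1) = %.3f (%d subjects x %d replicates)\n",
    x$icc, x$n_subjects, x$n_replicates_per_subject))
  invisible(x)
}
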