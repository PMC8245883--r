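#' Measurement-error signature statistics for one cohort
#'
#' Computes the per-cohort statistics that distinguish a precise assay from an
#' error-prone one in two-timepoint data: Pearson agreement between the two
#' assay tracks at baseline, follow-up and for the change score; the
#' within-assay baseline-change correlation (regression-to-the-mean
#' signature: negative under measurement error even when true change is
#' independent of true baseline); the fraction of individuals with apparent
#' lengthening (change strictly > 0); and mean change expressed in that
#' assay's baseline-SD units (sample SD, n - 1 denominator).
#'
#' A constant input series makes the affected correlation undefined; it is
#' returned as `NaN` with a warning, never silently zero.
#'
#' @param cohort A `telo_cohort` (or equivalent data frame) with both tracks
#'   present and at least 4 individuals.
#' @return An object of class `signature_summary`: a named list with elements
#'   `r_methods_baseline`, `r_methods_followup`, `r_methods_change`,
#'   `r_baseline_change_true`, `r_baseline_change_proxy`,
#'   `frac_lengthening_true`, `frac_lengthening_proxy`,
#'   `mean_change_sd_units_true`, `mean_change_sd_units_proxy`, and `n`.
#' @examples
#' coh <- simulate_cohort(cohort_params(), seed = 1)
#' signature_stats(coh)$r_methods_change
#' @export
signature_stats <- function(cohort) {
  if (nrow(cohort) < 4)
    stop("signature statistics need at least 4 individuals", call. = FALSE)
  req <- c("true_baseline_kb", "true_followup_kb",
           "proxy_baseline", "proxy_followup")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyNA(cohort[req]))
    stop("cohort has missing values in the truth or proxy track ",
         "(attach_proxy() not run?)", call. = FALSE)

  tb <- cohort$true_baseline_kb
  tf <- cohort$true_followup_kb
  pb <- cohort$proxy_baseline
  pf <- cohort$proxy_followup
  td <- tf - tb
  pd <- pf - pb

  structure(list(
    r_methods_baseline = cor_or_nan(pb, tb, "proxy vs true baseline"),
    r_methods_followup = cor_or_nan(pf, tf, "proxy vs true follow-up"),
    r_methods_change = cor_or_nan(pd, td, "proxy vs true change"),
    r_baseline_change_true = cor_or_nan(tb, td, "true baseline vs change"),
    r_baseline_change_proxy = cor_or_nan(pb, pd, "proxy baseline vs change"),
    frac_lengthening_true = mean(td > 0),
    frac_lengthening_proxy = mean(pd > 0),
    mean_change_sd_units_true = mean(td) / stats::sd(tb),
    mean_change_sd_units_proxy = mean(pd) / stats::sd(pb),
    n = nrow(cohort)
  ), class = "signature_summary")
}

# Pearson r that surfaces degenerate inputs instead of erroring or zeroing
cor_or_nan <- function(x, y, label) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning(sprintf("constant series: correlation (%s) is undefined", label),
            call. = FALSE)
    return(NaN)
  }
  stats::cor(x, y)
}

#' @export
print.signature_summary <- function(x, ...) {
  cat(sprintf("Signature statistics (n = %d)\n", x$n))
  cat(sprintf("  method agreement r: baseline %.3f, follow-up %.3f, change %.3f\n",
              x$r_methods_baseline, x$r_methods_followup, x$r_methods_change))
  cat(sprintf("  baseline-change r: truth %.3f, proxy %.3f\n",
              x$r_baseline_change_true, x$r_baseline_change_proxy))
  cat(sprintf("  apparent lengthening: truth %.0f%%, proxy %.0f%%\n",
              100 * x$frac_lengthening_true, 100 * x$frac_lengthening_proxy))
  cat(sprintf("  mean change (baseline-SD units): truth %.3f, proxy %.3f\n",
              x$mean_change_sd_units_true, x$mean_change_sd_units_proxy))
  invisible(x)
}

#' Replicated signature study
#'
#' Simulates `n_replicates` independent cohorts (replicate k uses
#' `child_seed(seed, k)` as its master seed), computes [signature_stats()] on
#' each, and summarizes every statistic by its median and interquartile range
#' across replicates (linear-interpolation quantiles, [stats::quantile()]
#' type 7). Also reports the fraction of replicates in which the proxy
#' apparent-lengthening fraction *strictly* exceeds the truth-track one (ties
#' count against). Replicates where a statistic is undefined (constant
#' series) are excluded from that statistic's summary; the per-statistic
#' count used is reported.
#'
#' @param params A [cohort_params()] object (its `n_individuals` is the
#'   per-cohort size).
#' @param n_replicates Number of simulated cohorts (>= 2).
#' @param seed Master seed for the whole study.
#' @return An object of class `signature_study`: list with `summary` (data
#'   frame: statistic, median, q25, q75, n_used),
#'   `prop_proxy_lengthening_exceeds_true`, `replicates` (per-replicate data
#'   frame of all statistics), `n_replicates`, `n_per_cohort`, `seed`.
#' @examples
#' study <- run_signature_study(cohort_params(), n_replicates = 50, seed = 1)
#' study$summary
#' @export
run_signature_study <- function(params = cohort_params(),
                                n_replicates = 1000,
                                seed) {
  params <- validate_cohort_params(params)
  stopifnot(is.numeric(n_replicates), length(n_replicates) == 1L,
            n_replicates >= 2)
  n_replicates <- as.integer(n_replicates)

  stat_names <- c("r_methods_baseline", "r_methods_followup",
                  "r_methods_change", "r_baseline_change_true",
                  "r_baseline_change_proxy", "frac_lengthening_true",
                  "frac_lengthening_proxy", "mean_change_sd_units_true",
                  "mean_change_sd_units_proxy")
  reps <- matrix(NA_real_, nrow = n_replicates, ncol = length(stat_names),
                 dimnames = list(NULL, stat_names))
  for (k in seq_len(n_replicates)) {
    coh <- simulate_cohort(params, child_seed(seed, k))
    s <- suppressWarnings(signature_stats(coh))
    reps[k, ] <- unlist(s[stat_names])
  }
  reps <- as.data.frame(reps)

  summarise_one <- function(v) {
    ok <- v[is.finite(v)]
    q <- stats::quantile(ok, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(median = q[2], q25 = q[1], q75 = q[3], n_used = length(ok))
  }
  summary_df <- do.call(rbind, lapply(reps, summarise_one))
  summary_df <- cbind(statistic = stat_names, summary_df)
  rownames(summary_df) <- NULL

  both_ok <- is.finite(reps$frac_lengthening_proxy) &
    is.finite(reps$frac_lengthening_true)
  prop_exceeds <- mean(reps$frac_lengthening_proxy[both_ok] >
                         reps$frac_lengthening_true[both_ok])

  structure(list(
    summary = summary_df,
    prop_proxy_lengthening_exceeds_true = prop_exceeds,
    replicates = reps,
    n_replicates = n_replicates,
    n_per_cohort = params$n_individuals,
    params = params,
    seed = seed
  ), class = "signature_study")
}

#' @export
print.signature_study <- function(x, ...) {
  cat(sprintf(
    "Signature study: %d replicates of n = %d (master seed %s)\n",
    x$n_replicates, x$n_per_cohort, format(x$seed)))
  print(x$summary, digits = 3, row.names = FALSE)
  cat(sprintf(
    "  proxy lengthening exceeds truth in %.1f%% of replicates\n",
    100 * x$prop_proxy_lengthening_exceeds_true))
  invisible(x)
}

#' Population (large-n) values of the signature statistics
#'
#' Closed-form values implied by the generative covariance structure for an
#' unexposed cohort, useful as analytic references for large simulated
#' cohorts. Writing \eqn{\sigma_b, \sigma_\Delta} for the baseline and change
#' SDs, \eqn{\sigma_f = \sqrt{\sigma_b^2 + \sigma_\Delta^2}} for the
#' follow-up SD and \eqn{r_b, r_f} for the validity correlations, the proxy
#' tracks are unit-variance with
#' \eqn{cov(P_b, P_f) = r_b r_f \sigma_b / \sigma_f}, so e.g.
#' \eqn{cov(\Delta P, \Delta) = r_f \sigma_\Delta^2 / \sigma_f} and
#' \eqn{var(\Delta P) = 2 - 2 r_b r_f \sigma_b/\sigma_f}.
#'
#' @param params A [cohort_params()] object; `exposure_fraction` must be 0.
#' @return Named list mirroring the [signature_stats()] correlation and
#'   fraction fields.
#' @export
signature_population_values <- function(params = cohort_params()) {
  params <- validate_cohort_params(params)
  if (params$exposure_fraction != 0)
    stop("closed forms assume an unexposed cohort", call. = FALSE)
  sb <- params$sd_baseline_kb
  sd_ <- params$sd_change_kb
  sf <- sqrt(sb^2 + sd_^2)
  rb <- params$validity_r_baseline
  rf <- params$validity_r_followup

  # proxy tracks have variance 1 by construction
  cov_pb_pf <- rb * rf * sb / sf
  var_dp <- 2 - 2 * cov_pb_pf
  cov_dp_dtrue <- rf * sd_^2 / sf
  cov_pb_dp <- cov_pb_pf - 1

  list(
    r_methods_baseline = rb,
    r_methods_followup = rf,
    r_methods_change = cov_dp_dtrue / (sd_ * sqrt(var_dp)),
    r_baseline_change_true = 0,
    r_baseline_change_proxy = cov_pb_dp / sqrt(var_dp),
    frac_lengthening_true = stats::pnorm(params$mean_change_kb / sd_),
    # population standardization centres both proxy timepoints at zero
    frac_lengthening_proxy = 0.5,
    mean_change_sd_units_true = params$mean_change_kb / sb,
    mean_change_sd_units_proxy = 0
  )
}
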