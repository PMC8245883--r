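#' Simulate the truth track of a two-timepoint LTL cohort
#'
#' Draws true baseline LTL i.i.d. Normal(mean_baseline_kb, sd_baseline_kb^2)
#' and true change i.i.d. Normal(mean_change_kb - exposed * d * sd_change_kb,
#' sd_change_kb^2), independent of baseline; true follow-up is baseline +
#' change exactly. Exposure is assigned deterministically to the first
#' `round(exposure_fraction * n)` individuals: the draws are i.i.d. and
#' exchangeable, so this is equivalent to randomized allocation.
#'
#' Draw order under `seed`: all n baseline values first, then all n changes,
#' so the truth track for a given (params, seed) never depends on whether a
#' proxy track is attached afterwards.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer RNG seed for the truth draws.
#' @return A `telo_cohort`: a data frame with one row per individual and
#'   columns `id`, `exposed`, `true_baseline_kb`, `true_change_kb`,
#'   `true_followup_kb`, `proxy_baseline`, `proxy_followup` (the proxy
#'   columns are `NA` until [attach_proxy()] fills them), carrying the
#'   generating `params` and seeds as attributes.
#' @seealso [attach_proxy()], [simulate_cohort()]
#' @export
simulate_true_cohort <- function(params = cohort_params(), seed) {
  params <- validate_cohort_params(params)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  n <- params$n_individuals
  n_exposed <- round(params$exposure_fraction * n)
  exposed <- seq_len(n) <= n_exposed

  set.seed(as.integer(seed))
  baseline <- stats::rnorm(n, params$mean_baseline_kb, params$sd_baseline_kb)
  mu_change <- params$mean_change_kb -
    ifelse(exposed, params$exposure_effect_d * params$sd_change_kb, 0)
  change <- stats::rnorm(n, mu_change, params$sd_change_kb)

  cohort <- data.frame(
    id = seq_len(n),
    exposed = exposed,
    true_baseline_kb = baseline,
    true_change_kb = change,
    true_followup_kb = baseline + change,
    proxy_baseline = NA_real_,
    proxy_followup = NA_real_
  )
  structure(cohort,
            params = params,
            seed_truth = as.integer(seed),
            seed_proxy = NA_integer_,
            class = c("telo_cohort", "data.frame"))
}

#' Attach an error-prone proxy track to a simulated cohort
#'
#' Generates the unitless proxy measurement (qPCR-like T/S ratio analogue) at
#' each timepoint as
#' \deqn{proxy_t = r_t z_t + \sqrt{1 - r_t^2}\,\varepsilon,}
#' where \eqn{z_t} standardizes the true value by the *population* mean and SD
#' of the unexposed generating distribution at that timepoint (baseline:
#' mean_baseline_kb, sd_baseline_kb; follow-up: mean_baseline_kb +
#' mean_change_kb, sqrt(sd_baseline_kb^2 + sd_change_kb^2)) and
#' \eqn{\varepsilon} is an independent standard normal draw. The population
#' cross-sectional correlation between proxy and truth is therefore exactly
#' \eqn{r_t}. Noise draws at the two timepoints are independent; under `seed`
#' the n baseline noise draws come first, then the n follow-up draws.
#'
#' @param cohort A `telo_cohort` with its truth track present.
#' @param r_baseline,r_followup Validity correlations in \[0, 1\]; default to
#'   the values stored in the cohort's generating parameters.
#' @param seed Integer RNG seed for the proxy noise (independent of the truth
#'   seed).
#' @return The cohort with `proxy_baseline` and `proxy_followup` filled.
#' @export
attach_proxy <- function(cohort,
                         r_baseline = NULL,
                         r_followup = NULL,
                         seed) {
  stopifnot(inherits(cohort, "telo_cohort"))
  params <- attr(cohort, "params")
  if (is.null(r_baseline)) r_baseline <- params$validity_r_baseline
  if (is.null(r_followup)) r_followup <- params$validity_r_followup
  for (r in c(r_baseline, r_followup))
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0 || r > 1)
      stop("validity correlations must lie in [0, 1]", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))

  sd_fu <- sqrt(params$sd_baseline_kb^2 + params$sd_change_kb^2)
  if (params$sd_baseline_kb <= 0 || sd_fu <= 0)
    stop("proxy generation needs positive population SDs at both timepoints",
         call. = FALSE)
  z_b <- (cohort$true_baseline_kb - params$mean_baseline_kb) /
    params$sd_baseline_kb
  z_fu <- (cohort$true_followup_kb -
             (params$mean_baseline_kb + params$mean_change_kb)) / sd_fu

  n <- nrow(cohort)
  set.seed(as.integer(seed))
  eps_b <- stats::rnorm(n)
  eps_fu <- stats::rnorm(n)
  cohort$proxy_baseline <- r_baseline * z_b + sqrt(1 - r_baseline^2) * eps_b
  cohort$proxy_followup <- r_followup * z_fu + sqrt(1 - r_followup^2) * eps_fu
  attr(cohort, "seed_proxy") <- as.integer(seed)
  cohort
}

#' Simulate a complete two-track cohort
#'
#' Convenience wrapper: simulates the truth track and attaches the proxy
#' track, deriving the two stage seeds from one master seed with
#' [child_seed()] (truth = child 1, proxy = child 2).
#'
#' @inheritParams simulate_true_cohort
#' @return A `telo_cohort` with both tracks filled.
#' @examples
#' coh <- simulate_cohort(cohort_params(), seed = 1)
#' cor(coh$proxy_baseline, coh$true_baseline_kb)
#' @export
simulate_cohort <- function(params = cohort_params(), seed) {
  cohort <- simulate_true_cohort(params, child_seed(seed, 1))
  attach_proxy(cohort, seed = child_seed(seed, 2))
}

#' @export
print.telo_cohort <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Simulated two-timepoint LTL cohort: n = %d (%d exposed), proxy %s\n",
    nrow(x), sum(x$exposed),
    if (all(is.na(x$proxy_baseline))) "absent" else "attached"))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

has_proxy <- function(cohort) {
  !anyNA(cohort$proxy_baseline) && !anyNA(cohort$proxy_followup)
}
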