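#' Pre-post analysis strategies for a two-group cohort
#'
#' Three standard ways to test a binary exposure in a two-timepoint design:
#'
#' * `analyze_cross_section()` — equal-variance two-sample t-test of the
#'   follow-up values by exposure, ignoring baseline.
#' * `analyze_difference_score()` — the same test on within-individual change
#'   (follow-up minus baseline).
#' * `analyze_ancova()` — ordinary least squares of follow-up on the exposure
#'   indicator with baseline as covariate; the exposure coefficient is tested
#'   with its t statistic on n - 3 df.
#'
#' Each runs on either the truth track (kb) or the proxy track (unitless).
#' Effect estimates are exposed minus unexposed (so extra attrition in the
#' exposed group gives a negative estimate); p-values are two-sided.
#'
#' @param cohort A `telo_cohort` containing exposed and unexposed individuals
#'   (at least 2 of each).
#' @param assay `"truth"` or `"proxy"`.
#' @param welch Use the Welch (unequal-variance) t-test instead of the pooled
#'   one. The generative model is homoscedastic, so the pooled test is the
#'   default.
#' @return An object of class `strategy_result`: list with `strategy`,
#'   `assay`, `effect_estimate`, `p_value`.
#' @name strategies
NULL

assay_columns <- function(cohort, assay = c("truth", "proxy")) {
  assay <- match.arg(assay)
  cols <- switch(assay,
    truth = c("true_baseline_kb", "true_followup_kb"),
    proxy = c("proxy_baseline", "proxy_followup"))
  out <- list(baseline = cohort[[cols[1]]], followup = cohort[[cols[2]]])
  if (anyNA(out$baseline) || anyNA(out$followup))
    stop(sprintf("cohort has no complete %s track", assay), call. = FALSE)
  out
}

check_groups <- function(exposed) {
  if (sum(exposed) < 2 || sum(!exposed) < 2)
    stop("need at least 2 exposed and 2 unexposed individuals", call. = FALSE)
}

two_group_test <- function(y, exposed, strategy, welch = FALSE) {
  check_groups(exposed)
  y1 <- y[exposed]
  y0 <- y[!exposed]
  if (stats::var(y1) == 0 && stats::var(y0) == 0)
    stop("zero pooled variance: t-test undefined", call. = FALSE)
  tt <- stats::t.test(y1, y0, var.equal = !welch)
  structure(list(strategy = strategy, assay = NA_character_,
                 effect_estimate = unname(diff(rev(tt$estimate))),
                 p_value = tt$p.value),
            class = "strategy_result")
}

#' @rdname strategies
#' @export
analyze_cross_section <- function(cohort, assay = c("truth", "proxy"),
                                  welch = FALSE) {
  assay <- match.arg(assay)
  v <- assay_columns(cohort, assay)
  res <- two_group_test(v$followup, cohort$exposed, "cross_section", welch)
  res$assay <- assay
  res
}

#' @rdname strategies
#' @export
analyze_difference_score <- function(cohort, assay = c("truth", "proxy"),
                                     welch = FALSE) {
  assay <- match.arg(assay)
  v <- assay_columns(cohort, assay)
  res <- two_group_test(v$followup - v$baseline, cohort$exposed,
                        "difference_score", welch)
  res$assay <- assay
  res
}

#' @rdname strategies
#' @export
analyze_ancova <- function(cohort, assay = c("truth", "proxy")) {
  assay <- match.arg(assay)
  v <- assay_columns(cohort, assay)
  check_groups(cohort$exposed)
  if (nrow(cohort) < 4)
    stop("ANCOVA needs at least 4 individuals", call. = FALSE)
  if (stats::sd(v$baseline) == 0)
    stop("constant baseline: ANCOVA design is rank-deficient", call. = FALSE)
  fit <- stats::lm(v$followup ~ cohort$exposed + v$baseline)
  co <- summary(fit)$coefficients["cohort$exposedTRUE", ]
  structure(list(strategy = "ancova", assay = assay,
                 effect_estimate = unname(co["Estimate"]),
                 p_value = unname(co["Pr(>|t|)"])),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s (%s track): effect = %.4g, two-sided p = %.4g\n",
              x$strategy, x$assay, x$effect_estimate, x$p_value))
  invisible(x)
}

#' Monte-Carlo power of the three strategies over a sample-size grid
#'
#' For each total sample size in `n_grid`, simulates `n_replicates` cohorts
#' with half the individuals exposed, runs every requested strategy on every
#' requested assay track of the *same* cohorts (common random numbers, so the
#' strategy and assay orderings are compared with minimal Monte-Carlo noise),
#' and reports the fraction of replicates rejecting at `alpha` (p < alpha,
#' two-sided).
#'
#' Replicate k at the i-th grid size uses master seed
#' `child_seed(seed, (i - 1) * n_replicates + k)`. A replicate on which a
#' strategy errors is excluded from that cell and counted in `reps_used`.
#'
#' @param params A [cohort_params()] object supplying the generative
#'   parameters; its `n_individuals` and `exposure_fraction` are overridden
#'   (grid n; half exposed) and its `exposure_effect_d` is the tested effect.
#' @param strategies Subset of `c("cross_section", "difference_score",
#'   "ancova")`.
#' @param assays Subset of `c("truth", "proxy")`.
#' @param n_grid Total sample sizes (even, >= 8).
#' @param n_replicates Simulated cohorts per grid size.
#' @param alpha Two-sided significance level in (0, 1).
#' @param seed Master seed.
#' @return An object of class `power_curve`: list with `power` (data frame:
#'   strategy, assay, n, reps_used, power), `alpha`, `effect_d`,
#'   `n_replicates`, `seed`.
#' @examples
#' p <- cohort_params(exposure_effect_d = 0.5)
#' pc <- estimate_power(p, n_grid = c(50, 100), n_replicates = 100, seed = 1)
#' pc$power
#' @export
estimate_power <- function(params = cohort_params(exposure_effect_d = 0.5),
                           strategies = c("cross_section", "difference_score",
                                          "ancova"),
                           assays = c("truth", "proxy"),
                           n_grid = c(20, 50, 100, 250, 500, 750, 1000),
                           n_replicates = 1000,
                           alpha = 0.05,
                           seed) {
  params <- validate_cohort_params(params)
  strategies <- match.arg(strategies, several.ok = TRUE)
  assays <- match.arg(assays, several.ok = TRUE)
  stopifnot(length(n_grid) >= 1, all(n_grid >= 8), all(n_grid %% 2 == 0),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            n_replicates >= 1)
  analyzers <- list(cross_section = analyze_cross_section,
                    difference_score = analyze_difference_score,
                    ancova = analyze_ancova)

  cells <- expand.grid(strategy = strategies, assay = assays, n = n_grid,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rejections <- integer(nrow(cells))
  used <- integer(nrow(cells))

  for (i in seq_along(n_grid)) {
    p_i <- params
    p_i$n_individuals <- as.integer(n_grid[i])
    p_i$exposure_fraction <- 0.5
    p_i <- validate_cohort_params(p_i)
    for (k in seq_len(n_replicates)) {
      coh <- simulate_cohort(p_i, child_seed(seed, (i - 1) * n_replicates + k))
      idx <- which(cells$n == n_grid[i])
      for (j in idx) {
        res <- tryCatch(
          analyzers[[cells$strategy[j]]](coh, assay = cells$assay[j]),
          error = function(e) NULL)
        if (!is.null(res)) {
          used[j] <- used[j] + 1L
          if (res$p_value < alpha) rejections[j] <- rejections[j] + 1L
        }
      }
    }
  }
  cells$reps_used <- used
  cells$power <- rejections / used

  structure(list(power = cells, alpha = alpha,
                 effect_d = params$exposure_effect_d,
                 n_replicates = n_replicates, params = params, seed = seed),
            class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo power (d = %.2f, alpha = %.3f, %d replicates per n)\n",
    x$effect_d, x$alpha, x$n_replicates))
  wide <- stats::reshape(x$power[c("strategy", "assay", "n", "power")],
                         idvar = c("strategy", "assay"), timevar = "n",
                         direction = "wide")
  names(wide) <- sub("^power\\.", "n=", names(wide))
  print(wide, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Extract one power value from a power curve
#'
#' @param pc A `power_curve`.
#' @param strategy,assay,n Cell coordinates.
#' @return The estimated power (scalar).
#' @export
power_at <- function(pc, strategy, assay, n) {
  stopifnot(inherits(pc, "power_curve"))
  row <- pc$power[pc$power$strategy == strategy & pc$power$assay == assay &
                    pc$power$n == n, ]
  if (nrow(row) != 1L)
    stop("no unique cell for the requested strategy/assay/n", call. = FALSE)
  row$power
}
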