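# Build a cohort data frame by hand (no generating params attached); used for
# exact worked examples where the values themselves are the fixture.
manual_cohort <- function(true_baseline, true_followup,
                          proxy_baseline = NA_real_,
                          proxy_followup = NA_real_,
                          exposed = rep(FALSE, length(true_baseline))) {
  structure(
    data.frame(
      id = seq_along(true_baseline),
      exposed = exposed,
      true_baseline_kb = true_baseline,
      true_change_kb = true_followup - true_baseline,
      true_followup_kb = true_followup,
      proxy_baseline = proxy_baseline,
      proxy_followup = proxy_followup
    ),
    class = c("telo_cohort", "data.frame")
  )
}

# Pull the median of one statistic out of a signature_study summary
study_median <- function(study, statistic) {
  study$summary$median[study$summary$statistic == statistic]
}
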