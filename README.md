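# telosim

Can a telomere-length assay that correlates at r = 0.9 with the gold
standard in a cross-section actually measure telomere *change*? `telosim`
is an R package plus analysis workflow for answering that question by
simulation. It is aimed at telomere epidemiologists planning longitudinal
studies and, more generally, at anyone weighing a cheap noisy biomarker
assay against an expensive precise one in a pre-post design.

## The model

True leukocyte telomere length (LTL) in kilobases is simulated at two
timepoints for each of n individuals:

    B  ~ N(mu_b, sigma_b^2)               baseline
    D  ~ N(mu_D - d*sigma_D*X, sigma_D^2) change over the interval, indep. of B
    F  = B + D                            follow-up

with X a binary exposure on half the cohort and d its effect in change-SD
units. A unitless error-prone proxy (qPCR-like T/S analogue) is generated at
each timepoint t as

    P_t = r * z_t + sqrt(1 - r^2) * eps,   eps ~ N(0,1) independent,

where z_t is the true value standardized by its population mean and SD, so
the cross-sectional proxy-truth correlation is exactly the validity r.
Defaults (mu_b = 7.0 kb, sigma_b = 0.4524 kb, mu_D = -0.19 kb over 6.6
years, sigma_D = 0.17 kb, r = 0.875) match the published summary statistics
of a cohort of 20 men measured twice by both qPCR and Southern blot.

On top of the simulator the package provides:

* **signature statistics** (`signature_stats()`, `run_signature_study()`):
  method-agreement correlations at baseline / follow-up / change,
  regression-to-the-mean baseline-change correlations, apparent-lengthening
  fractions, replicated over many cohorts;
* **power analysis** (`estimate_power()`): Monte-Carlo power of the
  cross-section, difference-score and ANCOVA strategies on each assay track
  over a sample-size grid, with common random numbers across cells;
* **worked-example statistics** (`pearson_p()`, `compare_correlations()`,
  `one_sample_t()`, `icc_oneway()`): the Fisher-z and t machinery needed to
  reproduce the published empirical analyses from their printed summaries.

## Worked example

```r
library(telosim)

study <- run_signature_study(cohort_params(), n_replicates = 1000,
                             seed = 20210210)
print(study)
```

```
Signature study: 1000 replicates of n = 20 (master seed 20210210)
                  statistic   median     q25    q75 n_used
         r_methods_baseline  0.88198  0.8421  0.912   1000
         r_methods_followup  0.88032  0.8379  0.913   1000
           r_methods_change  0.42205  0.2804  0.545   1000
     r_baseline_change_true  0.00341 -0.1557  0.169   1000
    r_baseline_change_proxy -0.38002 -0.5132 -0.240   1000
      frac_lengthening_true  0.15000  0.1000  0.200   1000
     frac_lengthening_proxy  0.50000  0.4500  0.550   1000
  mean_change_sd_units_true -0.42466 -0.5001 -0.354   1000
 mean_change_sd_units_proxy  0.00585 -0.0996  0.111   1000
  proxy lengthening exceeds truth in 99.9% of replicates
```

Read: an assay whose cross-sectional validity is 0.875 at both timepoints
agrees with the gold standard at only ~0.42 for *change*; it shows a
spurious negative baseline-change correlation (−0.38) that the truth track
does not (0.00); and it calls apparent telomere lengthening in half the
cohort when the true fraction is ~15% — in essentially every simulated
replicate, not just in unlucky samples.

The same comparison for statistical power (d = 0.5 effect on attrition,
alpha = 0.05, 1,000 replicates per cell):

```r
pc <- estimate_power(cohort_params(exposure_effect_d = 0.5),
                     n_replicates = 1000, seed = 20210210)
print(pc)
```

```
         strategy assay  n=20  n=50 n=100 n=250 n=500 n=750 n=1000
    cross_section truth 0.053 0.095 0.152 0.297 0.482 0.670  0.821
 difference_score truth 0.199 0.414 0.685 0.974 1.000 1.000  1.000
           ancova truth 0.185 0.401 0.674 0.975 1.000 1.000  1.000
    cross_section proxy 0.052 0.093 0.126 0.235 0.391 0.542  0.707
 difference_score proxy 0.066 0.105 0.137 0.365 0.612 0.760  0.909
           ancova proxy 0.061 0.134 0.174 0.398 0.686 0.832  0.945
```

On the gold-standard track, using the baseline information (difference
score or ANCOVA — their curves overlap) buys a dramatic power gain over the
cross-section strategy. On the error-prone track the gain is much more
modest: a longitudinal proxy study of 1,000 people (0.909) is still weaker
than a gold-standard study of 250 (0.974), while the cross-sectional powers
of the two assays stay comparable at moderate n.

And the worked-example statistics on the published inputs:

```r
compare_correlations(0.90, 20, 0.48, 20)
#> Fisher z comparison: r1 = 0.900 (n = 20) vs r2 = 0.480 (n = 20)
#>   z = 2.767, two-sided p = 0.005649
```

## The analysis workflow

Numbered drivers under `analysis/` chain the package into the full study;
each writes its tables (and a JSON run manifest with parameters, seed,
package version and output digests) under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   [seed]   # one n=20 two-track cohort
Rscript analysis/02_signature_study.R   [seed]   # 1,000-replicate signature study
Rscript analysis/03_power_curves.R      [seed]   # power grid + figure
Rscript analysis/04_empirical_stats.R   [seed]   # worked examples on printed inputs
```

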