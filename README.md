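# semscan

Detection and analysis of **stochastic epigenetic mutations (SEMs)** in
Illumina methylation array data (27K/450K beta values).

Epigenome-wide studies usually compare mean methylation between groups, so
they only see alterations shared across subjects. `semscan` targets the
opposite signal: rare, subject-private epimutations — CpG sites where one
subject's methylation lies far outside the population's normal range. The
per-subject count of such events (the epimutation burden) is low in
childhood, grows roughly exponentially with age, and correlates with
skewing of X-chromosome inactivation (XCI) in females; the package provides
the full chain from raw beta matrices to that mediation analysis. It is
aimed at epigenomics researchers working with array methylation data who
want per-subject (rather than group-mean) epigenetic readouts.

## The method

For each CpG probe, with first and third quartiles \(Q_1, Q_3\) of the
population beta values and \(\mathrm{IQR} = Q_3 - Q_1\), a subject is
called epimutated at that probe when its beta value exceeds the extreme
Tukey fences:

&nbsp;&nbsp;&nbsp;&nbsp;β < Q₁ − 3·IQR  (hypo)  or  β > Q₃ + 3·IQR  (hyper)

For normal data these fences sit at ±4.72 SD, a per-value false-positive
probability of ≈ 2.4 × 10⁻⁶. Around the caller the package provides:

* sample/probe QC (bisulfite-control cut-off, PCA outlier screen, missing
  beta / detection-p / sex-chromosome filters), quantile normalisation and
  27K/450K platform pooling;
* per-subject burden counts with the log(n+1) transform, BED export of
  calls, duplicate-concordance validation;
* gene-level over-representation of a sample's epimutated probes
  (upper-tail hypergeometric test, Bonferroni-corrected) — the positive
  control for samples with known regional alterations;
* degree of XCI skewing (DS ∈ [0, 50]) from HUMARA digested/undigested
  peak heights;
* standardized (Z-score) regression, the correlation ratio η, recursive
  path analysis for the age / burden / mean-methylation / skewing diagram,
  and multiple imputation pooled by Rubin's rules;
* a synthetic-cohort generator with full ground truth, so every stage is
  testable end to end without any data download.

## Worked example

```r
library(semscan)

cohort <- generate_cohort(cohort_config(seed = 7))   # 178 subjects, ages 3-106
calls  <- call_sems(cohort$beta, k = 3)
calls
#> SEM call set: 5748 calls (3519 hyper, 2229 hypo) over 1000 probes x 178 samples
#> [k = 3, quartiles: linear]

burden <- count_sems(calls)                  # n_sem and log_sem per subject
tab    <- build_cohort_table(burden, cohort$sheet, cohort$beta)

correlation_ratio(tab, "log_sem", "age_range")
#> [1] 0.7774427

path_analysis(tab)
#> Path analysis (6 edges, alpha = 0.05)
#>   from     to       beta_std std_error  ci_low ci_high        p significant   n
#> 1 age      log_sem    0.773     0.0478   0.679   0.867 1.34e-36 TRUE        178
#> 2 age      avg_beta  -0.737     0.0904  -0.914  -0.559 6.77e-14 TRUE        178
#> 3 log_sem  avg_beta   0.116     0.0904  -0.0614  0.293 2.02e- 1 FALSE       178
#> 4 age      ds_xci    -0.104     0.160   -0.417   0.210 5.19e- 1 FALSE        75
#> 5 log_sem  ds_xci     0.782     0.142    0.503   1.06  5.91e- 7 TRUE         75
#> 6 avg_beta ds_xci    -0.0212    0.103   -0.223   0.181 8.38e- 1 FALSE        75
```

Reading the output: the epimutation burden rises strongly with age
(standardized β = 0.77), mean methylation falls with age (β = −0.74), and
XCI skewing is driven by the burden (β = 0.78, p ≈ 6e−7) while the
*conditional* age → skewing edge is not significant (p = 0.52) — the
age–skewing association is mediated by the number of epimutations, which is
exactly the structure this synthetic cohort was generated with (its
generator has no direct age → skewing effect). η = 0.78 summarises the
burden across the five age ranges. `plot_sem_burden(tab)`,
`plot_probe_calls()`, `autoplot()` on calls or path fits, and `tidy()` /
`glance()` give the graphical and tabular views.

A command-line front end with the same functionality is installed at
`system.file("scripts", "semscan", package = "semscan")`, with subcommands
`simulate`, `preprocess`, `call`, `enrich`, `humara` and `stats`.

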