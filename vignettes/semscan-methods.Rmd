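---
title: "Detecting stochastic epigenetic mutations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stochastic epigenetic mutations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semscan)
```

## The problem

Conventional epigenome-wide analyses compare *mean* methylation between
groups and therefore see only alterations that are shared across subjects.
Rare epimutations — CpG sites where a single subject's methylation lies far
outside the population's normal range — are invisible to mean-based
statistics, yet their per-subject count (the epimutation burden) is itself a
biologically meaningful quantity: it is low in childhood, grows roughly
exponentially with age, and correlates with skewing of X-chromosome
inactivation (XCI) in females.

`semscan` implements the full analytical chain for Illumina 27K/450K
beta-value data: quality control and normalisation, per-CpG extreme-outlier
calling, burden quantification, gene-level validation, HUMARA XCI-skewing
computation, and the regression/path-analysis layer that relates burden,
age, global methylation and skewing.

## The SEM model

For each CpG probe the population of beta values defines a normal range via
the quartiles. With $Q_1$, $Q_3$ and $\mathrm{IQR} = Q_3 - Q_1$ computed
across samples, a subject is called *epimutated* at that probe when its
value $\beta$ satisfies

$$\beta < Q_1 - k\,\mathrm{IQR} \quad\text{or}\quad \beta > Q_3 + k\,\mathrm{IQR},$$

with $k = 3$ by default — the *extreme* Tukey fences, seven-fold stricter in
normal-tail terms than the familiar $k = 1.5$ whiskers. For normally
distributed values the $k=3$ fences sit at $\pm 7\,\Phi^{-1}(0.75)\,\sigma
\approx \pm 4.72\,\sigma$, so the per-value false-positive probability is
about $2.4\times10^{-6}$: on a 450K array a handful of spurious calls per
cohort, negligible next to real burdens of tens to hundreds.

Design choices in the caller:

* **Quartile convention.** The default interpolates order statistics at
  position $p\,(n-1)$ (the common "type 7" rule); boxplot routines differ in
  their hinge conventions, so Tukey hinges are available via
  `quantile_method = "hinges"`. Both variants are oracle-tested.
* **Strict comparison.** A value exactly on a fence is *not* a call; the
  definition is "exceeding" the fence.
* **Complete matrices only.** `call_sems()` refuses missing values rather
  than dropping them probe-wise, so every probe's fence is estimated from
  the same denominator. Resolve missingness upstream (`filter_probes()`).
* **Burden transform.** Counts are analysed as $\log(n+1)$, so zero-burden
  subjects (typically children) remain defined on the log scale.

A caveat that matters at small scale: the $2.4\times10^{-6}$ tail value is
asymptotic. With few samples per probe (say $n \le 60$) the sampling noise
of the quartiles widens the effective fences' error, and the realised
false-positive rate can be orders of magnitude above the asymptote while
still being well below one call per thousand values. The fence rule also
assumes outliers are *rare at each probe*: if more than a few percent of
samples are epimutated at the same CpG, the quartiles themselves absorb the
outliers and sensitivity drops. Real cohorts (25K+ probes) are far below
that density.

## Quality control and normalisation

`filter_samples()` removes, in order: samples with bisulfite-conversion
control intensity strictly below 4000 (strict, reflecting the rule's
"< 4000" phrasing); then samples whose scores on the first two principal
components of probe-standardized data lie more than `pca_sd` (default 4)
standard deviations from the component mean. The PCA criterion is this
package's own, since a numeric rule is rarely published; 4 SD is
conservative and the parameter is exposed.

`filter_probes()` removes, in order and with the first applicable reason
recorded: probes with any missing beta; probes whose fraction of samples
with detection $p < 0.05$ falls below 0.95 (skipped with a warning when no
detection-p matrix accompanies the betas, as is common for 27K exports);
and probes on chromosomes X and Y. The fixed order makes QC reports
deterministic.

`quantile_normalize()` maps every sample onto the across-sample mean of
order statistics; ties within a sample receive the mean of the reference
values over the tied rank span, preserving within-sample order. The
implementation is deliberately ours (ten lines) so the tie rule is exactly
the documented one; a test cross-checks it against `limma`'s equivalent on
tie-free data. Background correction and Infinium type I/II peak correction
operate on raw intensities, which a beta-level workflow does not see; they
are out of scope here and documented as such.

`pool_platforms()` intersects the probe sets of a 27K and a 450K matrix and
concatenates samples, mirroring the pooled-cohort construction used for
mixed-platform studies.

## Gene-level validation

For a chosen sample, `gene_enrichment()` asks whether its epimutated probes
pile up in particular genes: with $N_G$ probes in the universe, $N_S$ of
them epimutated in the sample, and a gene containing $G_I$ probes of which
$S_I$ are epimutated, the p-value is the inclusive upper tail
$P(X \ge S_I)$ of the hypergeometric distribution, computed in log space and
Bonferroni-corrected over the genes tested. The default universe is the
post-QC probe set the calls were made on (the universe is a parameter, since
"all probes on the array" is an equally defensible choice). Probes annotated
to several genes count once per gene but once in the totals. On an
imprinting-disorder sample, whose known regional alteration epimutates a
whole gene block, that gene should — and in the synthetic positive controls
does — rank first at Bonferroni $p < 0.05$.

## Duplicate concordance

Technical duplicates validate the caller: `duplicate_concordance()`
correlates two samples' binary per-probe call indicators (Pearson) over the
full probe universe. Note a subtlety: restricting the correlation to probes
called in *at least one* member makes it degenerate — over that union the
two indicators' rare zeros never coincide, forcing the correlation to be
negative or undefined whenever the sets differ in both directions. Over the
full universe the statistic behaves as intended: exactly 1 for identical
non-empty sets, negative for disjoint sets, and approximately the shared
fraction for partially overlapping sets. Pairs without any calls give `NA`.
The statistic is only informative when the duplicated subject carries a
non-trivial burden; duplicating adult samples is the sensible lab design.

## HUMARA XCI skewing

In the HUMARA assay, methylation-sensitive digestion (HpaII/HhaI) destroys
the unmethylated — active-X — allele of the polymorphic androgen-receptor
CAG repeat, so each allele's digested PCR peak reflects its inactive-X
fraction, and the undigested reaction corrects allele-specific amplification
bias. With digested heights $(d_1, d_2)$ and undigested $(u_1, u_2)$:

$$r = \frac{d_1/d_2}{u_1/u_2},\qquad f = \frac{r}{1+r},\qquad
\mathrm{DS} = \left|\,(1-f) - 0.5\,\right|\times 100,$$

where $f$ is the inactive fraction of allele 1 and DS runs from 0 (random
XCI) to 50 (complete skew). A zero digested peak is taken at the formula's
limit ($f \in \{0, 1\}$, DS = 50); both digested peaks zero is an error.
DS is invariant under allele relabeling and common rescaling of the four
heights. Heterozygosity checking (two resolvable CAG alleles) is the
caller's responsibility.

## Regression and path analysis

All association analyses run on Z-scores, so coefficients are standardized
($\beta$). `standardized_regression()` is OLS on complete cases with
normal-approximation 95% intervals; collinear designs are rejected rather
than silently aliased. The correlation ratio
$\eta = \sqrt{SS_\text{between}/SS_\text{total}}$ summarises the burden
across categorical age ranges (0–19, 20–39, 40–59, 60–79, 80–106 years,
binned on completed years).

`path_analysis()` fits a recursive (acyclic) path model by per-equation
standardized OLS: each endogenous variable is regressed on its parents. For
a just-identified recursive model this coincides with the
structural-equation estimates, which is why no dedicated SEM fitter is
needed. The default edge set treats age as exogenous, the log burden as a
function of age, average methylation as a function of age and burden, and
XCI skewing as a function of all three. The scientifically interesting
contrast is *mediation*: when skewing is driven by the burden and the
burden by age, the marginal age–skewing association is strong while the
conditional (burden-adjusted) age edge collapses to insignificance.

Missing covariates (typically BMI and DS) are handled either by complete
cases per model, or by `impute_missing()`: chained-equation regression
imputation with posterior draws of the coefficients and residual scale
(deterministic given a seed), producing $m = 5$ completed tables by
default. This is a deliberately simpler imputer than the bootstrap-EM
machinery some studies use; results are pooled identically by Rubin's
rules: $\bar q$, within-variance $W$, between-variance $B$, total
$T = W + (1 + 1/m)B$, with the classic degrees of freedom.

## The synthetic cohort generator

No public dataset accompanies the original mixed-platform ageing cohort, so
`generate_cohort()` produces cohorts with the statistical structure the
method assumes, plus a complete `truth` record for validation. Defaults
mirror the study design: 178 subjects, ages uniform on 3–106 (each of the
five age ranges then holds well over 10 subjects), 94 of 178 on the 450K
platform, with:

* **Baseline profile.** Per-probe means drawn from a bimodal mixture (60%
  unmethylated-mode at 0.12, 40% methylated-mode at 0.85, SD 0.04), noise
  logit-normal with SD 0.2 plus a per-sample global offset (SD 0.08),
  truncated to (0.001, 0.999) — values stay in the unit interval with
  realistic heteroscedasticity near the boundaries.
* **Burden.** Planted counts are Poisson with mean
  $\lambda_0 e^{b\,\mathrm{age}} u$, $\lambda_0 = 2$, $b = 0.04$/yr, and a
  mean-one gamma frailty $u$ (shape 2). The frailty reproduces the strong
  between-subject variability real burdens show at a given age (without it
  the age–burden correlation is implausibly near 1); being independent of
  age it leaves the exponential slope unbiased.
* **Epimutations.** Placed uniformly over shared probes, displaced toward
  the far unit-interval boundary by at least the configured effect size
  (default 0.2β) *and* at least 6.5 noise-SDs, so planted calls clear the
  fences; infeasible displacements (baseline too near a boundary) error out.
* **Drift.** Global hypomethylation of $-3\times10^{-4}$ β/yr and a BMI
  effect of $-4\times10^{-4}$ β/unit, giving the expected negative
  standardized age and BMI coefficients on mean methylation.
* **XCI skewing.** For females (55% of subjects; 85% of them heterozygous
  and hence measurable), $DS = 50\,\sigma(-0.8 + 0.8\,z(\log SEM) +
  \varepsilon)$, $\varepsilon \sim N(0, 0.7)$ — a monotone map onto
  $[0, 50]$ with *no direct age term*, so the generated mediation structure
  is exactly the one the path analysis should recover. The implied
  standardized burden-to-skewing path sits near 0.6; this is stronger than
  typical reported associations, chosen deliberately: with ~80 measurable
  females per cohort and the frailty-driven age–burden collinearity
  (VIF ≈ 2.6), a weaker link would leave per-cohort power for the
  burden→skewing edge well below the level at which the generator's
  mediation structure is reliably recoverable, which is the generator's
  contract.
* **Duplicates and positive controls.** `generate_duplicates()` appends
  technical replicates that re-draw all measurement noise, keep each planted
  epimutation with probability `duplicate_share` (0.99) and gain artefact
  epimutations at rate `1 - share`, so discordance runs both ways.
  Duplicated subjects are drawn from those with a measurable burden
  (default ≥ 10 planted epimutations), as a lab would choose validation
  samples — concordance on a near-zero-burden pair is dominated by the
  occasional baseline false positive and carries no signal.
  `plant_imprinting_block()` fully epimutates one gene in one sample.

What the generator does **not** emulate: probe-probe co-methylation,
cell-composition mixtures, batch effects beyond the platform split, and
Infinium chemistry artefacts. Passing the end-to-end tests therefore shows
the *pipeline logic* is sound under the model's assumptions, not that any
particular biological cohort will reproduce specific printed statistics.

## Problem sizes and numerical choices

The test-suite and acceptance workloads use desk-scale sizes chosen to make
every check sharp yet quick: 1,000 random matrices (≤ 50 probes × ≤ 30
samples) for exact oracle agreement; $10^7$ i.i.d. draws for the
false-positive tail (500 probes × 20,000 samples, where the asymptotic tail
value applies to within a few percent); full enumeration of hypergeometric
parameter tuples to $N_G = 40$ plus 3,000 random tuples to $N_G = 500$
(binomial-coefficient sums of positive terms stay within double range to
$N_G = 500$, so the exact-summation oracle carries ~$10^{-15}$ relative
error); 20 replicate cohorts of $n = 200$ for rate recovery; and 50 seeds
of $n = 200$ for mediation recovery. Matrix files are parsed with base R's
correctly-rounded number parser so that write–read–write round-trips are
byte-stable; coordinates are 1-based in annotations and 0-based half-open
in BED output.

## Known limitations

* Outlier calling assumes per-probe contamination is sparse; dense regional
  alterations (e.g. many subjects epimutated at one locus) widen the
  fences and reduce sensitivity by design.
* The PCA sample screen and the imputer are pragmatic defaults, not
  re-implementations of any specific published pipeline stage.
* Peak-correction and background-correction steps that require raw
  intensities are out of scope at the beta-value level.
* The path model is recursive and just-identified; latent variables, fit
  indices and non-recursive structures are out of scope.
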