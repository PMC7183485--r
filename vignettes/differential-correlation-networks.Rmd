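---
title: "Differential correlation networks for two-group metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential correlation networks for two-group metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the method answers

In a two-group metabolomics study — here, patients who did and did not
reach a clinically meaningful improvement after total joint replacement —
single-metabolite tests ask whether mean abundances differ. Differential
correlation analysis asks a complementary question: for which *pairs* of
metabolites does the strength of co-variation differ between the groups?
A pair that is tightly correlated in non-responders but uncorrelated in
responders points at a rewired piece of metabolism even when neither
metabolite shifts in mean.

## The statistic

For each metabolite pair $(i, j)$ the package computes the Pearson
correlation separately within cases (non-responders) and controls
(responders), applies Fisher's variance-stabilizing transform
$z = \tfrac{1}{2}\ln\!\big[(1+r)/(1-r)\big]$, and standardizes the
difference by the combined sampling variance:

$$
r_{\mathrm{diff}}(i,j) \;=\;
\frac{z_{\mathrm{case}}(i,j) - z_{\mathrm{control}}(i,j)}
     {\sqrt{\dfrac{1}{n_{\mathrm{case}}-3} + \dfrac{1}{n_{\mathrm{control}}-3}}}
$$

The denominator makes the statistic comparable across pairs when the two
groups are of very different size (67 vs 378 in the motivating cohort).
Under the null of equal population correlations $r_{\mathrm{diff}}$ is
approximately standard normal; the test suite verifies mean bias below
0.05 and a standard deviation inside $[0.9, 1.1]$ over 2000 simulated
replicates at $n = 100$ per group.

Pearson correlation is used throughout: the $1/(n-3)$ variance is the
Pearson form of the Fisher transform, and no rank-based variant is
implied by the machinery. Correlations numerically at $\pm 1$ are
clamped to magnitude $1 - 10^{-12}$ before the transform so collinear
pairs yield a large finite statistic instead of infinity — continuity at
negligible bias.

## Significance by permutation

Analytic normal p-values are fragile here: the same data are reused
across thousands of pairs and preprocessing (imputation, outlier
masking) perturbs the sampling distribution. Significance is therefore
assessed by label permutation. Each replicate shuffles the phenotype
labels once, globally — a single permuted dataset shared by all pairs,
which is both the natural reading of "shuffle the phenotype labels" and
the only computationally sensible one — and recomputes the full
statistic matrix. Group sizes are preserved by construction.

Design choices, all switchable through function arguments:

* **Two-sided test** on $|r_{\mathrm{diff}}|$, since both directions of
  differential correlation are of interest (positive and negative edges
  both appear in the resulting networks).
* **Add-one estimator** $p = (b+1)/(B+1)$, where $b$ counts permuted
  statistics at least as extreme as the observed one. This is a valid
  finite-sample p-value, never zero; with the default $B = 1000$ the
  smallest attainable p is $1/1001$.
* **Ties count as exceedances** — conservative.
* **Non-finite permuted statistics** (a permutation that isolates a
  zero-variance column) count as exceedances and are logged.
* **No multiple-testing correction** beyond the fixed thresholds
  $p < 0.01$ (primary) and $p < 0.05$ (exploratory). With 8515 candidate
  pairs from 131 metabolites, roughly 85 pairs are expected below 0.01
  by chance alone; users should read network sizes with that base rate
  in mind. This mirrors the original analysis design and is stated
  prominently rather than silently "fixed".

Calibration: `type1_calibration()` generates replicate null cohorts and
reports the fraction of pairs rejected at each level next to the central
99% binomial band. The calibration cohorts use uncorrelated metabolites
and no censoring so that pair-level rejections are as close to
independent as the design allows and the binomial band is the correct
reference; with correlated background the pooled fraction is still
unbiased but over-dispersed relative to a binomial. The packaged
calibration runs 50 replicate cohorts of 67 + 378 samples by 30
metabolites at $B = 1000$ — about 4 minutes on one core, chosen as the
smallest design that pins the rejection rate to within a few tenths of a
percentage point.

## Quality control

The QC chain is `filter_lod()` → `impute_mean()` → `log_zscore()` →
`mask_outliers()`, composed by `preprocess()`:

* **LOD filter** (default threshold 0.10): a metabolite is excluded when
  *more than* 10% of its values are below the limit of detection —
  strict inequality, so exactly 10% is retained.
* **Mean imputation**: missing and below-LOD values are replaced by the
  metabolite's mean over observed values, on the raw concentration
  scale, because imputation is part of QC and precedes the log
  transform. Whether below-LOD values deserve an LOD-based substitute
  rather than the mean is genuinely open; the mean is applied to them
  as to any other missing value, and the QC report counts them.
* **Normalization**: natural log, then Z-score with the sample standard
  deviation ($n-1$); each retained column has mean 0 and SD 1 to within
  $10^{-9}$.
* **Outlier masking** (default $k = 3$): cells with $|z| > k$ — strictly
  beyond — are re-masked as missing. Masking *cells* rather than
  dropping whole samples is a deliberate choice where the alternative
  reading (excluding entire outlying samples) was also defensible; the
  cell reading maximizes retained data, and downstream correlations use
  pairwise-complete observations with the per-pair $n$ feeding the
  statistic's denominator. Masked cells are not re-imputed.

## Responder classification

WOMAC subscales score pain 0–20 and function 0–68, 0 meaning no
symptoms, so improvement is `baseline − followup` and the change score
is positive when the patient improves. Non-responders fall strictly
below the minimal clinically important difference: change < 7 (pain) or
< 22 (function). Exclusions are applied per outcome in a fixed order —
missing scores, then non-primary osteoarthritis, then the baseline
floor. The floor excludes patients whose baseline pain is below 7 *and*
baseline function below 22 simultaneously: such patients cannot attain
either MCID. Reading the floor as a conjunction (rather than per
outcome) is the package's choice on an ambiguous rule and is recorded in
the exclusion reasons so users can audit it.

Reported percentages are rounded to one decimal, half away from zero.

## Networks

`build_network()` keeps edges with $p$ strictly below the chosen level,
signs them by the statistic (positive = more positively correlated in
cases; conventionally drawn red, negative blue), and computes connected
components. The *central network* is the component with the most nodes;
ties break by edge count, then by lexicographically smallest member.
Hubs are ranked by degree with ties reported as ties. Node classes
(acylcarnitine, amino acid, biogenic amine, glycerophospholipid, lysoPC,
sphingolipid, monosaccharide) derive from the Biocrates-style identifier
prefixes; unrecognized identifiers fall back to "other". Graphs export
to GraphML (attributes preserved, round-trip tested) and to the same
delimited edge schema the statistics stage writes.

Two structural fixtures — `fixture_pain_edges()` and
`fixture_function_edges()` — encode the *textual* description of the
motivating study's two p < 0.01 networks: 12 nodes as 8+2+2 components
with a hub of degree 3, and 23 nodes as 14+3+2+2+2 components with a hub
of degree 5, sharing five named metabolites. The exact published edge
lists exist only as figures, so the fixtures reproduce the described
component structure, node classes and overlap, not the drawings; they
are synthetic and labelled as such. One further wrinkle: the source
text describes the function network's edges as all positive yet also
says its negative glutamine–phosphatidylcholine relationships recur in
both networks. The fixtures resolve this by carrying the negative
glutamine edges in both, which satisfies the overlap description
without changing any count.

## The synthetic cohort generator

No public accession exists for the motivating dataset, so
`generate_cohort()` is a first-class, tested module that emulates its
statistical shape:

* **Log-normal concentrations.** Per group, log-scale abundances are
  multivariate normal with a background correlation (default 0.2, a
  typical baseline for a targeted metabolomics panel) plus planted
  per-group entries; per-metabolite location and scale are drawn once
  (log-means uniform on $[0,4]$, log-SDs on $[0.3, 0.8]$, i.e. raw
  medians of roughly 1–55 concentration units). The data are then
  exponentiated, so the pipeline's log transform recovers the planted
  correlations exactly; planted targets are defined on the log scale.
  The real data's distribution is not documented; log-normality is an
  assumption of convenience that makes the generator and pipeline
  exactly self-consistent, and results on real, heavier-tailed data may
  differ.
* **Positive-definiteness** of each group's target correlation matrix is
  checked by eigendecomposition; an unplantable combination errors,
  naming the offending edges.
* **Censoring**: below-LOD values are those under the metabolite's
  empirical `lod_fraction` quantile, mimicking a detection floor;
  additional cells go missing uniformly at random
  (`missing_fraction`); outliers replace log-values with deviates at
  least 4 SD from the column mean (`outlier_fraction`), placed so the
  ±3 SD rule must catch whatever survives censoring. Defaults (0.02,
  0.01, 0.002) keep every metabolite under the 10% LOD rule, matching a
  post-QC panel.
* **Outcome scores** are integers clipped to the WOMAC ranges, with
  baselines high enough to clear the floor exclusion and change scores
  forced to respect the responder contract on *both* subscales, so
  classification recovers the generated group labels exactly.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: batch and plate effects, heavy-tailed
or skewed-beyond-log-normal abundance distributions, structured
(non-random) missingness, per-outcome missingness patterns that give
different analyzable denominators per subscale, and biologically
realistic correlation blocks. The study-scale exclusion bookkeeping
(704 enrolled → 461 analyzable, with 445/455 per-outcome denominators)
is instead encoded directly in `fixture_outcome_records()`, because the
source reports the counts but not the joint missingness pattern that
produced them.

## Problem sizes and runtime

The packaged validation uses cohorts of 67 + 378 samples: 30 metabolites
(435 pairs) for calibration and planted-recovery studies, 186 for the QC
retention study, and 131 (8515 pairs) for the full workflow run — sizes
at which the whole validation completes in minutes on a single core
while the Monte-Carlo bands stay tight. Planted effects use
$r_\mathrm{case} = 0.6$ vs $r_\mathrm{control} = 0$, i.e. about 5 null
standard deviations at these group sizes, a regime where the test should
(and does) recover essentially all planted edges while the false-positive
rate among null pairs stays at the nominal level. An exhaustive-oracle
check at $n = 4 + 4$ compares sampled permutation p-values against
enumeration of all 70 label assignments.

## Known limitations

* Pairwise-complete correlations can use slightly different sample sets
  per pair; the per-pair $n$ enters the statistic, but no joint
  adjustment is made across pairs.
* The permutation null assumes exchangeable samples under the null;
  covariate-driven group structure (age, sex, BMI) is not modelled or
  adjusted for.
* With no multiplicity correction, edge counts at a fixed threshold
  scale with the number of candidate pairs.
* `cohort_summary()` reports whatever denominators arise from the
  supplied data; it does not attempt to reproduce unequal per-outcome
  denominators unless the input encodes them.
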