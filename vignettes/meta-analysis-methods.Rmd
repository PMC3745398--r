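---
title: "Genetic-association meta-analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-association meta-analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocmeta)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices
made where conventions diverge, and the known limits of the shipped
example.

## The data model

The unit of analysis is a published case-control *study row*: subject
counts, either genotype counts `(AA, AG, GG)` for cases and controls or a
risk-allele frequency (RAF) with sample sizes, plus the moderators used
downstream (ethnic group, study design, control source, genotyping method).
Optional *stratum rows* carry case subtypes — ER/PR receptor status or
invasiveness — that are contrasted against the parent study's full control
group, mirroring how subtype analyses are published.

Free-text ethnicity labels are mapped to four analysis groups (White, East
Asian, African, Other) by an editable two-column table. Two rules are
mapping policy rather than data: multi-population labels
(`"European, Asian"`) take the first listed population, because aggregated
rows cannot be split without the unpublished per-ethnicity counts; and
Tunisian studies are grouped African. Both choices live in
`ethnicity_map.tsv` so a user who disagrees edits a file, not code.

## Per-study effects

Effects are Woolf log odds ratios: for a 2x2 table with cells `a, b, c, d`,

\[ \hat\theta = \ln\frac{ad}{bc}, \qquad
   \widehat{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}. \]

Five contrasts are supported for risk allele A: allele (A vs G counts, two
per subject), dominant (AA+AG vs GG), recessive (AA vs AG+GG), and the
co-dominant pair, heterozygous (AG vs GG) and homozygous (AA vs GG). The
co-dominant contrasts *drop* the excluded genotype class from the
denominators — the standard pairwise reading; retaining it would mix the
baseline group across contrasts. The risk-allele orientation is fixed by
the data model (tables are never auto-flipped on sign).

Numerical choices:

* **Continuity correction.** 0.5 is added to all four cells only when a
  zero cell occurs (Haldane-Anscombe). At the sample sizes of this
  literature the correction never fires on real rows; it exists for
  degenerate strata. Tables with an empty margin (e.g. `a = c = 0`) are
  flagged non-estimable and excluded from pooling with a log entry rather
  than patched.
* **Confidence intervals** use the normal quantile 1.959964 throughout;
  Woolf's method is asymptotic and all reported CIs are 95%.
* **RAF reconstruction.** Studies publishing only RAF + N get an allele
  table `a = round(2 N p)`, `b = 2N - a`, with half rounded *away from
  zero* so results are platform-deterministic. Rounding perturbs the log OR
  by at most about `0.5 (1/a + 1/b)` per arm — negligible (< 0.2%) for
  N in the thousands at moderate frequencies, but up to ~0.5-1% for small
  studies at extreme frequencies. This matters for the shipped example
  (below).

## Pooling and heterogeneity

Three estimators are always available:

* inverse-variance fixed effect, weights `w_i = 1/v_i`;
* Mantel-Haenszel fixed effect on the raw tables,
  `OR_{MH} = \sum (a_i d_i/n_i) / \sum (b_i c_i/n_i)`, with the
  Robins-Breslow-Greenland variance for its log — preferable when some
  strata are sparse since it needs no per-study variance;
* DerSimonian-Laird random effects:
  `\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\}`,
  then re-weighting by `1/(v_i + \tau^2)`.

The random-effects estimate is the headline: between-study heterogeneity is
expected a priori when pooling across ethnic groups whose allele
frequencies range from ~0.06 to ~0.75. `\tau^2` and `I^2` are truncated at
zero exactly as in their defining method-of-moments forms; no REML or
Paule-Mandel alternatives are offered in core, keeping every pooled number
a deterministic closed form (and hence exactly testable). All p-values are
two-sided; Cochran's `Q` is referred to `\chi^2_{k-1}`.

**Subgroups.** Between-subgroup heterogeneity uses the fixed-effect Q
decomposition: total `Q` splits *exactly* into within-group sums plus
`Q_{between} = \sum_g W_g (\hat\theta_g - \hat\theta)^2`. The headline
per-group estimates are DL random effects while the decomposition is
computed on fixed-effect group means — this keeps the identity exact (it is
asserted to 1e-8 in the tests) while reporting the conservative estimates.

**Meta-regression** generalizes DL to a design matrix: with
`P = W - WX(X'WX)^{-1}X'W`, the residual moment estimator is
`\tau^2 = \max\{0, (Q_E - (k-p))/\mathrm{tr}(P)\}`, followed by weighted
least squares with `1/(v_i + \tau^2)` and z tests. Knapp-Hartung
adjustments are deliberately out of scope. The coding of moderators is a
configuration the caller owns; the `analysis/` scripts code sample size as
log10 of total subjects and genotyping method as an array-vs-assay
indicator, and make no claim of reproducing any particular published
meta-regression p-value, whose coding was not published.

**Subtype contrasts** pool each stratum (e.g. ER+ and ER-) against the
shared controls and compare the pooled log ORs with a z test that treats
the two strata as independent. They are not independent — they share
controls, so their estimates are positively correlated and the test is
mildly conservative — but the covariance is not recoverable from
study-level counts. The report object records this assumption.

## HWE screening

Control genotype distributions are tested with the Pearson chi-square
against expectations `n p^2, 2np(1-p), n(1-p)^2` at the sample allele
frequency, on 1 df. The inclusion rule excludes studies deviating at
`alpha = 0.05`; both the test form and the threshold are conventions (the
inclusion criterion in this literature names only "consistency with HWE"),
so alpha is a parameter. Rows publishing only RAF cannot be tested; they
are retained with an explicit `not_testable` flag, because exclusion would
discard studies for missing information rather than evidence — on the
shipped table this exempts all 26 rows. Monomorphic samples return
`chi2 = 0, p = 1` and a flag rather than NaN.

## Publication bias and sensitivity

Egger's test regresses the standardized effect `y_i/se_i` on precision
`1/se_i` by OLS and t-tests the intercept on k-2 df. Begg's rank
correlation computes Kendall's tau between the fixed-effect standardized
deviates and the sampling variances, with tie-corrected variance and a
continuity correction — ties are routine in reconstructed tables, which is
why the tie correction is not optional. Funnel asymmetry is exported as
coordinates, never "corrected": no trim-and-fill, matching how this
literature treats funnel plots as a visual check. Leave-one-out influence
re-pools k times and flags whether any omission crosses the OR = 1
significance boundary.

## The synthetic-study generator

The generator exists so that every stage is testable without external data
and so that parameter recovery — not just unit arithmetic — is part of the
acceptance surface. Per study it draws: an ethnic group from a mixture; a
control RAF from a per-ethnicity Beta distribution; a study odds ratio
`\lambda_i = \exp\{N(\ln\lambda, \tau^2)\}`; control genotypes multinomial
at HWE probabilities; case genotypes multinomial at the HWE probabilities
re-weighted by `(\lambda_i^2, \lambda_i, 1)` for a per-allele model (or
`(\lambda,\lambda,1)` dominant, `(\lambda,1,1)` recessive), renormalized.
This exposure-odds weighting yields the target genotype odds ratios exactly
in expectation without positing a disease prevalence, and for the
per-allele model it coincides with HWE at the case allele frequency
`p_1 = \lambda p_0 / (\lambda p_0 + 1 - p_0)` — an identity the tests
assert exactly.

Defaults describe the 2q35 literature and are *conditions, not dials*:
ethnicity mix 26/9/7/2 over 44 (the published dataset counts), Beta means
0.51 / 0.12 / 0.72 / 0.55 for White / East Asian / African / Other
controls, concentrations (600, 120, 80, 40) chosen once so the study-level
spread matches the within-group spread of the published table, per-allele
OR 1.14, `\tau^2 = 0.002` (the order of magnitude the reconstruction itself
estimates), arm sizes log-uniform on [500, 20000] (the central bulk of
published sizes). Subtype defaults: ER+ OR 1.17, ER- 1.08, PR+ 1.18,
PR- 1.10, with 70% / 65% receptor-positive prevalence among cases. ER
strata partition the case arm and sum to the whole-study row; PR strata are
an independent re-partition of the same cases, since study-level data do
not constrain the ER x PR joint distribution.

What the generator does *not* emulate: linkage disequilibrium with causal
variants, covariate-adjusted estimates, genotyping error (the very thing
HWE screening exists to catch), selective publication, or correlated
multi-row publications. Passing recovery tests therefore show the
*estimators* are consistent and calibrated under the stated model — they do
not certify robustness to those real-data failure modes.

All randomness flows from the single `seed` in the configuration;
the same configuration reproduces the same table byte for byte.

## Problem sizes used by the test suite

Chosen to make Monte-Carlo error small relative to the tolerances while
keeping a default run quick:

* parameter recovery: k = 30 studies of 2000/2000 subjects, 500 replicates
  per heterogeneity level (`\tau^2` of 0 and 0.002); bias tolerance 0.02 on
  the log scale, CI coverage required in [0.92, 0.975];
* subtype recovery: k = 12 studies of 3000/3000, 200 replicates; the ER+
  vs ER- difference sign must be recovered in at least 90%;
* calibration: HWE chi-square at n = 1000, p = 0.3 (5000 replicates,
  tolerance 0.01 around 0.05); Cochran's Q on homogeneous k = 10
  collections (2000 replicates, tolerance 0.015); Egger on unbiased normal
  meta-analyses with k = 26 (1000 replicates, tolerance 0.02);
* the meta-regression sign-recovery property uses large per-study sizes
  (50,000 per arm): the ethnicity effect it must detect is 0.018 on the log
  scale, and at published-literature scale (hundreds of thousands of
  subjects in total) sampling noise must sit well below the between-study
  variance for the sign to be identifiable at all.

## Limits of the shipped example

The published 2q35 analysis pooled 44 ethnicity-split, genotype-level
datasets; what is printed — and therefore what ships — is 26 aggregated
rows with frequencies rounded to two decimals. Reconstruction from those
rows is faithful to the printed data but not to the unpublished raw data:
three large East Asian studies print identical case/control RAFs (0.11,
0.10, 0.10) and so contribute an OR of exactly 1.00 that the genotype-level
analysis did not see, and aggregated multi-ethnic rows blur the
ethnicity-specific effects. The acceptance script consequently reproduces
the qualitative findings (a significant per-allele association, GWAS
subgroup above candidate-gene, non-significant bias tests, deletion
stability) and a pooled random-effects OR close to, but a few percent
below, the published point estimate. Genotype-model and subtype results
cannot be recomputed from printed data at all; they are covered by the
simulation-recovery properties instead.
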