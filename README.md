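# assocmeta

Meta-analysis of SNP case-control association studies in R: per-study odds
ratios under the standard genetic models, fixed- and random-effects pooling,
heterogeneity quantification and exploration, publication-bias diagnostics,
leave-one-out sensitivity analysis, Hardy-Weinberg filtering, and a
synthetic-study generator for calibration and parameter-recovery testing.

## The problem

Genome-wide association studies report susceptibility variants whose
replications across ethnic groups are often inconsistent. Study-level
meta-analysis reconciles them: each case-control study contributes a 2x2
contrast table (risk-allele vs other-allele counts, or genotype-based
contrasts), and the per-study odds ratios are pooled while quantifying how
much they genuinely disagree. The package implements this workflow for the
unit of analysis used throughout that literature — the published study row:
genotype counts `(AA, AG, GG)` in cases and controls, or a risk-allele
frequency (RAF) plus sample sizes when only those were printed.

The worked example throughout is the breast-cancer susceptibility locus
2q35-rs13387042 (risk allele A): a shipped 26-study table
(101,529 cases / 167,363 controls) with RAF and sample sizes per study,
spanning White, East Asian, African and other populations.

## Methods at the core

* **Per-study effects (Woolf):** `log OR = ln(ad/bc)`,
  `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, Haldane-Anscombe +0.5 correction only
  when a zero cell occurs. Contrasts: allele (A vs G), dominant
  (AA+AG vs GG), recessive (AA vs AG+GG), and co-dominant
  (AG vs GG, AA vs GG).
* **Fixed effects:** inverse-variance weighting, and Mantel-Haenszel
  `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` with the
  Robins-Breslow-Greenland variance.
* **Random effects (DerSimonian-Laird):**
  `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, re-weighting by
  `1/(v_i + tau2)`.
* **Heterogeneity:** Cochran's `Q`, `I2 = max(0, (Q - df)/Q)`; exact
  fixed-effect decomposition of `Q` into within- plus between-subgroup parts;
  method-of-moments meta-regression on study-level moderators.
* **Bias and sensitivity:** Egger regression of standardized effect on
  precision (t test on the intercept, k-2 df), Begg-Mazumdar rank
  correlation (tie-corrected Kendall tau with continuity correction),
  funnel-plot export, and leave-one-out re-pooling.
* **HWE screening:** Pearson chi-square (1 df) of control genotypes against
  Hardy-Weinberg expectations; deviating studies are excluded, RAF-only
  studies are flagged untestable.
* **Simulator:** controls drawn in HWE at ethnicity-dependent RAF, cases by
  exposure-odds re-weighting of the HWE genotype probabilities, log-normal
  between-study heterogeneity, optional ER/PR subtype strata sharing the
  study's controls.

## Worked example

```r
library(assocmeta)

tab <- read_study_table(system.file("extdata", "table1.tsv",
                                    package = "assocmeta"))
eff <- study_effects(tab, model = "allele")
pool_dersimonian_laird(eff)
#> Pooled allele (DL_random, k = 26)
#>   OR = 1.1147 [1.0843, 1.1461], Z = 7.679, P(Z) = 1.6e-14
#>   Q = 85.821 (df = 25), P(Q) = 1.36e-08, I2 = 70.9%, tau2 = 0.00267
```

The A allele is associated with increased odds of disease (pooled OR 1.11,
CI excluding 1), with substantial between-study heterogeneity (I2 = 71%).
Stratification shows the heterogeneity is largely ethnic:

```r
subgroup_analysis(tab, "allele", "DL_random", "ethnic_group")
#> Subgroup analysis by ethnic_group (allele model, DL_random)
#>   African      k =  5  OR = 1.0800 [1.0187, 1.1449]  P(Q) = 0.359
#>   EastAsian    k =  6  OR = 1.0894 [0.9682, 1.2257]  P(Q) = 0.0404
#>   Other        k =  1  OR = 1.7861 [1.3672, 2.3334]  P(Q) = NA
#>   White        k = 14  OR = 1.1216 [1.0903, 1.1539]  P(Q) = 1.67e-06
#>   Between-subgroup Q = 18.368 (df = 3), p = 0.000369
```

Bias diagnostics and sensitivity analysis:

```r
bias_report(eff)
#> Publication-bias diagnostics (k = 26)
#>   Egger: intercept = -0.6861 (SE 0.6072), t = -1.130, p = 0.27
#>   Begg:  tau = 0.1200, z = 0.838, p = 0.402
influence_analysis(tab)
#> Leave-one-out influence (DL_random, allele model, k = 26)
#>   full OR = 1.1147 [1.0843, 1.1461]; omission range [1.1082, 1.1205]
#>   no omission crosses the OR = 1 significance boundary
```

Neither test suggests small-study bias, and no single study moves the pooled
OR materially or across the null.

The numbered scripts under `analysis/` run this sequence end to end
(effects, pooling, subgroups + meta-regression, bias + influence, and a
simulation-based parameter-recovery study), writing their tables under
`results/`. `run_pipeline(run_config(...))` performs the same orchestration
programmatically and writes a complete report bundle.

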