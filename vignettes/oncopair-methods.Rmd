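---
title: "oncopair: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oncopair: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the pipeline does

`oncopair` searches for miRNA–mRNA interaction pairs that are conserved
across many tumour types. microRNAs predominantly repress their targets,
so a genuine interaction should show up as a miRNA and a gene that are
differentially expressed in *opposite* directions in the same tumour
types, whose expression is *negatively* correlated across tumour samples
once copy-number and methylation effects on the gene are accounted for.
The pipeline chains seven stages:

1. **Cohort validation** — a tumour type is analysed only if it has ≥ 10
   control samples and controls make up ≥ 5% of its samples. Two-group
   tests with fewer healthy samples are too unstable to trust.
2. **Differential expression** per tumour type — CPM < 1 filtering, TMM
   normalization, a negative-binomial exact test with a common
   dispersion, BH correction; features with FDR < 0.05 and |log2FC| > 1
   (both strict) are called DE.
3. **Pathway enrichment** — two-sided Fisher tests of the DE genes
   against seven hallmark cancer pathways (apoptosis, necrosis,
   senescence, DNA-damage response, cell cycle, DNA replication,
   telomere elongation), with the sample odds ratio ad/bc giving the
   direction: enriched (more altered than expected) or depleted
   (behaving more like healthy tissue).
4. **Cross-tumour recurrence** — a feature's recurrence is the number of
   distinct tumour types in which it is DE (in either direction; a gene
   may be up in some types and down in others). The recurrence cut-off
   can be chosen by scanning thresholds 5–10 and picking the one with
   the best right-tailed Fisher enrichment of known cancer genes or
   miRNAs; the pipeline default is 8.
5. **Pairing** — candidate pair instances join a DE miRNA and an
   inversely DE gene of the same tumour type through a predicted-target
   catalogue edge with genomic agreement ≥ 2 (two independent prediction
   methods at the same 3′ UTR position), with genes restricted to the
   pathway universe. Pairs whose members are both recurrent are
   *conserved*; pairs occurring in exactly one type (or only within a
   named type group, e.g. the two lung carcinomas) are *exclusive*; a
   right-tailed Fisher test on the instance table flags *highly
   specific* pairs whose partners have few co-interactors; pairs are
   marked novel or validated against a known-interaction list.
6. **Covariate-adjusted regression** — for every conserved pair, OLS of
   the gene's log2(RPKM+1) on the miRNA's log2(RPKM+1) in the tumour
   samples of each type, adjusting for the gene's CNA level (categorical
   factor over −2..2) and each methylation probe (M-values); plus a
   joint model over all types adding cancer type (sum-to-zero contrasts)
   and its interaction with the miRNA. The signed correlation is
   `sign(beta_mir) * sqrt(SS_mir / (SS_mir + SS_resid))` from Type-III
   ANOVA — the variance fraction attributable to the miRNA after the
   other factors. BH runs over the whole pair × dataset family
   (15 per-type + 1 joint = 16 datasets per pair). The final selection
   keeps pairs with *negative* joint correlation at FDR < 0.05.
7. **Survival** — per tumour type, Cox proportional hazards of survival
   on binary prognosis (stages I–II good vs III/IV/X bad; Gleason 6–7 vs
   ≥ 8 for the prostate-like type) plus the gene's log2 expression. A
   pair is *supported* in a type when both its per-type correlation and
   its gene's stage-adjusted survival association reach FDR < 0.05.

## The differential-expression engine

The exact test treats each feature's counts in the two groups as
negative binomial with a shared mean proportion and a **common
dispersion** φ (variance μ + φμ²). The steps:

- Effective library sizes are raw depths times TMM factors. Counts are
  mapped to **pseudo-counts** at the geometric-mean effective library by
  a quantile adjustment (percentile under a normal and a gamma
  approximation to the NB, averaged — accurate over the whole count
  range and smooth in the output). Extreme tail underflow falls back to
  linear scaling.
- φ is estimated by maximizing the conditional likelihood of the
  pseudo-counts given their group totals, profiled over
  δ = φ/(1+φ) ∈ (1e-6, 0.95); a method-of-moments estimate is the
  fallback when the optimizer fails or hits the boundary. Pseudo-counts
  and dispersion are iterated twice, which is enough for the estimate to
  stabilize.
- Given group sums (s₁, s₂) of n₁ and n₂ samples, group sums are
  NB(nⱼλ, φ/nⱼ); conditional on s₁+s₂ the two-sided p-value sums the
  probabilities of all splits at most as probable as the observed one
  (the same probability-ordering convention as the Fisher exact test —
  no "doubling" of the smaller tail). At φ = 0 this reduces exactly to a
  conditional binomial test, which is how the implementation is checked
  against exhaustive enumeration.
- log2 fold changes use normalized group means with a prior count of
  0.125 per group so zero counts give bounded estimates.

The engine's calibration is validated by simulation (type-I error within
[0.035, 0.065] at nominal 0.05 on 2,000 null features, 10 vs 10 samples,
φ = 0.1; power ≥ 0.9 for a planted four-fold change at mean count 100).
Numerical identity with any particular external implementation is not
claimed.

**TMM details.** The reference sample is the one whose upper-quartile
CPM is closest to the mean upper quartile. M and A values are computed
over features positive in both libraries, doubly trimmed (30% on M, 5%
on A, rank-based with first-occurrence tie-breaking), and combined with
inverse delta-method-variance weights. Factors are rescaled to geometric
mean 1. Fewer than one surviving feature yields factor 1 with a warning.

## Statistical conventions

- **Fisher tests** are computed directly from the hypergeometric
  distribution (`dhyper`), two-sided by probability ordering with the
  conventional 1e-7 relative tie tolerance — the same definition as
  `stats::fisher.test`, which the tests use as an independent
  cross-check. The reported odds ratio is the sample ad/bc (∞ and NaN
  allowed at zero cells); a Haldane–Anscombe 0.5-corrected OR is carried
  alongside for display and for ranking threshold scans where raw ORs
  are infinite. P-values always come from the uncorrected table.
- **BH correction** is `stats::p.adjust(method = "BH")` behind a
  validating wrapper; each stage states its own family (per-type DE
  features; seven pathways; scanned thresholds; all specificity pairs;
  all pair × dataset regressions; all gene × type survival tests).
- **Recurrence threshold ranking**: at thresholds where every known
  feature is selected the raw OR is infinite for all looser cut-offs
  too; ranking by the corrected OR makes the tightest such cut-off win,
  and remaining ties break toward the smaller threshold (more inclusive,
  conservative toward discovery).
- **Specificity table**: the informal notion — a pair that recurs in
  many tumours while each partner has few co-interactors — does not pin
  down a unique 2×2 layout; the default pools both margins over all pair
  instances: `[[#(m,g), #(m,¬g)], [#(¬m,g), #(¬m,¬g)]]`, right-tailed.
  One-sided variants (`margin = "mirna"`/`"gene"`) that compare one
  partner's split against the other partner's overall frequency are
  exposed for sensitivity analysis.
- **Type-III ANOVA** uses `car::Anova` on `lm` fits with sum-to-zero
  contrasts for all factors, so the miRNA main effect in the joint model
  (which contains a miRNA × cancer-type interaction) is the average
  within-type slope and its SS is contrast-invariant. The correlation
  uses the partial variance fraction SS/(SS+SS_resid) rather than
  SS/SS_total: in the joint model the latter would be diluted by
  between-type expression differences, and the partial form reduces to
  the Pearson correlation in simple regression (tested to 1e-10).
- **Cox models** use `survival::coxph` with Efron tie handling
  (configurable). Effects are reported per unit of log2 expression,
  both as natural-log HR and log2(HR). Non-convergent or degenerate
  fits are flagged and excluded from the FDR family.
- **Aliased or constant covariates** (methylation probes with variance
  < 1e-12, collinear probes) are dropped with a warning; samples with
  missing CNA/MET are excluded (complete-case; imputation is out of
  scope). Models with fewer samples than coefficients + 2 are declared
  `nonexistent`, reported with correlation 0, and excluded from FDR.

## The synthetic cohort generator

Controlled-access tumour data cannot ship with a package, so every stage
is validated against `generate_cohort()`, which plants known structure:

- **Counts**: NB (var = μ + φμ², default φ = 0.1) around a log-linear
  mean: per-feature baselines N(5, 1.5²) log2 units for genes (miRNAs
  +3, as mature miRNA libraries concentrate on fewer species), library
  sizes log-normal(log 1e6, 0.3) so normalization is non-trivial.
- **Planted DE**: 15% of features carry a ±2 log2-unit shift in the
  tumour samples of 10 of the 15 types (sampled per feature). The 30
  planted pairs tie an up-miRNA to a down-gene (or vice versa) sharing
  one type set; the gene additionally responds to the partner miRNA's
  centred log2-RPKM with slope −0.5.
- **Confounders**: per-gene CNA levels drawn symmetrically
  (P(0) = 0.74, ±1 0.10, ±2 0.03) shift expression by 0.3 log2 units per
  level; three methylation probes per gene (M-values normal around a
  probe baseline, β = logistic(M)) shift it by 0.2 per mean-M unit.
  Both apply to tumour samples; controls carry the *expected value* of
  each term, so confounders create within-tumour variance without
  faking control-vs-tumour differences.
- **Survival**: exponential event times with hazard
  (1/730) · exp(0.8·bad_stage + 0.7·z(gene expression)) for the planted
  survival genes, independent exponential censoring tuned to a 40%
  censoring fraction. Each survival gene acts in 5 of the 15 types:
  with all planted genes active everywhere, single-gene Cox fits suffer
  omitted-covariate attenuation strong enough to erase every call, and
  type-restricted effects match the observation that pair–survival
  support in real pan-cancer data is mostly single-type. One type
  carries Gleason grades instead of stages to exercise that coding.
- **Catalogue and lists**: planted pairs appear with agreement 2–5;
  10× as many decoy edges are emitted, half at agreement 1 (rejected by
  the filter) and half non-interacting at agreement ≥ 2 (candidates the
  statistics must reject). Known-gene/miRNA lists mix planted features
  with random decoys; half the planted pairs are listed as "known" so
  novelty flags exercise both branches.
- **Sample sizes**: 12 controls and 40 tumours per type — the asymmetry
  of real tumour cohorts, sized so a full 15-type, 500-gene, 150-miRNA
  run takes about half a minute and ten independent seeds stay within a
  routine test run.

What the generator does **not** emulate: read-level noise, isoform
structure, miRNA seed biophysics, correlated CNA/methylation segments
(the joint CNA/MET distribution is independent across genes and samples
— a modelling choice, not data-derived), shared regulatory programs
among decoy features, or the heavy-tailed dispersion heterogeneity of
real RNA-seq. Passing the recovery tests therefore demonstrates that the
statistics do what they claim under their own assumptions, not that real
tumour cohorts will yield comparable pair counts.

In this synthetic regime background promiscuity is low, so most
conserved pairs also pass the specificity test; on real catalogues,
where miRNAs have hundreds of predicted targets, the specificity test is
far more selective.

## Problem sizes used in validation

The test-suite simulations use the default conditions above: ten
independent seeds for end-to-end pair recovery (≥ 90% of planted pairs
recovered, false-discovery proportion ≤ 0.10, and a ≤ 8% pass rate when
the planted slope is zero), 2,000-feature null panels for exact-test
calibration, 500-permutation nulls and 20-seed recovery panels (n = 300,
~60% events) for the Cox stage, and exhaustive enumeration up to total
count 40 (plus sampled tables to margin 50) for the Fisher machinery.
Unit tests use a reduced cohort (3 types, 60 genes, 24 miRNAs) where the
full conditions are unnecessary.

## Known limitations

- The common-dispersion model ignores feature-specific (tagwise)
  dispersion; strongly heterogeneous real data would need shrinkage
  methods out of scope here.
- The joint regression represents methylation by the gene-level mean
  M-value (probe sets are not comparable across tumour types); per-type
  models keep every probe.
- Exclusivity is descriptive: a pair "exclusive" to a type may simply
  be underpowered elsewhere.
- The specificity test conditions on the observed instance table and
  inherits its biases (e.g. catalogue coverage differences between
  miRNAs).
- Survival modelling assumes proportional hazards and uses a single
  binary stage covariate; no proportionality diagnostics are run.
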