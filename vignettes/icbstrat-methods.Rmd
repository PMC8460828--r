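---
title: "Methods: 9p21.3 loss, cold tumor-immune phenotypes, and ICT response stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 9p21.3 loss, cold tumor-immune phenotypes, and ICT response stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Homozygous deletion of the 9p21.3 locus — which removes the tumor
suppressors *CDKN2A* and *MTAP*, and frequently the neighbouring type I
interferon gene cluster — is among the most common somatic copy-number
events in solid tumors (roughly 13% of cancers). Tumors carrying this
deletion tend to present a "cold" immune microenvironment: fewer
infiltrating T/B/NK cells, reduced immune trafficking and activation
signaling, lower PD-L1 positivity, and elevated immunosuppressive
signaling. Clinically this translates into markedly lower response rates to
anti-PD-1/PD-L1 checkpoint therapy (ICT).

`icbstrat` packages the full analysis chain needed to test and apply these
observations: 9p21 genotyping from gene-level copy calls, an expression
surrogate when genomic data are unavailable, immune abundance and pathway
scoring, differential screens, exact response-rate statistics, a composite
TMB / 9p21 / PD-L1 response score, and survival stratification — plus a
synthetic-cohort generator that reproduces the statistical structure those
analyses assume, so every stage can be validated by parameter recovery.

## Genotyping model

Gene-level thresholded copy calls (GISTIC-style, integers in −2…+2) map to
states HD (−2), LOH (−1), WT (0), GAIN (+1/+2). Cohort labels follow three
rules: HD at *CDKN2A* or *MTAP* → **LOSS**; LOH at both → **LOH**; WT at
both → **WT**. The 4×4 state grid leaves seven combinations (single-locus
LOH, any gain) unassigned by those rules; we label them **OTHER** and
exclude them from WT-vs-LOSS contrasts explicitly rather than silently.
Tumors with truncating *CDKN2A* mutations can be removed via an explicit
exclusion list; the package performs no mutation calling.

The expression surrogate classifies a sample **hi_hi** when both *CDKN2A*
and *MTAP* are strictly above their within-cohort medians, **lo_lo** when
strictly below both, otherwise **mixed**. Strict inequalities are the
conservative reading of an "above/below the median" rule; ties land in
`mixed`. Because only ranks matter, the labels are invariant under any
strictly monotone transform of the expression values. Quartile
stratification uses average ranks cut at the 25/50/75 percentiles; when
every value is tied the shared mean rank sits just above the 50th
percentile, so the deterministic degenerate output is Q3 for all samples.

## Immune profiling

*Marker abundance.* The score of a cell population in a sample is the mean
log2 expression of its marker genes (MCP-counter-style absolute scoring).
Marker lists for the ten profiled populations (T cells, CD8 T cells,
cytotoxic lymphocytes, B lineage, NK cells, monocytic lineage, myeloid
dendritic cells, neutrophils, endothelial cells, fibroblasts) ship as an
editable GMT file rather than being hard-coded, since marker membership is
a curation decision, not an algorithmic one.

*ssGSEA.* Per sample, genes are ranked by expression (ties averaged) and a
pathway's enrichment is the running sum over the descending-rank walk of
the difference between the weighted in-set ECDF (weights `rank^alpha`,
`alpha = 0.25`, the common projection default) and the unweighted
out-of-set ECDF. Weights use ascending rank values so higher expression
carries more weight. With `normalize = TRUE` scores are divided by the
global max − min of the score matrix. Both `alpha` and the normalization
are exposed. Scores depend only on within-sample ranks.

*TCR diversity.* Richness is the number of clonotypes with positive
counts; Shannon entropy is computed in nats by default (`bits = TRUE`
rescales); the base is a reporting convention with no effect on
comparisons.

*Differential abundance.* Two-sided Wilcoxon rank-sum per feature — exact
when both groups have ≤ 25 samples and the data are tie-free, otherwise the
normal approximation with tie and continuity corrections; both modes can be
forced. Fold change for score matrices is a difference of group means
(scores are log2-scale); BH q-values are computed across features.

## Expression screens

The DEG screen computes fold changes on de-logged values (`2^x − 1`) with a
pseudocount, reported with the sign convention `signed_fc = −1/ratio` for
ratios below 1, so `|signed_fc| ≥ 1` always. Whether published fold-change
cutoffs like 1.2 refer to linear ratios or log differences is generally
ambiguous; the linear ratio is the default and a log-scale mode is
provided. BH correction runs over the tested gene list only (a curated
screen, not the transcriptome). The Spearman screen computes rho on average
ranks with the t approximation for p, and tiers anti-correlated candidates
at rho < −0.2 (moderate) and < −0.4 (strong).

## Outcome statistics

Durable clinical benefit is CR/PR, or SD lasting more than 6 months; SD
without a PFS time and non-evaluable responses are NA rather than false,
since they cannot be classified.

Fisher's exact test uses the two-sided sum-of-small-probabilities rule
(point probabilities ≤ observed, with 1e-7 relative tolerance). The r×c
generalisation (Freeman–Halton) enumerates margin-preserving tables, with a
seeded Monte-Carlo fallback when an enumeration bound is exceeded. The
likelihood-ratio test uses G² = 2·ΣO·ln(O/E) with 0·ln 0 = 0. The composite
response score awards 2 points for TMB strictly above the cohort median
(ties count as low), 1 for hi_hi, and 1 for immune-cell PD-L1 IC2+ (≥ 5%
staining), tiered low (0) / intermediate (1–2) / high (3–4); the 2:1:1
weighting reflects a logistic fit in which the TMB coefficient is about
twice the others, formalised in `derive_score_weights()` as
round-to-smallest with a floor of one. Samples missing TMB or PD-L1 are
excluded with a reason, mirroring how such cohorts are analysed in
practice. TMB units are treated as opaque because only median splits are
ever used.

When reproducing published cohort statistics from printed counts, two
conventions required identification: one urothelial-cohort p-value matches
the one-sided Fisher test (the two-sided value is 1.6-fold larger), and the
three-tier response-score p-value corresponds to the pairwise Fisher test
of the high vs low tiers, not the 2×3 omnibus (which is an order of
magnitude smaller). The acceptance artifacts report all conventions side by
side rather than silently choosing one.

## Survival

Kaplan–Meier curves use the product-limit estimator with events preceding
censorings at tied times; the median is the earliest time with S ≤ 0.5 (no
interpolation). Log-rank tests are the standard unweighted χ² with k − 1
degrees of freedom; for three-group comparisons both the omnibus test and
pairwise subsets are available by subsetting the strata vector. Cox models
use Efron tie handling (more accurate than Breslow with discrete-looking
months) with Wald intervals; monotone likelihoods and non-convergence are
flagged. The endpoint (OS/PFS/DSS) is a configuration choice because
published cohorts differ in which endpoint is mature.

## The synthetic cohort generator

The generator's defaults are the study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `freq_loss` | 0.13 | homozygous-deletion frequency (the pan-cancer rate) |
| `freq_loh` | 0.25 | hemizygous-loss frequency |
| `delta_hd` | 3.0 log2 | *CDKN2A*/*MTAP* reduction under HD (strong) |
| `delta_loh` | 0.3 log2 | reduction under LOH (subtle) |
| `gamma` | −1.0 | latent infiltration shift in LOSS tumors |
| `marker_coupling` | 0.8 | log2 marker-gene change per unit infiltration |
| `immuno_up`/`immuno_down` | 0.6 | suppressive-up / trafficking-down shifts in LOSS |
| `hr_loss` | 1.8 | survival hazard ratio of LOSS tumors |
| `noise_sd` | 0.8 | residual log2 expression noise |

A single latent infiltration factor `z ~ N(gamma·[LOSS], 1)` couples
genotype to every immune feature (marker genes, stimulatory
immunomodulators, PD-L1 category via an ordered logit, TCR clonotype
richness via a Dirichlet-multinomial). One factor, rather than per-cell-type
factors, is the minimal structure that reproduces the correlated depletion
of T/B/NK scores observed in 9p21-loss tumors; it is a modeling choice, not
a biological claim. Response is Bernoulli with
`logit p = beta0 + beta_tmb·[TMB-high] + beta_surr·[hi_hi] + beta_pdl1·[IC2+]`
on the *observed* stratification flags, and survival is exponential with
the configured hazard ratio. All randomness flows from one seed with
per-table sub-streams, so edits to one stage's parameters do not perturb
another stage's draws.

The `imvigor-like` preset (`beta0 = −3.8`, `beta = (2.2, 1.2, 1.1)`) was
calibrated by simulation so the marginal hi_hi/lo_lo response rates land on
32%/12%, the rates of the large anti-PD-L1 urothelial cohort this preset
emulates; `melanoma-like` (`beta0 = −3.1`, `beta = (2.2, 2.1, 1.2)`,
`gamma = −1.2`) targets 60%/22%. The coefficient ratios depart from the
2:1:1 weighting of the response score because TMB is simulated independent
of the surrogate: matching the real cohorts' marginal rate gap then
requires a larger surrogate coefficient than a real cohort's partially
confounded factors would show. The `null` preset zeroes every effect for
false-positive-rate checks.

What the generator does **not** emulate: tumor purity, segment-level SCNA
geometry, batch effects, correlated TMB (TMB is independent of genotype
here, which real cohorts violate), non-proportional hazards, and dropout
patterns of real clinical annotation. Passing recovery tests therefore
demonstrates that the pipeline's statistics are correct and well
calibrated under its assumed structure — not that the biological effect
sizes are correct in any real cohort.

## Problem sizes and numerical choices

Recovery tests use 20 replicates of n = 2000 with fixed seeds, the scale at
which rate calibration windows ([0.28, 0.36] / [0.09, 0.15]) and ±20%
hazard-ratio recovery are comfortably identifiable; null checks use 15
replicates of n = 400. Oracle suites enumerate all 2×2 tables with N ≤ 40
(canonical representatives under transposition and row/column swaps, whose
invariance is asserted separately), 1000 random BH vectors, 5-gene ssGSEA
toys against a term-by-term running-sum evaluation, and full 126-assignment
Wilcoxon enumeration at n = (4, 5). Validation failures raise classed
conditions (`icb_validation_error`, `icb_parse_error`, …) rather than
silent coercion; degenerate inputs (all-tied quartiles, zero margins,
all-zero clonotype samples) have documented deterministic outputs.

## Pipeline interface

`run_pipeline()` executes genotyping → profiling → screening → outcome
statistics → survival from a single `pipeline_config()`, writing TSV
results with JSON sidecars (seed, config hash, payload checksum) and a run
manifest with per-stage exclusion accounting (included + excluded = input
at every stage). Each stage is equally usable as a plain exported function
— `generate_cohort()`, `genotype_9p21()`, `marker_abundance_scores()`,
`deg_screen()`, `response_rates_compare()`, `cox_fit()` — which is the
intended interface for interactive analysis; the pipeline wrapper exists
for reproducible end-to-end runs where byte-identical outputs under a fixed
seed matter.

## Known limitations

- The surrogate's median split is cohort-relative: labels are not
  transferable across cohorts and depend on cohort composition.
- The r×c exact test's enumeration bound is a cheap over-estimate; large
  sparse tables may be sent to Monte-Carlo mode earlier than strictly
  necessary.
- The penalized logistic fallback is a plain ridge fit, intended as a
  diagnostic under separation, not a publication-grade estimate.
- CNV genotyping keys only on *CDKN2A*/*MTAP* (plus the IFN cluster for
  co-deletion strata); whether a WT group should also exclude gains
  elsewhere in 9p21.3 is left to the caller's exclusion list.
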