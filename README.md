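# icbstrat

Immunogenomic stratification of immune-checkpoint-therapy (ICT) cohorts by
9p21.3 copy-number status.

Homozygous deletion of chromosome 9p21.3 — removing *CDKN2A*, *MTAP*, and
often the adjacent type I interferon gene cluster — occurs in roughly 13%
of solid tumors and is associated with a "cold" tumor-immune phenotype:
depleted T/B/NK infiltration, reduced immune trafficking/activation
signaling, lower PD-L1 positivity, and elevated immunosuppressive
signaling. Patients whose pre-treatment tumors carry this deletion respond
poorly to anti-PD-1/PD-L1 therapy. `icbstrat` implements the complete
analysis chain used to establish and apply that observation, for
statisticians and computational biologists working with bulk
transcriptomic + clinical ICT cohorts.

## What the package computes

- **9p21 genotyping** from GISTIC-style gene-level calls: HD of *CDKN2A* or
  *MTAP* → `LOSS`; LOH at both → `LOH`; diploid at both → `WT`; anything
  else → `OTHER` (explicitly excluded from contrasts). An expression
  surrogate (`hi_hi` / `lo_lo`: both genes strictly above / below their
  cohort medians) covers cohorts without genomic data, plus quartile
  stratification and IFN-cluster co-deletion strata.
- **Immune profiling**: marker-mean abundance scores for ten cell
  populations, single-sample gene-set enrichment (ssGSEA: rank-weighted
  running sum, `alpha = 0.25`), TCR richness and Shannon entropy, and
  Wilcoxon/BH differential abundance.
- **Screens**: curated-list differential expression (linear fold change
  with the `−1/ratio` sign convention, pass at |FC| ≥ 1.2 and q < 0.05) and
  a Spearman screen for targets anti-correlated with *CDKN2A*/*MTAP*
  (tiers at ρ < −0.2 and ρ < −0.4).
- **Outcome statistics**: durable clinical benefit (CR/PR or SD > 6
  months), exact 2×2 and Freeman–Halton r×c Fisher tests, likelihood-ratio
  G² tests, response-rate comparisons, logistic factor models, and the
  composite response score — 2 points for TMB above the cohort median, 1
  for `hi_hi`, 1 for immune-cell PD-L1 IC2+ (≥ 5%), tiered low(0) /
  intermediate(1–2) / high(3–4).
- **Survival**: Kaplan–Meier curves, log-rank tests, Cox
  proportional-hazards fits (Efron ties) over OS/PFS/DSS endpoints.
- **Synthetic cohorts**: a generator with a ground-truth ledger in which a
  latent infiltration factor, depressed under 9p21 loss, drives immune
  markers, PD-L1 and TCR diversity; calibrated presets (`imvigor-like`,
  `melanoma-like`, `null`) reproduce published marginal response rates for
  parameter-recovery testing.

## Worked example

```r
library(icbstrat)

co  <- generate_cohort(calibration_preset("imvigor-like", n_samples = 2000, seed = 7))
lab <- surrogate_from_expression(co$expr)
resp   <- setNames(co$clinical$response %in% c("CR", "PR"), co$clinical$sample_id)
groups <- setNames(lab$label, lab$sample_id)

rc <- response_rates_compare(resp, groups, c("hi_hi", "lo_lo"))
#> hi_hi: 164/579 (28%)  lo_lo: 89/579 (15%)  ratio 1.8
#> fisher_2x2: statistic = 2.174269, p = 1.20707e-07
```

The surrogate splits the cohort 579 / 579 / 842 (`hi_hi`/`lo_lo`/`mixed`);
the `hi_hi` group responds about 1.8× more often, and the exact test
rejects equal rates. Adding TMB and PD-L1 through the composite score
separates the cohort much more sharply:

```r
med <- median(co$clinical$tmb)
sc  <- compute_response_score(co$clinical$tmb, med,
                              groups[co$clinical$sample_id],
                              co$clinical$pdl1_ic, co$clinical$sample_id)
tab <- build_contingency(setNames(sc$tier, sc$sample_id),
                         ifelse(resp, "CR/PR", "SD/PD"))
#>                CR/PR SD/PD      response rate
#>   low             11   445      2.4%
#>   intermediate   146   854     14.6%
#>   high           224   320     41.2%
fisher_exact_rxc(tab)$p
#> 3.4e-20
```

Score-low patients are nearly exclusive non-responders (2.4%), while
score-high patients respond at 41% — the stratification pattern the score
was designed to produce. Genomic 9p21 loss also carries the configured
survival penalty:

```r
cx <- cox_fit(co$clinical$os_time, co$clinical$os_event,
              data.frame(loss = genotype_9p21(co$copy_calls)$group == "LOSS"))
#>      hr ci_low ci_high     p
#>   1.696  1.466   1.962  ~0        (generator truth: hr_loss = 1.8)
```

`run_pipeline(pipeline_config(...))` chains all stages end-to-end and
writes TSV results, JSON sidecars and an exclusion-accounting manifest;
identical config + seed gives byte-identical outputs.

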