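# cypddi

Literature-rule-based prediction of CYP-mediated drug–drug interactions
(DDIs) and retrospective-cohort assessment of their myopathy risk in
electronic medical records — as a tested, reusable R pipeline with
synthetic-data generators that expose their ground truth.

## Who this is for

Pharmacoepidemiologists and biomedical informaticians who want to screen
drug pairs for pharmacokinetic interaction potential from in vitro
literature (which drug is a substrate, which an inhibitor, of which
cytochrome P450 enzyme) and then test, in OMOP-like EMR tables, whether
joint exposure raises the risk of an adverse outcome — here myopathy
(myalgia, myositis, muscle weakness, rhabdomyolysis) — beyond what the two
drugs explain individually.

## The statistic at the core

For each predicted pair, patients fall into three 30-day exposure-window
cohorts: substrate alone, inhibitor alone, joint. With adjusted group risks
`Risk1`, `Risk2`, `Risk12` from a three-level logistic regression
(covariate standardization over age, sex, optionally co-medication count),
the synergy statistic is

```
RR = Risk12 / (Risk1 + Risk2)
```

`RR = 1` is exact additivity of the single-drug risks; `RR > 1` indicates a
synergistic interaction. The test of `H0: Risk12 = Risk1 + Risk2` is a
delta-method Wald test of `log(RR)` (seeded bootstrap as alternative),
two-sided, with Bonferroni control across pairs and an `RR > 1` direction
gate for significance. A companion additive model (joint vs substrate-alone
odds ratio) and a one-sided exact CYP enrichment test complete the
analysis. Upstream, sentence patterns (`[DEO]`, `[DOE]`, `[EOD]`, `[IDD1]`,
`[IDD2]`, `[DID]` and their permutations) and an extraction rule engine
(human assay systems, FDA probe reagents, negation handling) turn abstracts
into per-drug enzyme activities; enzyme sharing turns activities into
predicted pairs, with Ki-binned potency (strong < 10 µM, moderate
10–100 µM, weak > 100 µM).

## Worked example

```r
library(cypddi)
library(dplyr)

rr_statistic(0.022, 0.033, 0.093)
#> [1] 1.690909

run <- run_ddi_pipeline(ddi_pipeline_config(seed = 4, n_patients = 3000))
#> [...] simulate      51 knowledge-base activity rows
#> [...] simulate      60 abstracts
#> [...] screen        40 abstracts retrieved
#> [...] screen        16 in vitro assertions
#> [...] screen        12 drug-enzyme activities
#> [...] predict        7 predicted DDI pairs (unordered)
#> [...] simulate    3000 patients
#> [...] crossref       2 co-medicated pairs to test
#> [...] test           4 model fits
#> [...] test           2 significant synergistic pairs (p < 0.025)
#> [...] enrich         2 enzymes tested for enrichment

run$results |> filter(model == "synergistic") |> arrange(p_value) |>
  select(drug1, drug2, risk1, risk2, risk12, rr, p_value, counts)
#>      drug1    drug2 risk1  risk2 risk12   rr  p_value                  counts
#> 1 drug_001 drug_002 0.222 0.0998  0.839 2.61 7.04e-22 (81/364, 38/382, 52/62)
#> 2 drug_001 drug_003 0.221 0.1141  0.800 2.39 4.74e-18 (79/358, 42/366, 54/68)
```

The log is the analysis funnel (predicted → co-medicated → tested →
significant). Both significant pairs are exactly the ones the synthetic
EMR injected (`ground_truth(run$emr)$config$ddi_effects`: θ = 4 on
drug_001+drug_002 and drug_001+drug_003): the joint-group risk (0.84, 0.80)
far exceeds the sum of the single-exposure risks, the RR estimates sit
below the injected θ because the two injected pairs share drug_001 and
contaminate each other's single-exposure groups, and the counts column
reads "(m1/n1, m2/n2, m12/n12)" — events/size per exposure group.

Each stage is also a standalone verb on tabular data: `scan_patterns()`,
`filter_abstracts()`, `extract_invitro()`, `conclude_invivo()`,
`predict_pairs()`, `classify_potency()`, `crossref_emr()`,
`build_episodes()`, `apply_exclusions()`, `fit_additive()`,
`fit_synergistic()` (with `tidy()`/`glance()`/`autoplot()` methods),
`bonferroni_threshold()`, `enzyme_enrichment()`, `power_simulation()`, and
the generators `simulate_knowledge_base()`, `simulate_abstract_corpus()`,
`simulate_emr()`, `simulate_episode_groups()`.

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package, the
pipeline's reference quantities: the Bonferroni threshold for the 3670-pair
family, the myopathy prevalence implied by the packaged cohort summary
counts, the synergy RR statistic applied to the five packaged
published-risk triples, and the Monte-Carlo power of the synergistic test
for a 1.5-fold RR with a 110-patient joint group at the Bonferroni
threshold. Run it from the package root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/ddi-myopathy-pipeline.Rmd`) documents the
model, the rule systems, every numerical choice, what the synthetic world
does and does not emulate, and known limitations.
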