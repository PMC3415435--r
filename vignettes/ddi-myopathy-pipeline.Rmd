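---
title: "Predicting CYP-mediated drug interactions and testing their myopathy risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CYP-mediated drug interactions and testing their myopathy risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypddi)
library(dplyr)
```

## The problem

Most clinically important pharmacokinetic drug–drug interactions (DDIs) run
through the cytochrome P450 (CYP) enzymes: a *substrate* drug is cleared by
an enzyme, an *inhibitor* drug slows that enzyme down, and co-administration
raises the substrate's exposure. In vitro assays identify substrates and
inhibitors enzyme by enzyme, but they cannot say whether a predicted
interaction harms patients. `cypddi` chains the two worlds: a rule-based
literature screen turns abstracts into per-drug enzyme activities, enzyme
sharing turns activities into predicted DDI pairs, and a retrospective
cohort design over electronic-medical-record (EMR) tables tests whether
jointly exposed patients suffer more *myopathy* (myalgia, myositis, muscle
weakness, rhabdomyolysis — a recognised toxicity of many CYP substrates)
than the single-drug exposures explain.

Because neither the source EMR repository nor the curated abstract corpus
is distributable, the package carries a synthetic-data module whose
generators expose their ground truth, so every downstream stage is tested
against known parameters.

## Literature screen

Retrieval is a two-step rule system. Step one is a term template: an
abstract is kept only if it mentions at least one term from every required
category (drug name, enzyme name, enzyme-specific probe reagent, experiment
system, experiment type) and no prohibited term (oncology-study markers).
Step two scans each sentence for DDI-relevant token patterns over a
tagged vocabulary — drugs (dictionary longest-match, so multi-word names
are one slot), enzymes, and operator families `O1` (inhibit), `O2`
(substrate/metabolise/catalyse/probe), `O3` (induce), `INT` (interaction
verbs):

* single-drug patterns are any ordering of {drug, enzyme, operator} —
  tagged `DEO`, `DOE`, `EOD`, `OED`, `ODE`, `EDO` by the order observed;
* two-drug patterns are `IDD1` ("interaction between A and B"), `IDD2`
  ("impact of A on B") and `DID` ("A interacts with B").

Two numeric choices are deliberately config-exposed because the source
method defines token order only: consecutive pattern elements may be at
most `max_gap = 5` tokens apart, and a "not"/"no" token between the first
and last pattern element (window extended two tokens left, so a leading
"no impact of A on B" is caught) sets the `negated` flag. We do not require
a literal "by" in enzyme-first patterns: the order-generic rule subsumes
the enumerated forms and their permutation variants.

Extraction (`extract_invitro()`) replaces what was a manual curation step
with a deterministic rule engine over structured per-abstract annotations:
an assertion is accepted only from a human liver microsome/hepatocyte or
recombinant-CYP system, only when the reported probe is an FDA-listed probe
for that enzyme, and never from a negated sentence. `O2` operators assert
substrates, `O1` inhibitors, `O3` and `INT` nothing. In vivo study
conclusions (`conclude_invivo()`) default to the p-first rule — DDI if
p < 0.05, else fold-change > 2 when no p-value is reported — with a
stricter `conjunction` variant selectable, because the source text states
both readings in different places. Pregnant/newborn studies are excluded
outright; evidence with neither a p-value nor a fold-change is
`indeterminate`, distinct from `no-DDI`.

## Pair prediction and potency

Per enzyme, every (substrate, inhibitor) pair of distinct drugs is a
predicted DDI; pairs sharing several enzymes merge into one record, and
unordered deduplication (`pair_key`) is used for counting, since published
pair counts treat (A, B) and (B, A) as one. Inhibition potency bins Ki:
strong < 10 µM, moderate 10–100 µM, weak > 100 µM; the boundary values sit
in the moderate bin (the published notation `10 < Ki < 100` leaves them
unassigned — a documented package decision). Pair-level potency combines
metabolism route and inhibition strength on shared enzymes, in both drug
orderings. The default `methods` rule calls a pair strong only for
(major route, strong inhibitor); the published potency table, however,
labels one (minor route, strong inhibitor) pair strong, so a `table5` rule
reproducing that behaviour is selectable. The discrepancy is surfaced, not
resolved.

## Cohort design

Exposure windows are date-inclusive closed intervals
`[anchor − 30 d, anchor]` — "one month" is fixed at 30 days everywhere, so
a dispensing exactly 30 days before the anchor is in, 31 days is out. For
patients with myopathy, windows anchor at each myopathy date (or the first
only, in `first_event` mode) and the window content labels the group:
substrate alone, inhibitor alone, or joint. Patients without myopathy
anchor at the first substrate dispensing; when the two drugs were dispensed
at most 30 days apart the control is joint, anchored at the later
dispensing. The source design states control anchoring for substrates only;
we anchor inhibitor-alone controls at the inhibitor dispensing by symmetry,
flagged as an interpretation. Persons whose first myopathy event falls
within 183 days of the database start are excluded (an earlier event cannot
be ruled out), and pairs containing a drug used to treat myopathy symptoms
are flagged off the test list while their episodes remain available to
other pairs. The co-medication covariate counts distinct drug names in the
window including the index drugs ("total number of different medications");
a flag excludes them if wanted.

## The DDI tests

For each pair, three exposure groups with event/size counts
`(m1/n1, m2/n2, m12/n12)`:

* **Additive model** — logistic regression of myopathy on a
  joint-vs-substrate-alone indicator plus covariates; it asks whether
  adding the inhibitor raises the substrate's risk, and cannot separate an
  interaction from the inhibitor's own toxicity.
* **Synergistic model** — three-level exposure logistic regression; the
  synergy statistic is `RR = Risk12 / (Risk1 + Risk2)`, which equals 1
  under exact additivity of the single-drug risks.

The source tables print *adjusted* risks without defining the adjustment
target, so the package states one: covariate standardization
(g-computation) — the fitted model predicts every person's risk under each
group assignment and the group risk is the pooled average. This is
reproducible, and with no covariates it reduces *exactly* to the raw
proportions m/n (the three-group model is saturated), which a dual-route
test asserts against an independent glm + prediction oracle.

The synergy p-value method is also unstated in the source ("an additional
program calculated the relative risk"), so the package default is a Wald
test of log(RR) by the delta method — gradients of the standardized risks
with respect to the coefficients, mapped through the covariance matrix —
with a seeded stratified bootstrap as the alternative. In the
covariate-free case the delta variance has the closed form
`var(log r) = (1−p)/(np)` per group, which is what the calibration and
power simulations use; it is algebraically identical to the glm route.
Two-sided p-values are reported; the pipeline's significance rule
additionally requires the effect direction (> 1), matching how the source
counts significant pairs. Multiplicity is Bonferroni only
(`alpha / n_tests`); FDR is deliberately not added. Enzyme
over-representation among significant pairs uses a one-sided exact test on
the 2×2 table (the source cites an external enrichment method without
detail; the exact test is disclosed as our choice and checked against a
hypergeometric enumeration oracle).

Degenerate inputs: a zero-event or all-event joint group makes log(RR)
undefined — the fit is flagged and its p-value is `NA`, which simulations
count as a non-rejection. Complete separation in the additive model is
flagged, with a ridge-penalized odds ratio reported as fallback when
glmnet is available.

## The synthetic world

The generators' defaults are the conditions the source cohort states, and
they are not tuned:

| parameter | default | origin |
|---|---|---|
| per-window myopathy risk, female / male | 0.086 / 0.054 | published demographic effects |
| age effect | odds × 1.0015 per year, centred at the mean age | published estimate |
| female fraction | 0.591 | published cohort composition |
| age distribution | N(40.2, 23²), truncated to [0, 100] | published cohort |
| medications per window | Poisson, mean 3.8 | published medication frequency |
| study span | 2004-01-01 – 2009-12-31 | source database span |
| `baseline_window_risk` | 0 | free: the source reports no unexposed background rate |

Drug effects are additive on the risk scale (`base + drug_risks[d]`,
capped at 1 with a warning) because the synergy definition is on the risk
scale; a window jointly exposed to a configured pair gets
`θ·(Risk1 + Risk2)`, the quantity the synergistic test estimates as RR.
Sex is binary as in the published covariate analysis. Each patient has one
exposure window; dispensings fall inside it, and a myopathy event is dated
at the anchor, so the cohort builder reconstructs the generated groups
exactly. A marginal-calibration test checks that, at 50,000 patients with
no drug effects, the simulated female and male risks sit within 3 Monte
Carlo standard errors of 0.086 and 0.054.

What the generator does **not** emulate: multiple dispensing eras, dose
and adherence, time-varying confounding, code noise in the outcome
definition, and informative missingness. A green test therefore
establishes that the pipeline recovers what it claims from data obeying
its own design assumptions — not that those assumptions hold in any real
EMR. One visible consequence: the 6-month run-in exclusion removes a
constant fraction of cases, which perturbs the group risks slightly
asymmetrically, so end-to-end RR estimates sit a few percent above θ
while the direct group simulations recover θ within the stated 10%.

The null simulation under θ = 1 puts the two-sided empirical size of both
tests inside the 95% binomial envelope of α = 0.05 over 2,000 replicates
(the direction-gated rule rejects at ≈ α/2 by construction, so size is
assessed two-sided). For the additive model the θ = 1 null is
`Risk12 = Risk1`, which only holds when the inhibitor carries no risk;
`power_simulation(model = "additive")` therefore scales `risk1` rather
than the risk sum. Power at the published statin-pair scale — joint group
of 110, single risks ≈ 2.5%, 1.5-fold RR, Bonferroni threshold
0.05/3670 — is well below the quoted 15% ceiling (about 0.5–1% across
seeds), which is why well-known statin interactions could not reach
significance in a cohort that size.

## Worked example

```{r example, eval = FALSE}
run <- run_ddi_pipeline(ddi_pipeline_config(seed = 4, n_patients = 3000))
run$funnel
syn <- run$results |> filter(model == "synergistic") |> arrange(p_value)
syn
plot_ddi_results(syn, threshold = run$threshold)
```

The funnel log reproduces the published structure — predicted pairs,
co-medicated pairs, tested pairs, significant pairs — on the synthetic
inputs, and the injected pairs surface as the top hits.

## Known limitations

* The IE rule engine consumes structured annotations; it does not parse
  assay conditions out of free text (the original step was human).
* No drug-era stitching, dose, days-supply or adherence modelling; no
  propensity scores or matched controls (the source mentions matching only
  as future work).
* The enrichment and synergy-test families are package choices where the
  source is silent; both are documented above and tested against
  independent oracles rather than against the source's unpublished code.
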