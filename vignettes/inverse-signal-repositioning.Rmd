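---
title: "Inverse-signal drug repositioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse-signal drug repositioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inversig)
```

## Overview

`inversig` implements a repositioning pipeline that treats
under-reporting in a spontaneous adverse-event database as a therapeutic
hint.  A drug–event pair reported significantly *less* often than chance
(an **inverse signal**) suggests the drug may protect against the event;
when the event is a diagnosable disease, such drugs are candidates for
repositioning.  The pharmacovigilance evidence is then cross-checked
against the signature-reversion principle: candidate compounds should
*reverse* the disease's gene-expression signature, and their reversal
scores should correlate with the strength of their inverse signals and
with independent potency measurements (IC50).

This vignette describes each model, its assumptions, the tunable
parameters, and the design decisions taken where the methodology left
choices open.  Every empirical statement here is computed by the test
suite or the demo run; none is asserted from memory.

## Disproportionality statistics

Each drug–event pair is summarised by a 2×2 table: `a` reports with the
drug and the event, `b` with the drug and another event, `c` with
another drug and the event, `d` with neither; `n = a+b+c+d` and the
expected count under independence is `E = (a+b)(a+c)/n`.  The counting
unit is the unique (report, drug, event) triplet — each report
contributes at most one count per pair; the database itself does not fix
this unit, so it is stated here explicitly.

**ROR.**  `ROR = ad/(bc)` with the Wald interval
`exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.  Any zero cell leaves the ROR
undefined (the pair is then never flagged); a Haldane–Anscombe +0.5
correction is available behind an argument but off by default, so the
default statistic is the textbook estimator.

**IC.**  The information component is the regularised log2
observed/expected ratio `IC = log2((a+½)/(E+½))`.  Its credible bounds
are the exact 2.5th/97.5th percentiles of a Gamma(a+½, E+½) posterior
(on the log2 scale), whose mean is the regularised ratio.  The classical
presentation of the IC gives a two-term asymptotic variance
approximation instead; the exact-quantile form is used here because it
is verifiable against a numerical quantile oracle and is the modern
regularisation of the same quantity.

**EBGM.**  The gamma–Poisson shrinker models `a ~ Poisson(λE)` with
`λ ~ p·Γ(α₁,β₁) + (1−p)·Γ(α₂,β₂)`.  The five prior parameters are
estimated by maximising the marginal likelihood (a mixture of negative
binomials) with L-BFGS-B on log-transformed parameters, five seeded
random restarts around the classical diffuse starting point, and a
convergence tolerance of 1e-8 on the log-likelihood.  The posterior is
again a two-gamma mixture, so
`EBGM = 2^{E[log2 λ | a]}` has a digamma closed form per component, and
the 5th/95th posterior percentiles (EB05, EBGM95) are found by monotone
root-finding on the mixture CDF.  "Upper limit of the 90% interval" is
read as the 95th percentile of the posterior (a two-sided 90% interval);
EB05 is reported as well because it is the conventional lower bound in
pharmacovigilance.  No stratification is applied.  Cells with `a = 0`
participate in the prior fit and in IC/EBGM but not in the ROR, matching
each statistic's domain.

**Inverse-signal thresholds** are strict: ROR_UCI < 1, IC975 < 0,
EBGM95 < 1.  On null data the IC tends to flag at least as many inverse
pairs as the ROR; the suite checks this as a statistical tendency, not
as a hard guarantee.

## Report preprocessing

Deduplication keys on the case identifier and keeps the version
maximising (event date, version id) lexicographically — "most recent
version", with the version-id tie-break made explicit because the
recommendation behind the rule does not state one.  Three filters
follow: primary-suspect drug rows only; exclusion of the uninformative
event terms "drug ineffective" and "medication error" (case-insensitive;
a report whose every event term is excluded is dropped); and removal of
combination products, detected as a separator (`/`, `\`, `+`, or
`" AND "`) between two alphanumeric tokens, plus an optional curated
list — the reporting format has no structured ingredient field, so a
lexical rule is the only desk-scale option.  Drug names are uppercased,
whitespace-collapsed and stripped of trailing dosage tokens; no
ingredient-dictionary resolution is attempted.  The three filters
commute (verified property), so their order is irrelevant.

Event terms are mapped to ICD-10 by a static two-column table; chapters
A, B and R (infectious diseases and symptoms/signs) are flagged as
excluded from target-disease selection.  The target event is the mapped,
non-excluded event with the most inversely-flagged drugs, with related
terms optionally grouped under one label via a synonym list; ties break
alphabetically.  Contingency marginals are computed on the full filtered
pair set, before the event-exclusion step — the alternative (after
exclusion) changes `c` and `d` slightly; the pre-exclusion choice keeps
the marginals independent of the mapping table.

## Disease signature

Each study is normalised (log2(x+1) when values look linear-scale —
maximum above 50 — then per-sample median centring), probes are
collapsed to genes by maximum interquartile range (ties to the
lexicographically smallest probe id), and a two-sample **moderated t**
is computed per gene: the posterior variance is
`s̃²_g = (d₀·s₀² + d_g·s²_g)/(d₀ + d_g)` with `(d₀, s₀²)` estimated by
moment matching under a scaled inverse-chi-square prior for the gene
variances (from the mean and squared coefficient of variation of the
`s²_g`; when the observed dispersion does not exceed the chi-square
sampling floor, `d₀ = ∞`, i.e. complete shrinkage).  Setting `d₀ = 0`
recovers the ordinary pooled-variance t exactly — a tested identity.
The effect size is Hedges' g (bias-corrected standardized mean
difference); the log2 fold change is tracked separately because the DEG
thresholds are fold-change-based.

Studies are combined by **fixed-effect inverse-variance weighting**
(`w = 1/se²`); the combined p is taken from the combined z by default,
with Fisher's product method also reported — the phrase "combine p
values and effect sizes" is ambiguous between the two, so both are
computed and the inverse-variance p (which is consistent with the
combined effect) drives the thresholds.  Benjamini–Hochberg adjustment
is applied once, across all genes of the meta-analysis.

DEG thresholds are deliberately **asymmetric**: adjusted p < 0.001 with
log2FC > 1.5 (up) and < −2.0 (down), exactly as used in the psoriasis
analysis this pipeline operationalises; a stricter "core" signature at
|log2FC| > 2.5 is emitted alongside.  Both cuts are configurable.
Dataset inclusion is configuration — no quality-control scoring of
studies is performed here.

## Reversal scoring

Each compound profile is a strict rank permutation of the gene universe
(rank 1 = most up-regulated by the compound; numeric input values are
converted with ties broken by average rank then gene id).  For a gene
set with sorted positions `V(1) < … < V(s)` in a list of length `N`,
the KS-type enrichment score is `a = max_j (j/s − V(j)/N)`,
`b = max_j (V(j)/N − (j−1)/s)`, `es = a` if `a ≥ b` else `−b`.  The
reverse score is `RGES = es_up − es_down` when the two enrichments have
opposite signs and 0 otherwise — a profile that shifts both sets the
same way is not a reversal.  RGES ∈ [−2, 2], negative for reversing
profiles.

Profiles are summarised per compound against the **10 µM / 24 h
reference condition**.  The original method says only that scores were
"weighted"; the scheme here is chosen for determinism and testability:
conditions are split into dose (<10 vs ≥10 µM) and time (<24 vs ≥24 h)
classes; for each non-reference class a global offset is estimated as
the mean within-compound RGES difference from the reference class;
profile scores are offset-corrected and averaged with weight 1
(reference class) or `w0 = 0.5` (otherwise, configurable).  A
simulation-recovery test shows the corrected summary lands on the
reference-condition mean within ±0.05 across 200 compounds.  Profiles
from different cell lines are pooled; per-profile scores are emitted for
inspection, so a single-cell-line analysis is a one-line subset.

## Integration

Spearman correlations use average ranks with the t approximation on
n−2 degrees of freedom.  Sign conventions: lower sRGES = stronger
reversal, lower ROR_UCI / IC975 / EBGM95 = stronger inverse signal, so
a working pipeline yields *positive* correlations.

**Reversal genes** are called by leave-one-compound-out
cross-validation on one representative profile per compound (the
reference condition when present, else the nearest by
(|log10 dose − 1|, |time − 24|)).  In each trial the left-out compound
is removed; per gene, the Spearman correlation of its rank with the
compounds' activity (the ROR upper bound by default) is tested
two-sided, BH-adjusted across genes within the trial, and a gene is
selected only if it passes FDR < 0.25 in **every** trial.  The per-gene
statistic is not specified in the source methodology; rank correlation
is chosen to match the rank-based logic of the rest of the pipeline,
and the all-trials intersection is the strict reading of "in all
trials" (a fraction-of-trials relaxation is available).  The
intersection is conservative: under permuted activities the expected
number of selections is near zero (tested over 20 seeded permutations).

**IC50 validation** joins compounds to assay rows by the first 14
characters of the InChIKey (the connectivity block; the full key is
configurable), summarises multiple assays per compound as median,
minimum and maximum (in nM), and correlates sRGES with each summary.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised and tested; its defaults are fixed once and are not tuning
knobs.

* **Reports** are multinomial over (drug, event) cells with cell
  probabilities proportional to the product of the marginals times the
  planted reporting ratio λ (λ < 1 plants an inverse association), so
  planted expectations are analytically computable.  Duplicate case
  versions differ only in version id and event date (exercising the
  dedup rule); a configurable fraction of drug rows carry combination
  names, and extra non-suspect rows exercise the role filter.
* **Expression**: gene baselines N(7, 1) in log2 units, study shifts
  N(0, 0.5), unit residual variance, and a planted case–control
  difference of ±3 log2 units on the signature genes — large enough
  that the 12-up/8-down planted signature is recovered essentially
  always by six 20+20-sample studies at the default thresholds, so
  end-to-end tests are not confounded by marginal DEG calls.
* **Drug signatures**: for activity `t ∈ [0,1]`, signature genes are
  placed from the appropriate end of the rank list by
  truncated-geometric draws without replacement whose mean displacement
  is `(1−t)·N/2` — linear in the activity, giving uniform ranks at
  `t = 0` and exactly extreme ranks at `t = 1`, with mean RGES strictly
  decreasing along the activity grid (tested).  Non-reference
  conditions attenuate the effective activity by 0.6, giving the
  summarisation step real offsets to estimate.
* **IC50**: `log10 IC50(nM) = 3 − 2·t + N(0, 0.3)`, with 1–3 assay rows
  per compound; identifiers are format-valid 27-character
  InChIKey-shaped strings so the join logic is exercised.
* One latent activity per compound drives the planted reporting ratio
  (`λ = e^{−2.5 t}`), the signature reversal, and the IC50, which is
  precisely the dependence structure the integration stage is supposed
  to detect.

What the generator does **not** emulate: correlated gene–gene
expression, platform/batch structure beyond a study-level shift,
MedDRA hierarchy, realistic signature values (ranks suffice), or
pharmacokinetics.  Passing tests therefore demonstrate correctness of
the statistical machinery and the end-to-end plumbing, not performance
on real heterogeneous data.

## Problem sizes and numerical choices

The end-to-end checks run at a deliberately scaled-down study size —
100 compounds, a 978-gene universe with 20 planted signature genes, six
20+20-sample studies, 100,000 reports over 30 events (the demo uses 60
compounds, 300 genes, 60,000 reports) — chosen so the full pipeline
completes in well under a minute while leaving all statistical checks
decisively powered.  Headline numbers from full-scale extractions of
the public databases (tens of millions of reports, hundreds of
thousands of profiles) are not reproducible at this scale and are not
asserted anywhere.

Other numerical choices: per-stage seeds derive from the master seed by
a fixed affine formula, so stages can be rerun in isolation; the MGPS
optimiser is bounded to |log parameter| ≤ 12; posterior quantiles use
`uniroot` at tolerance 1e-10 bracketed by the component quantiles;
Fisher's method floors p-values at 1e-300 before taking logs; ties are
broken deterministically everywhere (documented per function), so a
rerun with the same seed is byte-identical — the manifest checksums the
outputs to make this checkable.

## Known limitations

* The lexical combination-drug rule cannot recognise single-name
  multi-ingredient brands without the curated list.
* The moment-matching variance prior is coarser than profile-likelihood
  estimation; it is exact in the two tested limits (no moderation,
  complete shrinkage) and adequate between them.
* The EBGM prior fit assumes enough cells (warns below 100) and no
  stratification.
* The all-trials LOOCV intersection is conservative; with few compounds
  it can under-select.
* Inverse signals are confounded by prescription channeling and
  under-reporting; nothing here is causal evidence of efficacy.
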