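---
title: "Methods: the lipidelta differential MRM workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lipidelta differential MRM workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidelta)
```

## The measurement model

Targeted shotgun lipidomics records, per flow injection, counts per second
for a fixed panel of MRM transitions: one per lipid species plus one
deuterated internal standard per lipid class. Absolute counts are not
comparable across injections (spray stability, extraction efficiency), so
the interpretable quantity is the within-injection ratio of a species to
its class standard. `lipidelta` takes that measurement model literally:

1. `normalize_to_standard()` forms `cps(species) / cps(class standard)` per
   injection. The ratio is invariant to any common rescaling of an
   injection, which is the property that motivates internal standards.
2. `average_duplicates()` collapses an animal's technical injections by
   the arithmetic mean, giving one value per animal × species. All
   statistics run on these per-animal values, so the biological animal is
   the experimental unit and technical replication only reduces
   measurement noise.
3. `class_fraction_normalize()` optionally re-expresses each species as a
   fraction of its class total *within the same animal*. Fractions sum to
   exactly 1 per animal × class, so a change of the class total cannot
   masquerade as a change of an individual species.

A design point worth making explicit: the "/tot" quantities are computed
per animal rather than by dividing group-level summaries. Per-animal
fractions are the only construction that yields per-species SEMs and
two-sample *t*-tests on the fraction scale, which the downstream reporting
requires; a group-level alternative would leave nothing to test. For that
reason no switch to a group-level variant is offered.

## Statistics

**Species level.** For each species, `species_stats()` reports the fold
change `fc = mean(treated) / mean(control)` of per-animal values and a
two-tailed two-sample Student *t*-test. The equal-variance Student form is
the default because that is the convention of this assay's reporting;
Welch is available (`var_equal = FALSE`). The *t* statistic and p-value
are computed in closed form, vectorized across species — the test suite
pins them against `stats::t.test()` to 1e-10 — because simulation studies
routinely push the species count to 10^4, where per-species `t.test()`
calls dominate runtime.

**Effect-size error.** `sem_fc` is the standard error of the treated
per-animal values scaled by the control mean. This puts `sem_fc` on the
same dimensionless axis as `|fc − 1|`, making the two directly
commensurable, and mirrors the convention of error bars drawn on
percent-of-control plots. An alternative reading (full delta-method SEM
of the ratio of means, using both groups' variances) is available as
`sem_method = "pooled"`. The effect filter itself is
`|fc − 1| > mean(sem_fc)`, the mean taken over all species of one tissue
at one scale (`effect_threshold()`). The literature this workflow follows
states the filter as "fold change greater than the average SEM" without
fixing either the SEM estimand or whether the fold change enters as
`fc` or `|fc − 1|`; the implemented reading treats a fold change of 1 as
"no effect", which is the only choice under which a null species can never
pass the filter.

**Volcano tiers.** `volcano_categorize()` partitions species into
`SIGNIFICANT_EFFECT` (p < α and effect), `SIGNIFICANT_ONLY`,
`EFFECT_ONLY`, and `UNCHANGED`. The four tiers are exhaustive and mutually
exclusive by construction.

**Multiplicity.** `bh_fdr()` applies Benjamini–Hochberg step-up via
`stats::p.adjust()`, one family per tissue × scale: raw-ratio and
class-fraction analyses answer different questions and are adjusted
separately.

**Direction counts.** Within a tier, increased means `fc > 1` and
decreased `fc < 1`; a species at exactly 1 has no direction and is counted
in neither column (a null species should not bias the split). The
within-tissue test is the two-sided exact binomial test at null proportion
0.5. For comparing the up/down split between two tissues the two-sample
construction of a "binomial test" is ambiguous; `direction_contrast()`
uses Fisher's exact test on the 2 × 2 tissue × direction table, the
standard exact test for that contingency question.

**Class level.** `class_summary()` sums species per animal and class and
reports the treated mean as percent of the control mean with a two-tailed
one-sample *t*-test of the control-scaled treated totals against 100%.
The carnitine class additionally reports three subgroups — free carnitine
(C0), acetylcarnitine (C2), and acyl chains of three or more carbons
(propionyl and longer) — while the "/tot" denominator remains the full
carnitine panel.

**Degenerate inputs.** When a group has zero variance the *t* machinery
has no sampling variability to work with; the package then reports p = 1
for identical means and p = 0 otherwise (both for the two-sample and the
one-sample tests). Zero control means, zero class totals and zero standard
signals are hard errors naming the offending species, animal or
injection, never silent NaNs.

## Nomenclature

`parse_species()` accepts the shorthand dialect in which these panels are
printed: `PC aa C36:4`, `PC ae C40:0`, `lyso-PC C22:6`, `SM C24:0`,
`TAG 48:0` (no `C` prefix), carnitines `C0`/`C2`/`C10`/`C3 OH` (leading
zeros tolerated, e.g. `C03 OH`), and `Cholesterol total`/`free` as two
standalone analytes outside acyl nomenclature. Parsing enforces
`double_bonds ≤ carbons`, and parse→format is the identity on canonical
labels. `expand_range()` expands figure-legend range notation: double-bond
ranges step by 1, carbon ranges by 2 (total acyl carbons of di-/tri-acyl
lipids are enumerated in even steps); both conventions are overridable.

The default panel (`build_default_panel()`) carries the measured class
sizes — 43 PC aa, 39 PC ae, 22 lyso-PC, 15 SM, 17 TAG, 41 carnitines,
2 cholesterol analytes. The PC ae roster is fully determined by its
chain-length ranges; for PC aa the ranges enumerate 40 species and three
individually reported species (C26:0, C28:0, C28:1) complete the 43. The
lyso-PC, SM, TAG and carnitine rosters are *synthetic* stand-ins of the
declared sizes that include every individually reported species; real
studies should supply their roster via `build_default_panel(rosters = ...)`
or a panel TSV (`read_panel()`). Replacement rosters must keep the
declared class size, which guards against silently analysing a truncated
panel.

## The synthetic data generator

`generate_dataset()` emulates the study design this workflow was built
for: 2 groups × 6 animals × 2 technical injections, every injection
measuring the full panel plus standards. The signal model is
multiplicative-lognormal throughout:

```
cps(injection, species) = baseline(species)           # lognormal across species
                        × bio(animal, species)        # lognormal, CV = noise_cv
                        × fc(species)^[treated]       # ground-truth effect
                        × tech(injection, species)    # lognormal, CV = tech_cv
cps(injection, standard) = standard_intensity × tech × (1 + matrix_drift)^[treated]
```

Lognormal factors have mean 1, so group ratios are centred on the true
fold change; intensities are positive by construction, and CVs are the
natural noise scale for MS intensities. Matrix drift is applied to
standards only and only in the treated group, giving `matrix_effect_qc()`
a known truth to recover (3% injected drift is reported as exactly 3.00%
when `tech_cv = 0`).

Defaults, chosen once as realistic study conditions and stated here as
assumptions: `n_per_group = 6`, `n_tech_reps = 2` (the emulated design),
`noise_cv = 0.10` and `tech_cv = 0.04` (a biological CV around 10% with
technical replication several-fold tighter is typical for
standard-normalized MRM ratios), `baseline_log_mean = log(2000)` cps with
`baseline_log_sd = 1` (signals spanning roughly two decades around the
standard's order of magnitude), `standard_intensity = 5000` cps, and
`matrix_drift = 0.013` (an average standard-ratio shift of about 1.3%,
the magnitude such QC checks typically report).

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: chromatography-free spectra artifacts
(isotope overlap, in-source fragmentation), heteroscedastic or
intensity-dependent noise, missingness/limit-of-detection censoring,
batch structure beyond the group-linked matrix drift, and any correlation
between species beyond the shared standard. In particular, with
`tech_cv > 0` all species of a class share their standard's technical
noise, which induces a weak positive correlation across species within an
injection; the null-calibration simulation below therefore switches
technical noise off where independence across species is the point of the
check.

## Problem sizes and numerical choices in the test suite

The suite's simulation scales were chosen to make sampling error
negligible relative to each tolerance: class-fraction conservation is
checked to 1e-12 over 100 random datasets; *t*-test agreement against
`stats::t.test()` to 1e-10 over 1,000 random fixtures; the exact binomial
test against brute-force pmf summation for every `(k, n)` with `n ≤ 25`;
the null type-I rate at α = 0.05 on one 10,000-species panel (6 + 6
animals, `noise_cv = 0.10`, `tech_cv = 0`, fixed seed), required to lie
within 3 binomial standard deviations of 0.05; and spiked-recovery over
200 replicates of a 30-species panel with one species at fold change 1.5,
where the median estimate must land within 5% of truth and the
`SIGNIFICANT_EFFECT` rate within 5 percentage points of the analytic
power of the pooled *t*-test under the generator's noise model
(≈ 0.9996 at these settings, computed from the lognormal moments in the
test helper).

Two floating-point details are deliberate: percent-of-control is computed
as `100 * (mean(treated) / mean(control))` — the parenthesisation keeps an
exactly-null comparison at exactly 100 — and report files serialize
numbers via `%.15g`, which makes repeated runs byte-identical while
round-tripping doubles to ~1 ulp.

## Limitations

- Shotgun MRM cannot resolve sn-positions or isomers; species identity is
  the total-carbon : double-bond shorthand, nothing finer.
- The workflow tests one species or class at a time; it provides no
  enrichment analysis over lipid sets, for which dedicated packages
  exist, and no mixed models or covariate adjustment.
- The dual p/SEM filter is a reporting convention, not an inferential
  procedure with controlled error rates; the BH q-values are provided
  precisely so that readers can apply a calibrated criterion instead.
- Cholesterol enters as two pre-summarized analytes; no acyl profile or
  esterification modelling is attempted.
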