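---
title: "Lipidomics biomarker discovery: models, assumptions and design choices"
author: "lipidScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipidomics biomarker discovery: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidScreen)
```

## The analysis problem

Untargeted plasma lipidomics of a three-group clinical cohort — healthy
controls, a first-time disease group (UF) and a recurrence group (RUF) —
asks two questions: which lipid species differ between groups, and how
well does a small panel of them discriminate patients from controls.
`lipidScreen` implements the complete chain: theoretical-mass
annotation, rank-based screening, OPLS-DA marker ranking, logistic
diagnostic models with cross-validated performance, and lipid-class
enrichment, plus a synthetic cohort generator whose planted truth
validates every stage.

## Theoretical lipid database

Species are enumerated at the *sum-composition* level: class, total
acyl/alkyl carbons C and total double bonds D (e.g. PC 34:1). Each
class has a linear composition rule in (C, D); for example diacyl PC is
C~C+8~H~2C−2D+16~NO~8~P, so PC 34:1 is C~42~H~82~NO~8~P with
monoisotopic mass 759.5778 Da. The rules for all 12 classes were
verified species-by-species against an independent elemental-mass
calculator; a 20-species golden panel frozen from that calculator backs
the test suite. Sphingolipid d-notation (SM d18:1/22:0) and
chain-annotated glycerolipid names (TG 18:0_18:1_18:1) are parsed by
summing chains into totals.

Enumeration ranges are a declared convention, not a measured fact:
even-carbon totals only; two-chain classes C 24–48, D 0–12; TG C
30–70, D 0–15; LPC/FA C 12–26 and CE C 12–24 (single chain, D 0–6).
These cover every species the analysis chain or the default design
names. Adducts are the standard singly charged ESI set under an
ammonium-formate mobile phase — positive: [M+H]\^+^ and [M+Na]\^+^
(TG/CE instead [M+NH4]\^+^ and [M+Na]\^+^); negative: [M−H]\^−^ for
acidic classes and [M+HCOO]\^−^ for choline-containing classes. Adduct
deltas include the electron mass.

Annotation matches observed peaks within a 10 ppm window (inclusive
edges), ranks candidates by |ppm|, optionally confirms with
class-diagnostic MS/MS fragments (phosphocholine 184.0733 for
PC/LPC/SM/PC-O; neutral losses 141.0191 for PE/PE-O and 87.0320 for
PS; 369.3516 for CE; water loss for Cer; any fatty-acid + NH~3~ loss
for ammoniated TG; tolerance 0.01 Da — a Da rather than ppm tolerance
because the diagnostic fragments sit at low mass), and resolves
ambiguity deterministically: confirmed beats unconfirmed, then
smallest |ppm|, then lexicographic name.

## Preprocessing

The fixed order is: half-minimum imputation (zeros/missing replaced by
half the feature's minimum positive value; dead features dropped), QC
relative-standard-deviation filter (features with RSD > 0.30 across ≥ 3
pooled-QC injections dropped; with fewer QC samples the filter is
skipped with a warning), then total-ion-current normalization of every
sample to the median original total. Downstream stages use different
scales on purpose: the Mann–Whitney screen runs on normalized raw
intensities (rank-based, so any monotone transform is irrelevant),
OPLS-DA on log~10~ intensities with unit-variance scaling (the
chemometrics convention), and the logistic models on raw-scale
intensities — coefficients of order 10^−5^–10^−6^ against intensities
of order 10^5^ are the natural pairing for diagnostic formulas quoted
on the raw scale.

## Univariate screening

The Mann–Whitney statistic is U = #\{x~i~ > y~j~\} + ½#ties. For
tie-free groups with at most 8 observations each, the two-sided p is
exact: the null distribution of U is built by the standard counting
recursion c(n, m, u) = c(n−1, m, u−m) + c(n, m−1, u) and the p-value
sums all labelings at least as extreme as observed. Otherwise a normal
approximation with tie correction and continuity correction is used,
refined by an Edgeworth fourth-cumulant term (the exact null of U is
platykurtic, with γ~2~ = −(6/5)(n² + m² + nm + n + m)/(nm(N+1)) for
tie-free data); the refinement keeps the approximation within |Δp| <
0.01 of the exact branch even at n = m = 8, where the plain corrected
normal misses by ~0.011. Selection uses raw p < 0.05 with no
multiplicity adjustment — faithful to common screening practice in this
field — while a Benjamini–Hochberg column is reported for reference.
"Two-sided" is our reading of the ambiguous phrase "two-way" sometimes
used for this test.

## OPLS-DA

For a two-class response coded 0/1 and centered, with X centered and
unit-variance scaled (pareto and no scaling available; zero-variance
features are dropped first):

* the predictive weight is w ∝ X^T^y (unit norm); y-orthogonal
  components are extracted by w~o~ ∝ p − (w^T^p)w from the loading
  p = X^T^t/(t^T^t), with X deflated by t~o~p~o~^T^ per component.
  Because w ∝ X^T^y, every orthogonal score satisfies t~o~^T^y = 0
  exactly — asserted numerically to 10^−8^ in the tests;
* the final predictive component on the filtered X gives R²X (fraction
  of scaled-X variance captured by all modeled components), R²Y, and
  ŷ = tq;
* the component sign is fixed so the class coded 1 has positive mean
  score, making score plots comparable across runs;
* VIP is computed over the predictive component only, which preserves
  the identity ΣVIP² = number of modeled features and keeps the
  discriminant interpretation; markers are features with VIP strictly
  greater than 1;
* Q²Y = 1 − PRESS/SS(y) by stratified 7-fold cross-validation with
  scaling and the full component system re-estimated inside every
  training split. The default of 7 folds is our resolution of the
  contradictory phrase "sevenfold leave-one-out cross-validation";
  `folds = n` expresses true LOO. One orthogonal component is the
  default (configurable).

Permutation validation refits the model on label-permuted responses
and reports the empirical p of the observed Q²Y. A caveat worth
stating plainly: the permutation null of Q² is *negative* by
construction — a model fitted to permuted labels predicts held-out
labels worse than the mean — and at this cohort's size (n = 50 for the
control-vs-UF comparison) its mean is around −0.2 to −0.3. We verified
this is not an artifact of our implementation: scikit-learn's
PLSRegression and mixOmics' `perf()` give the same null mean on
matched designs. The null only approaches zero for much larger cohorts
(|mean| < 0.1 from roughly n ≥ 100 at small panel sizes). What matters
for validation is the *rank* of the observed Q² against the null, not
the null's center.

## Logistic diagnostic models

The diagnostic model is y = 1/(1 + e^−(β₀ + β·I)^) over the raw
intensities I of the VIP panel, fitted by iteratively reweighted least
squares. For numerical conditioning the predictors are standardized
internally and a tiny ridge (λ = 10^−8^) is applied to the
standardized slopes — a deliberate, documented deviation from plain
maximum likelihood that keeps estimates finite under the
quasi-separation VIP pre-selection often induces; coefficients, Wald
z/p and 95% CIs are mapped back to the raw scale. Complete separation
is detected and flagged, not treated as an error. Performance is
leave-one-out cross-validated sensitivity and specificity at a 0.5
probability threshold (configurable); a training fold reduced to one
class excludes that sample with a warning. On well-conditioned data
the fit matches `glm(family = binomial)` to 4 decimals (tested), and
parameters simulated at n = 2000 are recovered within 3 standard
errors.

## Enrichment

Over-representation uses the exact hypergeometric upper tail
P(X ≥ k) with BH adjustment across pathways. The bundled pathway map
is a compact stand-in for a curated pathway library:
glycerophospholipid {PC, LPC, PE, PS, PA}, sphingolipid {SM, Cer},
ether lipid {PC-O, PE-O}, glycerolipid {TG}, and linoleic acid
metabolism — membership in the last requires an explicitly stated 18:2
chain, because sum-composition names cannot be resolved to chains.
The background is the set of annotated lipids actually analyzed, not
the full theoretical database (standard ORA practice).

## The synthetic cohort generator

The generator emulates the study conditions end-to-end: 15 control /
35 UF / 31 RUF samples; 267 plasma features acquired positive-mode
over m/z 400–1000 (each feature tied to a distinct theoretical ion,
observed m/z perturbed by 2 ppm Gaussian noise); log-normal
intensities, intensity(f, s) = 10^μ~f~ + log₁₀(2)·FC(f, g) + ε^ with
μ~f~ ~ N(5, 0.5) — base intensities of order 10^5^, consistent with
the raw-scale logistic coefficients above — and ε reproducing a
within-group biological CV of 0.3 (σ~ln~ = √log(1 + CV²)); pooled QC
injections drawn around the size-weighted pooled mean with an
*analytical* CV of 0.1 only, since replicate injections of one pooled
sample carry no biological variance (a typical instrument-level RSD;
using the biological CV here would make the 0.30 RSD filter discard
stable features at random, which is physically wrong).

The default design plants 25 markers: 8 "disease" markers perturbed in
both UF and RUF (the control-vs-UF panel) and 17 "recurrence" markers
perturbed in RUF only, so the control-vs-RUF comparison inherits the
largest differential set — matching the qualitative ordering of the
three comparisons. Effect magnitudes |log₂FC| are drawn uniformly from
[0.6, 1.5] with random sign; true effect sizes in real cohorts are
unknown (only significance is usually reported), so these are a stated
convention: 0.6 is near the detection limit at n = 15 vs 35 and CV
0.3 (≈ 1.4σ on the log scale), 1.5 is a comfortably strong effect.
Marker identities are drawn from species names recurrent in the plasma
lipidomics literature for this disease area, so reports read
naturally; the marker feature positions are sampled reproducibly from
the seed. All randomness flows from a single seed per run through a
save/restore RNG wrapper, so the generator never disturbs the caller's
RNG state.

What the generator does *not* emulate — and therefore what passing
tests do not show about real data: chromatographic drift and batch
effects, isotopologues and co-elution, missingness that is
intensity-dependent rather than random, heavy-tailed or skewed
deviations from log-normality, and correlation structure between
lipids of the same class. Recovery rates and LOOCV performance on the
synthetic design are upper bounds on what identical settings would
achieve on real cohorts.

## Numerical choices and degenerate inputs

* ppm windows are inclusive at both edges; candidate ties break by
  smaller |ppm|, then name.
* The exact U-test branch activates for max(n, m) ≤ 8 without ties.
* IRLS: at most 100 iterations, relative deviance tolerance 10^−10^,
  weights floored at 10^−10^; separation flagged when training data
  are perfectly classified with |η| > 15.
* OPLS stops adding orthogonal components early if no orthogonal
  variation remains (‖w~o~‖ < 10^−12^).
* Zero-total samples make TIC normalization fail loudly; all-zero
  features are dropped by imputation rather than propagated.
* The pipeline skips the multivariate stages of a comparison with
  fewer than 3 significant features and records the counts.

## Problem sizes used in validation

The test suite and the acceptance script run at the study's own scale:
267 features × 89 samples (81 cohort + 8 QC) for pipeline runs, 2 000
null features for the type-I error check, 1 000 planted peaks for
annotation recovery, 100 label permutations for the Q² null, and
exhaustive enumeration up to N = 25 for the hypergeometric test. A
full pipeline run takes a few seconds on one CPU; the complete test
suite under a minute.

## Known limitations

Sum-composition annotation cannot resolve isomeric chain splits or
sn-positions; MS/MS rules are class-level, not species-level; the
enrichment map is deliberately small and class-based rather than a
licensed pathway database; only two-class OPLS-DA is provided (the
three-group design is analyzed as three pairwise models, as is common);
and the logistic panel is taken as given by the VIP cut rather than
re-selected by model-based criteria.
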