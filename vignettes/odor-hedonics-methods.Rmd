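---
title: "Methods: estimating odor pleasantness from profiles and molecular features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating odor pleasantness from profiles and molecular features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorhedonics)
```

## The model

Odor pleasantness (hedonic valence) is treated as a one-dimensional
quantity on a symmetric −4…+4 scale, where −4 is "very unpleasant" and +4
"very pleasant". The package implements three ways of placing an odorant
on that scale and the machinery to relate them:

1. **Semantic coding.** Verbal panel labels map onto the seven-point scale
   −4, −2.67, −1.33, 0, 1.33, 2.67, 4. The intermediate steps are the
   thirds of the scale (±4/3, ±8/3) at the conventional two-decimal
   printing; we store the printed values, not the unrounded fractions, so
   coded data rounds identically across implementations.

2. **Tone-weighted profile averaging.** If descriptor *j* has hedonic tone
   $HT_j$ and odorant *i* has applicability $x_{ij} \ge 0$ for it, then
   $$H_i = \frac{\sum_j HT_j\, x_{ij}}{\sum_j x_{ij}}.$$
   $H_i$ is a convex combination of the tones of the descriptors actually
   applied: bounded by their min and max, invariant to rescaling a profile
   row and to column order. The key assumption is that descriptor
   applicability is a meaningful non-negative weight; the method does not
   require the applicabilities to be calibrated beyond that. Rows with
   zero total weight are *odorless*: the score is undefined and propagates
   as an explicit missing value excluded from every downstream fit.

3. **PC1 scores.** When the first principal component of an autoscaled
   profile matrix has loadings that track the descriptor tones, its scores
   order odorants by pleasantness. PC1-score scales are typically
   asymmetric (the unpleasant range stretches further than the pleasant
   one), so weighted-average scores are the default regression response
   and PC1 scores serve as corroboration.

Hedonic scores are then regressed on elementary molecular features: the
heavy-atom count $N_{at}$ (all atoms except hydrogen, a molecular-size
proxy) and presence indicators for oxygen, sulfur, carboxyl and amine
groups, with optional $N_{at}^2$ and $I_{ox} \cdot N_{at}$ terms. Five
published equations of this family ship as immutable presets
(`preset_equations()`); their closed-form analytics — the pleasantness
threshold where a prediction crosses zero and the vertex where a quadratic
model peaks — are exposed as `null_crossing()` and `optimum_nat()`.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| profile noise threshold | 4 | % of scale max | applicabilities under 4% are panel noise; *strictly* below is zeroed, a value exactly at 4 is kept |
| transform rule | skewness > 1.5 → log(x+1); (0, 1.5] → sqrt; else none | — | profile variables are positively skewed; explicit per-column overrides always win |
| log offset | 1 | applicability units | keeps log defined at zero applicability |
| Q² folds | 7 | — | element-wise deletion groups; every cell is held out exactly once |
| Q² threshold (PC1) | 0.13 | — | conventional small-matrix retention value; configuration, not a derived quantity |
| Pearson test | two-sided, t transform, n−2 df | — | loading–tone significance |
| influential point | Cook's D > 1 or leverage > 3p/n | — | reported always, excluded only on explicit opt-in |
| pleasant class | score > 0 | — | zero is *not* pleasant (strict inequality) |

## Numerical and design choices

**PC sign convention.** Eigenvector signs are arbitrary. PC1 is oriented
so its loading–tone correlation is non-negative (larger scores = more
pleasant); without tones, the largest-magnitude loading is made positive.
Flipping the input data leaves the oriented output unchanged.

**Q² scheme.** Cross-validated goodness of fit is computed by element-wise
deletion: cells are randomly assigned (seeded) to folds, held-out cells
are predicted by a rank-k model re-estimated from the remaining cells via
iterative SVD imputation (missing cells initialized at the column mean,
refined to 1e−8), and $Q^2_k = 1 - \mathrm{PRESS}_k / SS_{k-1}$ with
$SS_{k-1}$ the full-data residual sum of squares after k−1 components.
Row-wise deletion was the plausible alternative; element-wise was chosen
because it predicts individual cells rather than whole odorants and
degrades monotonically with added noise, which the tests verify. The 0.13
threshold is configuration with a conventional default, not a value the
package derives.

**Loading–tone fit.** The quadratic loadings-on-tones model is fitted
*through the origin*, so a descriptor with zero tone has zero fitted
loading and the loading sign classifies descriptors as pleasant or
unpleasant. R² is computed about zero (not the mean), and
|studentized residual| > 2 flags outliers.

**Functional-group definitions.** A carboxyl is a carbon bearing both a
double-bonded oxygen and a hydroxyl oxygen (an oxygen with no second heavy
neighbour) — esters and anhydrides do not match; carboxylate anions are
out of scope since odorants are neutral volatiles. An amine nitrogen has
only single bonds, only carbon/hydrogen neighbours, and no neighbouring
carbonyl carbon: amides, nitriles, nitro groups, azides and aza-aromatic
nitrogens are excluded, while aryl amines (aniline-like) are *included* —
the fishy-urinous odor family is not limited to aliphatic amines, though
whether historical "amine" tallies included them is not recorded.
Structure perception (including kekulization of aromatic SMILES) is
delegated to Open Babel via ChemmineR; features depend only on atom counts
and neighbour patterns, so aromaticity-perception differences cannot
change them.

**Tri-state indicators.** Acid/amine flags are structural, not
compositional: a formula-only molecule without explicit flags gets `NA`
("undetermined"), and any fit or prediction whose term list needs those
indicators refuses to proceed rather than silently assuming absence.

**Alias merging.** When a profile descriptor is renamed onto a descriptor
that already has a column, the two merge by element-wise maximum — not
sum — so applicability stays on the 0–100 scale.

**Printed-coefficient discrepancies.** The preset analytics use the
printed coefficients exactly. Two published threshold values differ
slightly from what those coefficients give: 7.5 vs 7.554 (eq11) and 5.9
vs 6.036 (eq12), implying unrounded internal coefficients in the source
fits. The package documents the ≈0.1 gaps rather than guessing hidden
precision; the four-equation average (5.94) still rounds to the printed
5.9, and the optima round to the printed "about 14" and "about 19".

**eq8 and the ranking scale.** The preference-ranking-scale preset is
retained for round-trip checks against its hedonic-scale twin through the
H = 7.11 − 0.091·PR calibration (agreement to ~2 decimals, limited by the
printed rounding); predictions default to the hedonic scale. The eq10
preset carries a "not recommended for prediction" advisory — it was fitted
on a set with no hedonically neutral odorants and its oxygen coefficient
is inflated.

## The synthetic-data generator

The literature datasets behind the published fits (panel studies and odor
atlases) are not redistributable, so the generator plants known truth with
their *statistical* shape:

- **Molecules**: heavy-atom counts uniform on 2…22 by default, matching
  the published composition tables' ranges; oxygen in 73% of molecules
  (the cross-set average), small sulfur/acid/amine/chlorine rates. Each
  molecule is emitted as a linear-chain SMILES with the drawn groups as
  terminal/branch fragments plus a consistent Hill formula; a configurable
  fraction is emitted formula-only with explicit flags, exercising the
  tri-state path. An optional weight vector over the size range lets a set
  emulate a *concentrated* size distribution: the perfumery-biased set
  uses binomial weights with mean 13 over 3…22 and 93% oxygen, because a
  perfumer's inventory clusters around mid-sized oxygenated molecules
  rather than spreading uniformly — a uniform draw would misrepresent
  exactly the property (few small molecules) that makes such sets
  predictedly pleasant.
- **Truth scores**: preset prediction plus Gaussian noise (sd 0.5 by
  default), clipped to [−4, 4] with clip events flagged.
- **Profiles**: descriptor tones uniform on [−4, 4]; applicability weight
  proportional to a Gaussian kernel $\exp(-(HT_j - H_i)^2 / 2\tau^2)$
  with $\tau = 0.8$ tone units — wide enough that several descriptors
  light up per odorant (realistic spread), narrow enough that the
  weighted average recovers the planted score — times a Bernoulli keep
  mask (0.5) and truncated-Gaussian noise (sd 2), row-scaled into the
  0–100 range. At $\tau = 0$ all weight collapses onto the nearest-tone
  descriptor.

What passing tests on this generator **do** show: the estimator, PCA
decision and regression recover planted structure at realistic noise; the
pipeline's plumbing (thresholding, aliasing, joins, exclusions) does not
distort n or leak information. What they **do not** show: real panel
psychophysics — descriptor correlations driven by odor *quality* rather
than valence, usage-frequency artifacts, concentration dependence, or
cultural variation in hedonic judgments. Conclusions about real datasets
require real data.

Problem sizes used throughout the tests and analysis scripts — 300
molecules, 40 descriptors, 7 Q² folds, 2 PCA components — are the
package's chosen study conditions: large enough for 3-SE coefficient
recovery and stable correlations, small enough to iterate comfortably.

## Known limitations

- The full 146-descriptor hedonic-tone vocabulary is not public; the
  shipped fixture carries only the eight printed tones, and users must
  supply their own vocabulary files for full-atlas work.
- SMILES support covers neutral organic odorants; charged species,
  isotopes and polymers are out of scope.
- Q² values depend on the deletion pattern (hence on the seed) and on the
  imputation scheme; they are decision aids, not portable statistics.
- The regression family is deliberately minimal (atom counts and four
  indicators); it explains roughly half the variance in hedonic scores at
  best and misclassifies well-known exceptions (e.g. large urinous
  steroids predicted pleasant from size alone).
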