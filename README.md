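# odorhedonics

Quantitative structure–odor relationship (QSOR) toolkit for estimating the
pleasantness — the *hedonic valence* — of odorant molecules, for
chemosensory scientists, chemometricians and fragrance/malodor researchers
who work with numerical odor-character profiles and simple molecular
descriptors.

## What it computes

Three linked analyses, each exposed as package functions and driven by the
numbered scripts under `analysis/`:

**1. Hedonic scores from odor profiles.** Given an odorant × descriptor
applicability matrix X (values 0–100) and a vocabulary of per-descriptor
hedonic tones HT on a −4…+4 scale, the hedonic score of odorant *i* is the
tone-weighted average

    H_i = Σ_j HT_j · x_ij / Σ_j x_ij

a convex combination of the tones of the descriptors applied to the
odorant. Profiles are first cleaned (applicabilities under 4% of scale are
panel noise and are zeroed; descriptors left empty are dropped and
reported) and descriptor names are resolved against the vocabulary via an
alias map. Panel hedonic *labels* ("moderately unpleasant", …) are coded on
the symmetric seven-point scale −4, −2.67, −1.33, 0, 1.33, 2.67, 4, and
mean preference rankings convert through the affine calibration
H = 7.11 − 0.091·PR.

**2. Is PC1 the hedonic dimension?** Profile matrices are transformed
towards normality (log/sqrt by a skewness rule, with per-column overrides),
autoscaled, and decomposed by PCA. A component is retained if its
eigenvalue exceeds 1 or its cross-validated Q² (element-wise deletion,
iterative SVD imputation) clears a configurable threshold; PC1 is declared
*hedonic* when its loadings correlate positively and significantly with
the descriptor tones. A no-intercept quadratic fit of loadings on tones
(`p1 = b1·HT + b2·HT²`) quantifies the relation.

**3. Hedonic scores vs molecular features.** Molecules described by SMILES
and/or molecular formula are reduced to the heavy-atom count N_at and
binary indicators I_ox, I_sul, I_acid, I_amine (carboxyl and amine groups
detected by substructure rules). OLS models of H on subsets of
{N_at, N_at², I_ox, I_sul, I_acid, I_amine, I_ox·N_at} are fitted with
residual-normality and influential-point diagnostics. Five published
prediction equations ship as immutable presets (`eq7`–`eq12`), e.g.

    eq7:  H = −2.56 + 0.23·N_at + 1.26·I_ox − 1.54·I_sul
    eq11: H = −2.33 + 0.33·N_at − 0.0104·N_at² + 0.057·I_ox·N_at − 0.83·I_sul − 1.62·I_acid

with their analytic properties: the *pleasantness threshold* (N_at at which
the prediction crosses zero for an oxygenated molecule) and, for the
quadratic models, the *hedonic optimum* (vertex in N_at).

Because the underlying literature datasets are not redistributable, a
synthetic-data generator plants known ground truth (molecule sets emulating
the published composition tables; profile matrices whose weighted-average
scores track a planted hedonic variable) so that every stage is testable
end to end.

## Worked example

```r
library(odorhedonics)

# an odorant described as 36% "fruity", 8% "sweet"
m <- odor_profile_matrix(matrix(c(36, 8), 1, 2,
       dimnames = list("benzyl acetate", c("fruity", "sweet"))))
v <- hedonic_vocabulary(c("fruity", "sweet"), c(2.23, 2.03))
estimate_hedonic_eq1(m, v)
#>               id hedonic_score method flags
#> 1 benzyl acetate      2.193636    eq1
```

2.19 on the −4…+4 scale: a clearly pleasant odorant, pulled slightly below
the "fruity" tone (2.23) by the less-pleasant "sweet" component.

```r
# predicted pleasantness of decanol-sized oxygenated molecule
predict_hedonic("eq7", data.frame(id = "x", n_at = 10, i_ox = 1,
                                  i_sul = 0, i_acid = 0, i_amine = 0))
#>   id hedonic_score     method flags
#> 1  x             1 regression

null_crossing("eq7")$threshold   # 5.652 -> oxygenated molecules need ~6
optimum_nat("eq12")$nat_opt      # 13.96 -> pleasantness peaks near N_at 14
```

Running the analysis workflow (`Rscript analysis/01_simulate.R` … `05`)
simulates a 300-molecule study, scores its profile matrix (r = 0.98
against the planted truth), confirms PC1 is the hedonic dimension
(loading–tone r = 0.81; r = 0.04 after tone shuffling), refits the planted
equation (all coefficients within 0.89 SE of truth), and tabulates the
preset-equation analytics (thresholds 5.65, 4.52, 7.55, 6.04; average
5.94; optima 13.96 and 18.61).

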