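# finestruct

Two-group discrimination of grayscale textured images by **fine
structure analysis**, built for fovea-centered retinal fundus regions
of interest but applicable to any texture whose groups differ in
spatial autocorrelation. The motivating application is screening for
*subclinical* diabetic retinopathy — retinal changes present before any
microaneurysm or hemorrhage is visible to a clinician.

## The method

Each image patch is summarised by the ordinary-least-squares fit of a
2D lag-shifted autoregressive model

```
y[i,j] = b0 + Σ_{k,l ∈ 0..2, k+l>0} b[k,l] · y[i−k, j−l] + u[i,j]
```

— 8 lag coefficients plus an intercept. Per-group coefficient matrices
`B1`, `B2` (one column per image) and their pooled stack `Bp` give
covariances `Ω1`, `Ω2`, `Ωp`, and the projection direction `v` solves
the weighted Fisher eigenproblem

```
(n1·Ωp − n2·Ω1 − n3·Ω2) v = γ1 (n2·Ω1 + n3·Ω2) v,
n1 = N1+N2−1,  n2 = N1−1,  n3 = N2−1
```

whose left side is exactly rank one, so a single eigenvalue `γ1`
carries all between-group separation. Each image's scalar projection
`z = vᵀb` is scored with the Gaussian Kullback–Leibler log-likelihood
ratio

```
L(z) = ln(s2/s1) + (z−m2)²/(2s2²) − (z−m1)²/(2s1²)
```

positive `L` ⇒ group 1, negative ⇒ group 2, |L| = confidence. The
discrimination rate is the percentage of correctly signed images,
under resubstitution (in-sample, the original protocol) or
leave-one-out (honest) evaluation. Because no clinical images are
publicly available, the package ships a seeded synthetic-cohort
generator — stationary causal AR random fields with class-specific
coefficients, plus vessel phantoms with tunable tortuosity — that makes
every stage testable end to end. See the vignette
(`vignettes/fine-structure-discrimination.Rmd`) for the full model
account.

## Worked example

```r
library(finestruct)

co <- generateCohort(cohortSpec(seed = 3, gap = 0.1))   # 16 + 17 fields
B1 <- groupCoeffMatrix(lapply(co$group1, fitImage), "control")
B2 <- groupCoeffMatrix(lapply(co$group2, fitImage), "case")

solveFld(B1, B2)
#> FldSolution (corrected weighting): gamma1 = 152.61, |l2|/|g1| = 3.72e-16
#>   v: -0.2560 -0.4673 -0.0407 -0.7986 -0.1610 0.0795 0.1615 0.0201 -0.1336

discriminateGroups(B1, B2, mode = "leave_one_out")
#> DiscriminationReport (leave_one_out): 33/33 correct = 100.00% (~100%)
#>          predicted
#> truth     control case
#>   control      16    0
#>   case          0   17
```

`gamma1 = 152.61` with `|λ2|/|γ1| ≈ 4e-16` says one direction carries
essentially all between-group signal, as the rank-one structure of the
eigenproblem predicts. The leave-one-out rate of 100 % reflects the
deliberately well-separated synthetic classes (coefficient gap 0.1 on
the two first-order lags, an order of magnitude above the estimation
noise); at gap 0 the same pipeline averages ~70 % — the resubstitution
optimism floor for 9 coefficients and 33 images — and `gap` sweeps the
power curve in between.

File cohorts run from a CSV manifest
(`path,group,center_row,center_col,radius_px`, 0-based indices):

```r
runDiscrimination("manifest.csv", outputDir = "results")
# writes coefficients.csv, fld.json, report.json, report.csv, run.log
```

or from the shell via the thin wrapper:

```sh
Rscript inst/scripts/finestruct.R synth --out cohort --seed 1
Rscript inst/scripts/finestruct.R run --manifest cohort/manifest.csv --out results
```

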