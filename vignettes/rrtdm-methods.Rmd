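---
title: "Random regression test-day models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression test-day models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model the package implements, the numerical and
statistical choices behind it, what the synthetic-data generator does and
does not emulate, and the known limitations. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The model

A test-day record of trait `t` (milk, fat or protein) in lactation `l`
(1-3) of cow `i` at days in milk (DIM) `d` is modelled as

$$ y = \mathbf{X}b + \mathbf{Q}(\mathbf{Z}a + \mathbf{W}p) + e $$

* Fixed effects `b`: herd-year-month of test (one classification shared
  across lactations, separate effects per trait), breed group x calving
  season x stage-of-lactation month within lactation, and linear plus
  quadratic age at calving within trait and lactation. Breed groups follow
  the Holstein-Friesian blood fraction (below 87.5%, 87.5-93.75%
  inclusive, above 93.75%); seasons are winter (Nov-Feb), summer
  (Mar-Jun), rainy (Jul-Oct); the stage month is `ceiling(DIM/30.5)`
  capped at 11.
* Random regressions: each animal carries one additive-genetic (AG)
  coefficient vector `a` and each cow with records one
  permanent-environmental (PE) vector `p`, with `order` coefficients per
  trait-lactation stratum (45 in the full order-5, 9-stratum model). The
  DIM dependence sits entirely in the covariables
  $\phi_j(d) = \sqrt{(2j+1)/2}\,P_j(x(d))$, orthonormal Legendre
  polynomials on DIM standardized to $[-1,1]$. This orthonormal scaling is
  the convention of the covariance-function literature and makes `G0`
  entries comparable across studies.
* Covariance structure: $\mathrm{var}(a) = A \otimes G_0$ with `A` the
  pedigree numerator relationship matrix, $\mathrm{var}(p) = I \otimes
  P_0$, and a diagonal residual with one variance per trait-lactation
  stratum, constant along DIM. Traits observed on the same test day are
  residual-independent, so a test contributes one observation row per
  non-missing trait and missing fat/protein simply drop their rows.

305-d aggregates use the summing vector $S_j = \sum_{d=5}^{305}\phi_j(d)$
over the 301 integer DIM (sums, not integrals, matching the usual
"sum of (co)variances" definition): a stratum's 305-d EBV is $S^\top
\hat a$, its 305-d genetic variance $S^\top G_{0,ss} S$, and the 305-d
heritability divides by AG + PE + 301 times the daily residual variance
(a configuration switch can omit the residual term, since published table
footnotes are ambiguous about it; accumulating it reproduces the
characteristic ordering daily h² < 305-d h²).

Average daily heritability is reported under both conventions — the mean
of the daily ratios and the ratio of the mean variances. They agree to
about 0.01-0.02 at realistic magnitudes; the ratio-of-means convention is
the one used for comparisons with published average-daily tables.

## Pedigree machinery

`build_A()` implements the recursive tabular method and serves as the
small-scale oracle. The mixed-model equations never use `A` itself, only
the sparse inverse from Henderson's rules; inbreeding is accounted for via
Meuwissen-Luo coefficients, so `build_A_inverse()` is the exact inverse of
`build_A()` on any valid pedigree (the test suite checks the product
against the identity on random inbred pedigrees). Unknown parents
contribute as the base population mean; unknown-parent groups are not
modelled. Animals are renumbered internally to consecutive integers in
topological order.

## Gibbs sampler

Variance components are estimated by single-chain blocked Gibbs sampling:

* Location effects are drawn from Gaussian full conditionals by iteration
  on data, maintaining the residual vector incrementally. Scalar
  fixed-effect levels are single-site blocks; an animal's AG vector is a
  joint block; and crucially, a recorded cow's AG and PE vectors are drawn
  as **one joint block**. Their sum is pinned by the cow's own records, so
  separate updates leave the chain creeping along the AG/PE ridge; the
  joint draw re-partitions the sum every sweep and mixes the variance
  components orders of magnitude faster.
* `G0 | a` is inverted-Wishart with scale $M^\top A^{-1} M$ plus the prior
  scale and degrees of freedom `n_animals` plus prior df; `P0 | p` is the
  identity-weighted analogue; each stratum residual variance is scaled
  inverse-chi-square with scale `sum(e^2)` and df equal to the stratum's
  observation count (an empty stratum keeps its previous draw, with a
  warning).
* The "uniform prior" of the estimation protocol is implemented as a
  near-flat proper inverted-Wishart (identity scale times 1e-6, df =
  dimension + 1): truly flat priors on 45 x 45 blocks are improper at
  desk-scale data sizes. A flat option exists and refuses to run when the
  conditional would be improper.
* The default desk-scale protocol is chain 20,000 / burn-in 5,000 /
  thinning 10; the published full-scale protocol (200,000 / 50,000 / 20,
  retaining exactly 7,500 draws) is available as the `"paper"`
  configuration preset. Burn-in is fixed rather than judged from trace
  plots; `geweke_z()` provides an optional convergence diagnostic.

The per-iteration work is done in compiled code (RcppArmadillo). The
observation structure is gathered into dense per-block row sets once —
the sparsity pattern never changes over the chain — and every draw uses
R's RNG, so chains are bit-reproducible from `set.seed()`.

## Mixed-model equations and solver

`assemble_mme()` folds the covariables directly into the incidence rows
(mathematically identical to carrying a separate covariable matrix),
weights rows by their stratum residual variance, and adds
$A^{-1}\otimes G_0^{-1}$ and $I\otimes P_0^{-1}$. Equations are ordered
fixed effects first, then AG coefficients grouped per animal, then PE per
cow. `solve_mme()` runs conjugate gradient with a Jacobi (diagonal)
preconditioner from a zero start to a default relative-residual tolerance
of 1e-10; rank-deficient fixed-effect blocks are left unconstrained —
CG converges on the singular but consistent system and estimable
functions (EBVs, contrasts) are unique, which the tests verify by
shifting all phenotypes and checking the EBVs do not move.

## The synthetic-data generator

`simulate_pedigree()` builds yearly cohorts: founder sires, founder dams
(optionally fewer dams than cows, giving full-sib families), and recorded
daughter cows. Two structural options matter for validation studies:

* `dam_from_cows`: later cohorts take their dams from the previous
  cohort's recorded cows, creating recorded dam-daughter pairs;
* `sire_from_cows`: both parents are previous-cohort recorded cows paired
  into matings, so every later animal has two recorded parents plus full
  sibs.

`simulate_records()` draws true AG vectors down the pedigree (midparent
plus Mendelian residual with variance $(0.5 - 0.25(F_s+F_d))G_0$, exact
for inbred parents as well), iid PE vectors, fixed effects once per level
(herd-year-month and breed-season-stage effects scaled by each stratum's
residual SD), monthly DIM grids with jitter, joint fat/protein
missingness, and lactation drop-out. Phenotypic means default to the
magnitudes of tropical Holstein-Friesian upgrades (about 13.1 / 0.47 /
0.41 kg per day). The default `G0`/`P0` come from a Kronecker
construction — a stratum-level covariance (average daily variances from
the calibrated anchor table, cross-stratum correlations from the 305-d
anchor correlation tables) crossed with a decaying coefficient profile —
so the implied average daily variances match the anchors exactly and all
matrices are SPD by construction.

Genetic trends are generated in two ways. With founder-dam cohorts the
founder coefficient means shift linearly with birth year — simple, but an
animal-model BLUP cannot recover such a trend because it violates the
zero-mean founder assumption and the confounded herd-year-month effects
absorb it. The validation mechanism is therefore **selection**: with both
parents recorded, parents are truncation-selected on their own-record
information (daily-average genetic plus permanent value plus the
measurement error of an 8-test mean), with the truncation point chosen so
the selected parents' true 305-d BV mean advances the cohort mean by the
design trend. Selection on information carried by the records is exactly
the situation in which animal-model BLUP tracks genetic trends without
bias.

What the generator does **not** emulate: culling on yield, heterogeneous
residual variance along DIM or across herds, seasonal calving patterns
(calving months are uniform), genotype-by-environment interaction, and
real lactation-curve shapes beyond what the polynomial basis induces.
Passing recovery tests therefore demonstrates correctness of the
machinery under the model's own assumptions, not robustness to their
violation.

## Validation designs and problem sizes

Two fixed designs drive the recovery checks (and the acceptance script):

* **`recovery_design()`** — single trait, single lactation, order 2,
  true average daily AG = 4, PE = 4, residual = 2 (true average daily
  heritability 0.40, component proportions like first-lactation milk);
  500 recorded cows in two cohorts of 250 with 8 tests each, second
  cohort from recorded mating pairs. The AG/PE split is identified only
  through phenotypic covariances among relatives, and at 500 cows the
  posterior mean of the AG variance has an irreducible seed-to-seed
  spread of order 1 (a quarter of its value) whatever the family
  structure — the information bound scales with the number of relative
  pairs times the squared relationship, against the product of total
  individual variances. Recovery is therefore assessed on the **average
  over five replicate populations and chains** (about seven minutes of
  computing): the mean posterior-mean daily heritability against the true
  0.40, and the mean AG variance against 4. Recorded mating pairs were
  chosen over half-sib-only structures because parent-offspring and
  full-sib pairs carry the largest relationship coefficients and hence
  the most information per recorded animal.
* **`trend_design()`** — milk in lactations 1-3 (order 2), eleven
  cohorts of 150 cows, parents selected recorded cows; genetic scale set
  to a 305-d genetic SD of 40 kg so the imposed 10 kg/yr equals about a
  quarter of a genetic SD per year, the regime of intense dairy
  selection. Three lactations per cow spread each animal's tests over
  three to four calendar years, which ties adjacent birth cohorts
  together within herd-year-month classes; without that overlap the
  cohort means are confounded with the test-date effects and the
  estimated trend collapses toward zero. The trend check regresses yearly
  mean lactation-1 EBV on birth year over five replicate populations.

Unit tests use much smaller populations (tens of cows, chains of a few
hundred) and the oracle comparisons (dense matrix constructions, tabular
relationship matrices, quadrature) use exact algebra.

## Numerical choices

* Legendre covariables come from the standard three-term recurrence in
  double precision; orthonormality holds to 1e-9 under adaptive
  quadrature.
* SPD checks go through Cholesky; the stratum-correlation anchors are
  shrunk toward the identity until Cholesky succeeds (a safety net that
  is inactive for the shipped values).
* A non-SPD Gibbs full conditional triggers one jitter retry
  (1e-8-scaled diagonal) before aborting with a diagnostic.
* Dates are carried as year-month integers only; the herd-year-month
  classification needs no finer resolution.
* Delimited files are comma-separated with a header; missing values are
  empty strings; `readr` writes shortest round-tripping representations
  so tables re-read exactly.
* All randomness flows through R's RNG: a single `set.seed()` reproduces
  simulations and chains bit-for-bit on a platform.

## Open design points, resolved

* *Stage month*: "month in tested milk group" is interpreted as
  stage-of-lactation month (eleven monthly classes spanning DIM 1-305),
  not calendar test month — the calendar month is already inside the
  herd-year-month classification.
* *Partial tests*: the edit rules keep tests with missing fat/protein by
  default (matching the unequal trait counts real recording produces); a
  strict mode drops them.
* *Edit-rule order and attribution*: test-level drops first (milk out of
  \[2, 40\] kg, DIM beyond 305), then cow-lactation checks in a fixed
  order (first-test window, test count, last-test DIM, age window,
  lactation sequence, sire known); a cow-lactation is attributed to the
  first rule it fails, and one that fell below the test-count minimum
  through drops is attributed to the dropping rule. This makes removal
  reports deterministic and idempotent.
* *Inbreeding in* `A^-1`: included (with a switch), because exactness
  against the tabular oracle demands it.
* *PCG details*: Jacobi preconditioning and a relative-residual criterion
  of 1e-10, both configurable.

## Known limitations

* Reliabilities / prediction error variances of EBVs are not computed.
* No unknown-parent groups, so populations with strong unmodelled
  base-population structure will bias trends (the generator avoids
  creating such structure in its validation designs for exactly this
  reason).
* Residual variance is homogeneous along DIM within stratum; heterogeneous
  variants are out of scope.
* The Gibbs sampler runs a single chain; multi-chain diagnostics beyond
  the Geweke z-score are not provided.
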