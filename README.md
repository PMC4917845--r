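# acegrowth

Genetic and environmental variance decomposition of height from infancy
to early adulthood, using the classical twin design.

## What this is for

In twin data, monozygotic (MZ) pairs share their full genotype and
dizygotic (DZ) pairs on average half of their segregating alleles.
Comparing the within-pair resemblance of the two kinds of pairs splits
the phenotypic variance of height into additive genetic (A), shared
environmental (C) and unique environmental (E) components. This package
is aimed at biostatisticians and behaviour geneticists who want a tested,
self-contained implementation of that analysis across the growth period:

* a **synthetic cohort generator** that emulates a large multi-region
  pooled twin database (three geographic-cultural regions, ages 1–19,
  zygosity mix 39% MZ / 34% same-sex DZ / 27% opposite-sex DZ,
  region-specific growth curves, cohort effects, repeated measurements)
  with a fully known generating ACE structure;
* the **sample-construction pipeline**: age windowing into half-open
  one-year bins, outlier trimming, one observation per individual per age
  group, a minimum-cohort-size filter, and OLS residualization on birth
  year, exact age and cohort within strata;
* the **ACE sex-limitation model** per one-year age group — 11 free
  parameters: sex-specific paths a, c, e, the opposite-sex additive
  genetic correlation r_gOS, and zygosity-by-sex means. For sex *s*:

      y = mu(zyg, s) + a_s A + c_s C + e_s E

  with A correlated 1.0 (MZ), 0.5 (same-sex DZ), r_gOS (opposite-sex),
  C correlated 1.0, E uncorrelated; within-pair covariances
  a² + c² (MZ), a²/2 + c² (DZ), r_gOS·a_m·a_f + c_m·c_f (OS);
  h² = a²/(a² + c² + e²). Fitting is exact maximum likelihood from
  per-group sufficient statistics, with a saturated model
  (equal-environment test), nested submodels (equal sexes, scale,
  drop-C/drop-A), likelihood-ratio tests, Bonferroni correction and
  profile-likelihood confidence intervals;
* the **gene-by-age moderation model** on same-sex pairs: path
  coefficients and zygosity-specific means are quadratics in age
  (15 parameters per group), fitted per sex and per sex-by-region by
  per-pair maximum likelihood, with the degrees-of-freedom arithmetic
  for the published comparisons (15 for sex equality, 30 for
  three-region equality, 3 for the quadratic terms).

## Worked example

Simulate twin pairs at the variance components reported for one-year-old
boys and girls (h² = 0.40/0.38, c² = 0.48/0.49, total SD 4.3 cm) and
refit them:

```r
library(acegrowth)

sd1 <- 4.3
truth <- sexlim_params(
  a_m = sqrt(0.40) * sd1, c_m = sqrt(0.48) * sd1, e_m = sqrt(0.12) * sd1,
  a_f = sqrt(0.38) * sd1, c_f = sqrt(0.49) * sd1, e_f = sqrt(0.13) * sd1,
  r_gos = 0.5, mu_mzm = 74.3, mu_mzf = 72.9)
pairs <- simulate_pairs_at_age(
  c(MZM = 1511, MZF = 1511, DZM = 1318, DZF = 1318, OS = 2092),
  truth, seed = 42)
fit <- fit_ace_sexlim(pairs)
fit
#> ACE twin-model fit [ACE sex-limitation]
#>   -2logL = 82163.11262  free parameters = 11  converged = TRUE
#>   males  : h2 = 0.381  c2 = 0.505  e2 = 0.114
#>   females: h2 = 0.392  c2 = 0.474  e2 = 0.134
#>   r_gOS  = 0.488
profile_ci(fit, "h2_m")
#>     lower     upper
#> 0.3337496 0.4324937
#> attr(,"estimate")
#> [1] 0.381184
#> attr(,"level")
#> [1] 0.95
```

At ~7,750 pairs a single replicate scatters around the truth
(here 0.381 against a generating 0.40, with the 95% interval covering
it); averaging over replicates recovers the generating components to
well under a point (see below).

The end-to-end analysis lives in `analysis/01_simulate.R` …
`analysis/06_sensitivity.R`: generate a 20,000-pair cohort, preprocess
it, tabulate descriptives and twin correlations, fit the per-age
sex-limitation models with profile CIs and equal-environment tests, fit
the gene-by-age moderation models with the sex/region/quadratic
comparisons, and run a cohort-exclusion sensitivity analysis. Each stage
prints what it found and writes its tables under `results/analysis/`
(bulky intermediate data go to `scratch/`). On the default synthetic
cohort, stage 4 prints, among other things:

```
fitted 19 age groups; 19 converged
boys' h2: 0.38 at age 1 rising to 0.88 at its peak (age 15)
equal-environment test rejections after Bonferroni: 0 of 19
```

— the generator's heritability rises from 0.40 at age 1 to low-0.8s in
adolescence, and per-age estimates at ~2,000 pairs per age scatter
around that trajectory; the equal-environment assumption holds in the
generator and is correctly not rejected.

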