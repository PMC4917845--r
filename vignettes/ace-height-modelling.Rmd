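---
title: "Variance decomposition of height across the growth period: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance decomposition of height across the growth period}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acegrowth)
```

## The scientific problem

Height is a strongly heritable, approximately normal quantitative trait
whose genetic and environmental architecture changes over the growth
period. The classical twin design exploits the contrast between
monozygotic (MZ) pairs, who share their full genotype, and dizygotic (DZ)
pairs, who share on average half of their segregating alleles: the excess
resemblance of MZ over DZ co-twins identifies additive genetic variance
(A), the resemblance that remains in DZ pairs beyond half of the MZ
resemblance identifies shared environmental variance (C), and the
remainder — including measurement error — is unique environmental
variance (E). `acegrowth` implements this decomposition for height in
one-year age groups from 1 to 19 years, with sex-specific components and
an opposite-sex genetic correlation (the *sex-limitation* model), and a
gene-by-age interaction model in which the path coefficients are smooth
functions of age.

Because individual-level pooled twin-registry data are not publicly
deposited, the package is built around a synthetic-data generator with a
fully known generating structure; every estimator is validated by
parameter recovery against that structure.

## The ACE sex-limitation model

Pairs fall into five zygosity-sex groups: MZM, MZF, DZM, DZF and OS
(opposite-sex DZ, male listed first). For sex $s$, the phenotype of twin
$i$ is

$$y_i = \mu_{z,s} + a_s A_i + c_s C + e_s E_i,$$

with standard-normal latent deviations correlated within a pair as

* $A$: 1.0 (MZ), 0.5 (same-sex DZ), $r_{gOS}$ (opposite-sex);
* $C$: 1.0 in all groups;
* $E$: uncorrelated.

This gives within-pair covariances $a_s^2 + c_s^2$ (MZ),
$\tfrac12 a_s^2 + c_s^2$ (same-sex DZ) and
$r_{gOS}\, a_m a_f + c_m c_f$ (OS), and total variance
$V_s = a_s^2 + c_s^2 + e_s^2$. Standardized components are
$h^2 = a^2/V$, $c^2 = c^2/V$, $e^2 = e^2/V$. Because DZ twins tend to be
slightly taller than MZ twins in childhood, means are free per
zygosity-by-sex cell ($\mu_{MZm}, \mu_{DZm}, \mu_{MZf}, \mu_{DZf}$; OS
pairs use the DZ means of their sexes). That yields 11 free parameters.

Two parameterization points deserve emphasis:

* **OS genetic covariance.** We write it as $r_{gOS}\, a_m a_f$, so the
  estimated correlation is directly comparable with its no-sex-limitation
  reference value 0.5. Estimates below 0.5 indicate qualitative
  sex-specific genetic effects.
* **Unbounded paths.** The optimizer works on raw paths (any sign) and
  reports their absolute values; variances are squares, so no boundary
  constraints are needed, and a component that is truly absent converges
  to a path of 0. $r_{gOS}$ is kept in $[-1, 1]$ by a $\tanh$ transform.

### Likelihood

With complete pairs, constant group moments, and data grouped into the
five cells, the bivariate-normal likelihood depends on the data only
through each group's pair count, sample mean vector and scatter matrix.
`neg2ll()` evaluates this closed form by default and retains a direct
per-pair summation (`method = "perpair"`) for verification; the two agree
to $10^{-8}$ on arbitrary data, which the test suite checks against an
independently written density oracle. The sufficient-statistic form makes
a full 11-parameter fit take milliseconds regardless of sample size,
which is what makes the replicate-based calibration studies below cheap.

### Model family and tests

* `fit_saturated()`: free means, variances and within-pair covariances
  per group, equated across co-twins within same-sex groups because the
  within-pair ordering is arbitrary (6 means + 6 variances +
  5 covariances = 17 parameters; closed-form ML with the $n$
  denominator). Comparing ACE against it tests the equal-environment
  assumption; the per-age tests are Bonferroni-corrected across age
  groups.
* `fit_submodel()`: `equal_sexes` (paths equated, $r_{gOS} = 0.5$; 7
  parameters), `scale` (equal standardized proportions with a free
  female/male variance ratio; 9), `drop_C` and `drop_A` (9 and 8). The
  deviance ordering saturated $\le$ ACE $\le$ scale $\le$ equal-sexes is
  a tested invariant.
* `lrt()`: $\Delta(-2\log L)$ against the $\chi^2$ tail with
  $\Delta\mathrm{df}$ equal to the difference in free-parameter counts.
* `profile_ci()`: likelihood-based intervals; the boundary is where the
  profiled deviance (nuisance parameters re-optimized) rises by the
  $\chi^2_1$ quantile, 3.841 at 95%. Profiling a standardized proportion
  re-parameterizes that sex's block as (total variance, fixed proportion,
  split of the remainder), so the constraint is exact. Intervals are
  truncated to $[0,1]$ (proportions) or $[-1,1]$ ($r_{gOS}$); when the
  estimate sits at a boundary the interval is closed there one-sidedly.

## Gene-by-age moderation

Fitting 19 separate age-group models costs many parameters; the
moderation model instead lets the paths vary smoothly with age. For
same-sex pairs of one group, with $x = \text{age} - 10$ (centering chosen
purely for numerical conditioning),

$$a(x) = a_0 + a_1 x + a_2 x^2,$$

and similarly for $c(x)$ and $e(x)$; variances are the squared path
polynomials, so they are non-negative by construction. Means are
zygosity-specific quadratics in $x$ (6 coefficients), giving 15 free
parameters per group. Opposite-sex pairs are excluded: the size of the
sex-specific genetic effect itself varies with age, which the model does
not represent.

**A reconstruction caveat.** The 6-parameter mean structure is inferred
from degrees-of-freedom arithmetic (9 path + 6 mean coefficients per
group reproduces the 15-df sex comparison, the 30-df three-region
comparison, and the 3-df quadratic-terms test), not from an explicit
published equation. It is the simplest structure consistent with those
counts, but a quadratic cannot track a 100+ cm growth curve exactly, and
because the mean misfit is shared by co-twins it loads on the C
component when the model is fitted to full-age-range cohort data whose
only covariate adjustment is birth year and cohort. Region- or
age-restricted fits, where the quadratic approximation is good, do not
show this artefact; parameter recovery on data generated from the
moderation model itself is clean (checked at 30,000 pairs).

Ages enter as exact (continuous) ages, so no sufficient-statistic
shortcut exists; the per-pair likelihood is fully vectorized.
`count_free_params()` exposes the df arithmetic used by the comparisons,
and `variance_curves()` tabulates the implied A/C/E variances by age and
locates the age of maximal genetic variance by fine grid search with
local refinement.

## The synthetic-data generator

`generator_config()` defaults *are* the study conditions:

* three geographic-cultural regions (Europe; North-America and
  Australia; East-Asia) sampled with weights proportional to the
  observed paired-measurement counts (131,856 / 29,856 / 17,924), with
  20 / 15 / 6 cohorts of heavy-tailed sizes;
* zygosity mix 39% MZ, 34% same-sex DZ, 27% opposite-sex DZ, sexes
  assigned at 1:1 within MZ and SSDZ;
* region- and sex-specific mean growth curves and total SDs taken from
  the reference descriptive table (`growth_reference()`), interpolated
  linearly in exact age;
* standardized components per age and sex (`default_components()`)
  anchored at the reported pooled estimates — boys 0.40/0.48/0.12 at
  age 1, $h^2$ 0.83 at 14 and 0.82 at 16; girls 0.38/0.49/0.13 at age 1
  with a 0.76 peak — and interpolated smoothly in between with $e^2$ held
  in the 0.05–0.14 band typical of height;
* a geometric number of repeated age groups per pair with
  `repeat_prob = 0.5`, giving about 2 measurements per pair, close to
  the observed ratio of paired measurements to distinct pairs (~2.1);
* `r_gOS = 0.5` (no qualitative sex limitation), DZ mean shift 0, cohort
  effects with SD 0.5 cm, birth years 1950–2005 with a 0.02 cm/yr
  secular trend — small, plausible values for the nuisance structure the
  preprocessing stage is supposed to remove.

A and C latents persist across a pair's repeated measurements; the
within-person correlation of E across age groups is unknown in real data
and is exposed as `repeat_e_corr` (default 0) rather than asserted.
Assortative mating (`assortative_r`) is off by default and, when enabled,
raises the DZ/OS genetic correlation through the correlated parental
midpoints; it is documented as approximate and exists for robustness
experiments only. Measurement error is folded into E unless
`measurement_error_sd` is set, which supports equal-environment-violation
experiments.

What the generator does **not** emulate: longitudinal autocorrelation
beyond the shared latent structure, gestational age and birth-weight
effects, true growth-curve biology within an age bin, and real
between-cohort heterogeneity in anything but the mean. Passing recovery
tests on this generator therefore shows that the estimators are correct
for the model class, not that real heights satisfy the model.

## Preprocessing choices

* Age bins are half-open, $[k - 0.5, k + 0.5)$: a partition with no
  double assignment; ages outside $[0.5, 19.5)$ are discarded.
* Outliers: the original procedure was visual inspection of histograms,
  which cannot be reproduced mechanically. We substitute hard
  plausibility bounds (default 30–250 cm, optionally per age-sex) plus
  iterated $|z| > 3.5$ trimming within age-by-sex strata; on clean
  simulated data this removes well under 1% (about 0.1% in the default
  cohort), of the order of the 0.3% removed in the original sample.
  Strata with fewer than 10 records skip the z-rule.
* One observation per individual per age group keeps the record nearest
  the integer age (ties: earliest record), a deterministic rule chosen
  where the original choice is unstated.
* Cohorts contributing fewer than 50 measurements are dropped
  (inclusive boundary: exactly 50 is kept).
* Residualization is OLS within sex-by-age strata on birth year, exact
  age and cohort indicators for the per-age models, and within sex
  strata on birth year and cohort only for the moderation models (age is
  the moderator there and must remain in the phenotype). Cohort enters
  as fixed-effect indicators; collinear columns are dropped by the fit.
* Only complete pairs are analyzed; MZ pairs with discordant recorded
  sex are impossible and are routed to a data-error report.

## Numerical choices

* **Optimizer.** Quasi-Newton (BFGS) on transformed parameters with
  per-parameter scaling, from a Falconer start
  ($a^2 = 2(r_{MZ} - r_{DZ})$, clipped to $[0.05, 0.9]$) plus 4 jittered
  restarts under a fixed restart seed. Non-finite trial values are capped
  so the line search backs off rather than aborting. After the best start
  is chosen, BFGS is re-polished until the improvement falls below
  $10^{-8}$.
* **Convergence.** The reported flag requires a clean optimizer exit and
  a scaled finite-difference gradient norm below
  $10^{-5}\max(1, |-2\log L|)$. The tolerance is relative because the
  attainable finite-difference accuracy scales with the magnitude of the
  objective (about $10^5$ on cm-scale data); an absolute cutoff near
  machine precision would never be met even at the exact optimum.
  Non-convergence after all starts returns the best point, flagged.
* **Degenerate inputs.** A singular implied covariance yields
  $+\infty$ deviance, not an exception; saturated fits flag groups with
  fewer than 2 pairs as unidentifiable, and the pipeline reports the
  equal-environment test as missing at such ages; a negative
  likelihood-ratio statistic beyond $10^{-4}$ (an optimizer artefact)
  warns and clamps to zero.
* **Boundary estimates.** $\hat a^2 = 0$ is reported as exactly 0 with a
  one-sided interval; no sign flips.

### Boundary non-regularity of the drop-C test

Testing $c = 0$ by a likelihood ratio against $\chi^2_2$ is non-regular:
the covariance depends on $c$ only through $c^2$ (and $c_m c_f$), so the
null value lies on the boundary of the induced parameter space and the
information in the paths vanishes there. The asymptotic null is a
mixture with an atom at zero, making the nominal $\chi^2_2$ test
conservative — in 500-replicate simulations at the null, the 5%-level
test rejects in roughly 0.5–3% of replicates, not 5%. The package still
reports the conventional $\chi^2$ p-value (the field's standard
practice, and the quantity the published model-fitting tables print),
but users should read near-threshold drop-C p-values as conservative.
The corresponding calibration check in the test suite is asserted at the
nominal band and documents this known failure.

## Problem sizes used by the validation suite

Chosen as the package's own trade-off between Monte-Carlo precision and
a desk-scale run: likelihood-oracle equivalence on 20 random datasets of
up to 20 pairs at $10^{-8}$; Falconer agreement on 50,000 balanced
same-sex pairs within 0.01; parameter recovery at the age-1 and age-14
reported components on 100 replicates of ~7,750 pairs within $\pm 0.02$;
drop-C type-I calibration on 500 replicates of 750 small-sample pairs;
95% profile-interval coverage on 200 replicates at 5,000 pairs per group
within $95\% \pm 4\%$; moderation null calibration (equating two
identically generated groups costs a mean deviance near its 15 df) on 40
replicates of 1,400 pairs.

## Known limitations

* Dominance genetic effects (D) are not modelled: with twins reared
  together, D and C cannot be estimated jointly.
* Assortative mating is not corrected for in estimation (no parental
  data); uncorrected, it inflates C at the expense of A.
* The moderation mean structure is a df-consistent reconstruction (see
  above), and age enters it as exact age rather than the bin midpoint —
  both choices are documented, not published facts.
* The profile-interval method and the correlation estimator
  (double-entry Pearson) are reasonable defaults where the original
  choices are unstated.
* Real-data estimates cannot be reproduced here because the underlying
  individual-level registry data are not public; all empirical claims in
  this package are about recovery of known generating structures.
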