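---
title: "Twin variance-component models in twinkit: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin variance-component models in twinkit: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinkit)
```

# The model

`twinkit` analyses same-sex twin pairs measured on continuous (or
continuized) phenotypes. The classical decomposition writes each
twin's phenotype as a sum of latent additive-genetic (A), shared
environmental (C), and unique environmental (E) deviates with path
coefficients $a$, $c$, $e$:

$$P_i = a A_i + c C + e E_i .$$

A correlates 1 across monozygotic (MZ) co-twins and 0.5 across
dizygotic (DZ) co-twins; C is shared; E (which absorbs measurement
error) is independent. The implied pair covariance has diagonal
$a^2+c^2+e^2$ and off-diagonal $\rho a^2 + c^2$ with $\rho = 1$ (MZ)
or $0.5$ (DZ). `pair_covariance()` is this matrix; the nested AE, CE,
and E families zero out paths.

**Sibling interaction.** When the saturated model shows unequal total
variances across zygosity, a phenotypic interaction coefficient $s$ is
added: each twin's phenotype feeds linearly into the co-twin's, so the
pair vector solves $P = B P + u$ with $B$ holding $s$ off-diagonally,
giving $\Sigma = (I-B)^{-1}\Sigma_u (I-B)^{-\top}$. Because the
off-diagonal of $\Sigma_u$ differs by zygosity, the *total* variances
then differ by zygosity too — exactly the signature the assumption
test picks up. $|s|<1$ keeps $I-B$ invertible. The same mechanism also
absorbs rater-contrast bias (parents scoring one twin against the
other), so a fitted $s$ is not by itself evidence of a causal
interaction.

**Standardization under interaction.** Standardized components are
squared paths over the *pre-interaction* total $a^2+c^2+e^2$, with $s$
reported separately. This keeps A + C + E = 1 next to an $s$ column,
matching the conventional presentation; the interaction-adjusted total
variance is recoverable from `pair_covariance()`.

**Longitudinal Cholesky.** For two assessment ages the triangular
decomposition gives each source X three paths: $x_1$ (age-1 loading),
$x_b$ (carryover of the age-1 factor to age 2), and $x_u$ (an age-2
unique factor). Squared paths standardized by the per-age totals give
the proportion of age-2 variance carried over versus unique;
`shared_variance_proportions()` reports $x_b^2/(x_b^2+x_u^2)$ per
source. Sibling interaction, when requested, acts within each age
(block-diagonal $B$ with $s_1$, $s_2$): the univariate construction
applied per timepoint. A cross-age interaction is never modeled — no
within-age interaction pattern motivates one, and the parameter would
be poorly identified from two occasions.

# Estimation

All structured models are fitted by full-information maximum
likelihood on the multivariate-normal pair vectors: rows are grouped
by missingness pattern and summarized once (count, mean, scatter), so
a likelihood evaluation costs the same at 200 pairs as at 100,000, and
incomplete pairs contribute the marginal likelihood of their observed
cells. A single grand mean per timepoint is used in the structured
models; mean and variance homogeneity over twin order and zygosity is
checked first by likelihood-ratio tests against the saturated model
(`fit_saturated()`), and covariates are residualized out beforehand by
the GEE stage, which is why the structured means carry no further
structure.

**Parameterization and optimizer.** Paths enter unconstrained and are
squared into variances, so the implied covariance is positive
semi-definite by construction and no constrained optimizer is needed;
path signs are not identified and are reported as magnitudes. BFGS
runs from a method-of-moments (Falconer) start plus deterministic
jittered restarts (default 10 for univariate fits; 8
moment-derived starts for the bivariate model). Convergence requires
`optim` success and a gradient norm below
$\max(10^{-3}, 10^{-5}\,|{-2\mathrm{LL}}|)$; failures are flagged on
the fit object, never silent.

**Free-parameter counts.** $k$ = paths + interaction terms + one mean
per timepoint: 4 for univariate ACE, 10 for bivariate AE-s, 11 for
bivariate ACE. AIC = $-2\mathrm{LL} + 2k$.

**Model selection.** Candidates whose likelihood-ratio test against
the most general fit (ACE-s by default) is non-significant at 0.05
compete on AIC; ties within $10^{-9}$ go to fewer parameters, then to
a fixed family order, so selection is fully deterministic.

**Confidence intervals.** Univariate standardized components and $s$
get profile-likelihood intervals: the set of fixed values whose
re-maximized $-2\mathrm{LL}$ stays within $\chi^2_1(0.95) = 3.84$ of
the minimum, bounded to $[0,1]$ for proportions. The profile is
computed by re-parameterizing on (total variance, split of the
remaining proportion), and the endpoints by root-finding on the
profile deviance. Bivariate standardized components use delta-method
Wald intervals from the numerical Hessian instead — profiling nine
paths per component grid point buys little at these sample sizes. The
reporting choice (profile univariate, Wald bivariate) is the package's
own; the tables it emulates do not state how their intervals were
formed.

**Boundary effects on the interaction LRT.** With a single timepoint
the ACE-s model is exactly identified (four structural parameters,
four second moments), and its moment inverse can demand negative
$a^2$ or $c^2$; in finite samples the ACE vs ACE-s deviance therefore
sits below the nominal $\chi^2_1$ reference. The AE vs AE-s contrast
is over-identified with an interior null and is what the package's
calibration checks use. Naive $\chi^2$ p-values are nevertheless the
default throughout (the field's convention); they are conservative for
boundary-affected component tests.

# Clustered regression

Covariate screening, residualization, and polygenic-score association
use Gaussian generalized estimating equations with the twin pair as
cluster. The working correlation is exchangeable by default — the
natural structure for twins — with independence available; either way
the reported covariance is the cluster-robust sandwich
$B^{-1} M B^{-\top}$, so inference does not lean on the working
choice. The within-cluster correlation is estimated by moment matching
of Pearson-residual cross-products, the dispersion by the residual sum
of squares over $n-p$. No small-sample correction is applied by
default (the study regime has >400 clusters); an HC1-style factor is
available. Residualization subtracts population-averaged fitted
values, consistent with GEE's marginal interpretation. Polygenic
scores and phenotypes are z-scored, so association coefficients are
standardized effects; ancestry principal components enter as supplied
columns (deriving them is out of scope). Bonferroni corrections are
applied per score across its phenotype-by-age tests.

# Preprocessing rules

- **Durations**: parsed to minutes; hour units multiplied by 60;
  ranges ("10–30 min") replaced by midpoints; "a couple/few minutes"
  mapped to 2; empty cells missing. Bare numbers are minutes, except
  that under the default ambiguity rule a bare positive value below 1,
  or any negative value, is excluded with provenance
  `excluded_ambiguous` (such entries could plausibly be hours). The
  alternative rule excluding only negatives is available; the source
  description of this rule is internally inconsistent ("a number less
  than zero … unclear whether minutes or hours"), so both readings are
  configurable and neither is asserted as authoritative.
- **Corrected age**: chronological days minus $7(39-\mathrm{GA})$;
  gestational ages above 45 or at/below 0 weeks error, below the
  34-week study floor warn.
- **Assessment windows**: individuals outside target ± 40 days
  (boundaries inclusive — "40 days younger or older" is read as strict
  exclusion beyond ±40) have that assessment's phenotypes blanked;
  the co-twin's data survive and the model fitters handle the
  incomplete pair. Exclusion reports partition the input into
  retained / too-young / too-old / missing-age. Published descriptives
  show some 5-month ages outside the stated window; the filter follows
  the stated rule and the discrepancy is simply noted.
- **Daylight**: geometric sunrise-to-sunset with the conventional
  −0.833° altitude (refraction plus solar radius) and a Fourier-series
  declination, clamped to [0, 1440] minutes. The postal-digit → region
  map is explicit configuration: reference latitudes 55.60°
  (Malmö), 59.33° (Stockholm), 62.39° (Sundsvall), 67.86° (Kiruna),
  digits 2–4 / 1, 5–6 / 7–8 / 9 respectively, evaluated on the 15th of
  the assessment month. Neither the cities nor the digit grouping is
  published, so the defaults are overridable and any analysis records
  them in its manifest.

# The synthetic-cohort generator

The generator draws zero-mean Gaussian pair vectors with exactly the
covariance the models assume — MZ pairs first, then DZ, one RNG stream
per cohort, so fixtures are bit-reproducible from a seed. Default
cohort size is 242 MZ and 218 DZ pairs, the scale of the emulated
study. Covariates are attached at the correct level (pair-shared:
income band, parental ages, gestational age, assessment age, daylight;
twin-specific: birthweight) with distributions mirroring the study's
descriptive table, and linear effects are applied to standardized
covariates so coefficients read in phenotype-SD units. A rendering
layer maps latent scores through a monotone transform to
exponential-marginal durations (mean 20 min, a typical settle/crying
magnitude) and writes free-text responses with configurable rates of
range answers, verbal answers, unit-ambiguous small numbers, and
missing cells.

What it deliberately does not emulate: the latent phenotypes are
exactly Gaussian after the inverse transform, whereas real
questionnaire durations are discretized, heaped at round numbers, and
zero-inflated; item non-response is independent rather than clustered
in families; and no genotype or ancestry structure is simulated
(polygenic-score columns in examples are synthetic noise). Passing
tests therefore demonstrate correctness of the estimators under the
models' own assumptions, not robustness to real questionnaire
pathology. The duration marginal is a stand-in, not a claim about the
source data.

The longitudinal "wakeups" fixture deserves a note: its carryover
paths are solved from the published *correlation* structure
(within-age correlations at both ages, phenotypic cross-age 0.40,
cross-twin cross-age 0.38 MZ / 0.29 DZ), because the published
bivariate variance-component table implies a larger cross-age
covariance than the published correlation table permits — the two
cannot be satisfied simultaneously, and the correlation structure is
the quantity the fixture's consumers check.

# Problem sizes used by the test suite

Estimator-recovery checks run at 5,000 pairs per zygosity (3 seeded
replicates per family; 24 for the noisier exactly identified ACE-s
case). Null calibration of the interaction LRT uses 400 replicates of
200 + 200 pairs; profile-interval coverage uses 500 replicates at the
study scale; GEE size uses 2,000 replicates of 230 pairs; stochastic
recovery of the AE-s regimes uses 200 study-scale replicates. These
sizes put Monte-Carlo error comfortably inside each check's tolerance
while keeping the full suite in the minutes range on one core.

# Known limitations

- Continuous Gaussian likelihoods only: no liability-threshold models
  for binary/ordinal items, no sex-limitation models (the design is
  same-sex pairs), no extended-family structures.
- Two timepoints only in the longitudinal model; no simplex or growth
  parameterizations.
- Component LRT p-values use the naive $\chi^2$ reference rather than
  boundary mixtures (conventional, conservative).
- The GEE implementation covers the Gaussian identity-link case used
  here, not other families.
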