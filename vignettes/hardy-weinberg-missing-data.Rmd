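---
title: "Hardy-Weinberg inference with missing genotype calls: methods and design"
author: "HardyMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hardy-Weinberg inference with missing genotype calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HardyMI)
```

# The problem

A test for Hardy-Weinberg proportions (HWP) asks whether genotype counts
at a diallelic marker are compatible with the frequencies $p^2$, $2pq$,
$q^2$ implied by the allele frequencies.  In quality-control practice the
missing calls at a marker are discarded first.  That is harmless only if
the calls are missing completely at random (MCAR).  Genotype callers
assign no-calls from the same allele intensities that define the
genotypes, dropping points that fall between or off the genotype clouds —
which are disproportionately heterozygotes and dim samples.  Discarding
then depletes heterozygotes among the *observed* calls and pushes the test
toward rejecting HWP for a reason that has nothing to do with the
population.

HardyMI treats the problem as a missing-data inference task: estimate the
inbreeding coefficient $f$ — the one-parameter disequilibrium measure with
genotype law $(p^2 + pqf,\; 2pq(1-f),\; q^2 + pqf)$ — after multiply
imputing the missing calls, and report the uncertainty the missingness
itself contributes.

# Complete-case estimation

`estimateInbreeding()` implements the maximum-likelihood estimator
$\hat f = 1 - (n_{AB}/n) / (2\hat p\hat q)$ with the large-sample variance

$$\widehat{\mathrm{Var}}(\hat f) \;=\; \frac{(1-f)^2(1-2f)}{n_{\mathrm{var}}}
 \;+\; \frac{f(1-f)(2-f)}{2\,n_{\mathrm{var}}\,pq},$$

evaluated at the estimates.  Two conventions for $n_{\mathrm{var}}$ are
exposed.  The statistically standard choice is the observed sample size
(`nVar = "observed"`, the default).  The `"total"` option uses the full
panel size including missing calls; it is the convention under which the
published worked example's confidence interval is reproduced exactly, and
it is the natural scale for comparing complete-case intervals with
post-imputation intervals, which refer to the completed sample.  At
$f = 0$ the variance reduces to $1/n_{\mathrm{var}}$; at $|f| = 1$ it
degenerates to zero and is reported as `NA` — such markers cannot enter
Rubin pooling and are flagged as skipped rather than propagated as `NaN`.

`chisqHWP()` is the 1-df goodness-of-fit chi-square without continuity
correction; it satisfies $X^2 = n\hat f^2$ algebraically, and the test
suite verifies the identity numerically on random tables.  `exactHWP()`
sums the conditional (Levene–Haldane) probabilities of all heterozygote
counts no more probable than the observed one; it is checked against a
full-enumeration oracle for every table with $n \le 20$.  A mid-p variant
is deliberately out of scope.

# Diagnosing MCAR

Under MCAR the individuals with a missing call are a random subsample, so
their mean allele intensities match those of the called individuals.
`mcarReport()` compares the two groups per marker with:

* per-channel two-sample $t$ tests, pooled-variance and Welch;
* Hotelling $T^2$ on the (A, B) intensity vector, with the classical
  pooled-covariance $F(2, n_1+n_2-3)$ reference and, for unequal
  covariances, the Behrens–Fisher statistic with Yao's approximate degrees
  of freedom (the heteroscedastic reference is not pinned down by
  convention; Yao's is the standard choice);
* a contingency test of missingness status against the genotypes of the
  best LD covariate marker — chi-square when all expected cells are at
  least 5, otherwise Fisher's exact test (the threshold is the usual
  sparsity rule of thumb).

Markers are tested only when at least `minMissing = 15` calls are missing:
below that, group means are too unstable for the comparison to be
informative, and the same floor was applied in the study design this
mirrors.  Rejecting MCAR does not establish MAR — MAR versus MNAR is not
testable from observed data — but it does establish that discarding is not
innocuous.

# Imputation models

`imputeRandom()` draws every missing call independently from the marker's
observed genotype distribution.  This is exactly the model implied by
MCAR: it cannot correct any bias, but it converts the missingness into
quantified extra variance, which is its purpose.

`imputeChained()` is the informative engine.  Each incomplete variable is
modelled by a multinomial (polytomous) logit on the other model variables
— covariate markers in LD with the target plus, optionally, the
variable's own two intensity channels — and the variables are iterated as
chained equations, which handles non-monotone patterns (covariates with
their own missing calls).  Design choices, several of which are genuinely
open in the underlying method and fixed here:

* **Covariate selection** (`selectCovariates()`): dosage $r^2 \ge 0.5$
  with the target, descending, capped at 10.  The dosage correlation is a
  composite proxy for haplotype $r^2$; phase is never inferred.  Perfect
  duplicates ($r^2$ numerically 1) are excluded because they create a
  diagonal contingency structure the logit cannot use.
* **Coding of SNP covariates**: allele dosage plus a heterozygote
  indicator.  With all three genotypes present this spans the same space
  as unordered-factor coding, but it remains well-defined when an imputed
  category appears only in the rows being predicted, which factor coding
  does not survive.
* **Perfect separation**: tightly linked covariates often predict the
  target without error.  Rather than detect-and-fallback, a small ridge
  penalty (`ridge = 1e-4`) is always on, keeping coefficients finite; the
  separation itself is a numerical nuisance, not evidence against the
  predictors.  Optimizer iterations default to 2000 because penalized
  fits near separation have long shallow plateaus.
* **Properness**: before each draw of missing categories, the coefficient
  vector is sampled from the normal approximation centred at the
  penalized fit with the penalized-Hessian covariance
  (`drawCoefficients()`).  Without this step the between-imputation
  variance $B$ understates the estimation uncertainty and Rubin's rules
  undercover.  The sampler clips negative eigenvalues of the (nearly
  singular, near separation) covariance to zero.
* **Visit order and initialization**: incomplete variables are visited in
  order of increasing missingness, after initializing all missing entries
  by marginal draws.  Both are conventional; neither is prescribed by the
  method.
* **Failure handling**: variables with a single observed category, or
  whose fit fails, fall back to marginal draws with a warning; collinear
  predictors are dropped with a warning.  Imputed categories are always a
  subset of the categories observed at the marker — a marker whose
  heterozygotes were all lost can therefore never recover them, and its
  pooled $\hat f$ is driven to 1.  This is a structural limitation of
  sample-based imputation, not a bug, and such markers are reported as
  skipped when the degenerate variance makes pooling undefined.

`convergenceTrace()` exposes the per-sweep $\hat f$ of the target for each
stream; flat, well-mixed traces across 10 sweeps (the default) indicate
convergence of the chained sampler.

# Pooling

`poolEstimates()` implements Rubin's rules exactly as stated in the
README: $\bar Q$, $\bar W$, $B$, $T = \bar W + (1 + 1/m)B$, relative
variance increase $r$, degrees of freedom $\nu = (m-1)(1+1/r)^2$, and
fraction of missing information $\lambda = (r + 2/(\nu+3))/(r+1)$, with
$\bar Q/\sqrt T$ referred to Student $t_\nu$.  When $B = 0$ the result
collapses to complete-data normal inference, so markers without missing
calls reproduce the complete-case Wald test exactly.  Within-imputation
variances are evaluated at the completed sample size — all individuals —
which is forced by the logic of multiple imputation (each completed copy
is a full data set).  The inbreeding coefficient is an intraclass
correlation, so `poolFisherZ()` optionally pools on the
$z = \operatorname{atanh} f$ scale with delta-method variances and
back-transforms; on real-scale examples the two scales agree to well
under 0.01 in $\hat f$, and the identity scale is the default.

# The synthetic test bed

No deposited genotype panel accompanies the method, so the package
carries a generator whose defaults emulate the study conditions, and all
simulation-based tests run on it.

* `genGenotypes()` draws markers from the $f$-parametrized trinomial.
  LD blocks use a two-haplotype-pool Markov chain: adjacent-locus
  haplotype frequencies are solved from the target $r^2$ and the MAFs,
  two independent haplotypes are summed per individual, giving per-locus
  HWP inside blocks and adjacent dosage $r^2$ within ±0.1 of target.
  This is far simpler than coalescent simulation and sufficient for
  covariate selection and imputation; it does not produce realistic decay
  of LD with distance, allele-frequency spectra, or recombination
  hotspots, so tests passing on it say nothing about those features of
  real panels.
* `genIntensities()` places three Gaussian clouds at (2, 0.2),
  (1.1, 1.1), (0.2, 2) with common sd 0.25 — separated clouds with
  shared boundary regions, as in array intensity plots — and multiplies
  each individual's signal by an attenuation factor
  $\exp(-|N(0, 0.35)|)$ representing sample-quality variation (dim
  samples).  The cluster geometry is invented: published intensity plots
  show the phenotype but not its parameters.  The defaults were fixed
  once, by checking that they reproduce the qualitative profile of real
  no-call diagnostics (a boundary-deletion regime at these defaults gives
  ≈35% missing calls, Hotelling rejection far above one half, and
  near-perfect linear-classifier recovery of genotype from intensities);
  they are not adjusted per analysis.
* `applyMissingness()` degrades a complete panel under MCAR (uniform),
  MNAR (per-genotype deletion probabilities — equal probabilities recover
  MCAR), or MAR from the intensity plane.  The MAR rule deletes with
  probability rising as the classification margin — the distance to the
  second-nearest cluster mean minus the distance to the nearest —
  shrinks.  A purely radial rule (distance to the nearest mean alone)
  was rejected at design time: with equal per-genotype deletion rates it
  is exactly mean-preserving for the missing group, so no intensity-mean
  diagnostic could ever detect it, contradicting what the diagnostics
  demonstrably do on real panels; the margin rule concentrates no-calls
  between the genotype clouds, which is the observed phenotype.
  `probs` is the margin width at 50% deletion; 0.55 is the canonical
  width used in the tests (≈35% missing at the default intensity
  geometry).

# Simulation harness and problem sizes

`runRegime()` compares discarding against MI by RMSE of $\hat f$ relative
to the *complete-data estimate* (not the generative $f$) over the markers
the regime actually degraded — both conventions follow from how such
deletion experiments are scored: markers without missings are unaffected
by either method, and the complete-data estimate is the recoverable
target.  `significanceReversalReport()` classifies each marker by the
two-test outcome (discard vs impute) and reports the reversal percentage.

Default problem sizes are desk scale, chosen so the full test suite and
the acceptance script run in minutes on one core while leaving
Monte-Carlo error well inside the asserted bands: panels of 150–400
individuals, replicate counts of 20 (paired-comparison properties),
300–500 (bias checks), and 1000 (type-I calibration, giving a 3σ band of
±0.021 around 0.05).  Known consequences of the scale: single-run
missing-information statistics ($r$, $\lambda$) have ≈20% relative
standard deviation at $m = 50$, so stochastic checks compare averages
over replicate runs, and published single-run values are matched only to
that tolerance.

# Limitations

* Reference-panel haplotype imputation (IMPUTE-class tools) is out of
  scope; where both apply, reference-panel methods exploit vastly more
  information and will beat sample-based MI on accuracy.
* Exact-test p-values are not pooled across imputations (the pooled test
  is Wald-type on $\hat f$); combining exact tests under MI is an open
  methods question.
* Multi-allelic markers, indels/CNVs, phased semantics and case/control
  stratification are not handled.
* Categories unobserved at a marker can never be imputed; very low MAF
  markers with lost heterozygotes are reported at the $f = 1$ boundary
  with undefined variance rather than silently corrected.
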