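---
title: "Variance-component analysis of genetic heterogeneity between disease subtypes"
author: "subtypeHerit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component analysis of genetic heterogeneity between disease subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtypeHerit)
```

## The scientific question

Clinically defined subtypes of a psychiatric disorder — here modelled on
bipolar disorder type I and type II — may share most of their common-variant
genetic architecture or may diverge substantially. Two quantities address
this with genotype data alone:

* the **SNP-based heritability** (SNP-h²) of each subtype — the proportion
  of liability variance attributable to the additive effects of genotyped
  SNPs, estimated by variance-component REML on a genetic relationship
  matrix (GRM); and
* the **genetic correlation** r_g between the subtypes — the correlation of
  per-SNP additive effects, estimated by a bivariate REML model fitted to
  two disjoint case groups, each paired with one half of a split control
  set.

A raw r_g below 1 is not by itself evidence of heterogeneity: sampling
noise, the boundary constraint at |r_g| ≤ 1 and cohort structure all
depress or inflate finite-sample estimates. The package therefore
implements a permutation contrast: the distribution of **subtype-pair**
estimates (r_g between the true BD I and BD II case groups, over repeated
control splits) is compared with the distribution of **mixed-pair**
estimates (r_g between two random halves of the pooled cases, sized like
the subtype groups, over repeated case splits nested in the same control
splits). Under a single shared architecture the two distributions
coincide; genuine subtype divergence pushes the subtype-pair distribution
below the mixed-pair one. A Welch t-test summarizes the difference.

## The generative model behind the simulator

Every analysis stage is exercised on cohorts from a two-subtype polygenic
liability-threshold simulator (`simConfig()`, `simulateCohort()`):

* Genotypes are unlinked biallelic autosomal SNPs in Hardy–Weinberg
  proportions; per-SNP allele frequencies are uniform on a configurable
  interval (default 0.05–0.5).
* A set of causal SNPs carries standardized effects (β₁ⱼ, β₂ⱼ) drawn
  bivariate normal with correlation ρ; each vector is rescaled so the
  genetic liability variance equals the subtype's liability-scale
  heritability exactly. The rescaling keeps truth values exact at any
  number of causal SNPs; its cost is a slightly smaller between-replicate
  spread of estimates than fully random effect draws would give.
* Liability for subtype k is the genetic value plus independent N(0, 1−h²ₖ)
  noise; an individual is a subtype-k case when liability k exceeds the
  threshold Φ⁻¹(1−Kₖ). An individual above both thresholds receives the
  subtype with the larger threshold exceedance — the subtypes are treated
  as mutually exclusive diagnoses, which is our construction; the clinical
  literature does not define a generative comorbidity rule.
* Case–control ascertainment draws the target numbers of each stratum
  without replacement and assigns site labels from configurable per-site
  weights, so site/subtype imbalance (and the 75% single-site exclusion
  rule) can be exercised.

Defaults mirror the epidemiology the package targets: prevalences 0.6%
and 0.4%, liability heritabilities 0.35 and 0.25, effect correlation 0.78.
Standardization of genotypes in the liability uses the *true* allele
frequencies, so simulated heritabilities are exact rather than
sample-frequency-dependent.

What the simulator deliberately omits: linkage disequilibrium (an optional
block-correlated mode exists solely to exercise LD pruning and index-SNP
selection), genotyping batch effects, realistic minor-allele-frequency
spectra, and population stratification beyond an optional two-population
Balding–Nichols divergence switch used for MDS testing. Passing tests
therefore demonstrate correctness of the estimators under their model
assumptions, not robustness to the artefacts of real genotype data.

## REML implementation

`fitGremlUnivariate()` fits y = Xβ + g + e with V = σ²g A + σ²e I. The GRM
is eigendecomposed once, after which every REML quantity (restricted
likelihood, gradients, average-information matrix) is O(n) per iteration.
The schedule is one EM step followed by average-information (AI) updates;
whenever a proposed direction fails to increase the restricted likelihood
the fitter halves the step, and if the AI direction is exhausted it falls
back to the EM and then to a scaled gradient direction before declaring a
(local) maximum. Variance components are kept non-negative by projection
onto a small positive floor (10⁻⁶ of the phenotypic variance).
Convergence is |Δ log-lik| < 10⁻⁶ (at most 100 iterations); standard
errors come from the inverse AI matrix and the heritability SE by the
delta method. Case–control status is fitted directly on the observed 0/1
scale and transformed afterwards.

`fitGremlBivariate()` stacks two traits measured on disjoint individuals;
the residual covariance is structurally zero, and
V = [[A₁₁σ²g1 + Iσ²e1, A₁₂σg12], [A₂₁σg12, A₂₂σ²g2 + Iσ²e2]]. The dense
fit computes the projection matrix explicitly per iteration (the
trace terms then reduce to elementwise products), which keeps each
iteration at one Cholesky factorization plus O(n²) work. Three
numerical safeguards matter in practice and are worth documenting:

* **Start values.** A Haseman–Elston moment regression (phenotype
  cross-products on relationship entries) provides the starting point; a
  neutral split of the phenotypic variance is also tried and the better
  restricted likelihood kept.
* **The coupled constraint.** The genetic correlation is bounded to
  [−1, 1] by clamping σg12 into ±√(σ²g1σ²g2). When a genetic variance is
  pinned at its floor this clamp also pins the covariance at zero, a trap
  the fitter escapes by deterministic restarts from interior points with
  non-zero covariance.
* **Boundary polish.** When the optimum lies on the |r_g| = 1 boundary the
  likelihood must be maximized *along* the constraint manifold
  σg12 = ±√(σ²g1σ²g2); the fitter switches to Newton steps in the reduced
  four-parameter space (chain rule on the AI matrix). Without this step
  boundary solutions stall short of the constrained optimum.

The tests verify, on tiny instances, that the fitted components match a
brute-force grid search of the restricted likelihood: parameters to the
grid resolution of 10⁻³ when the optimum is interior, and the restricted
likelihood itself at boundary optima, where the likelihood is flat along
the constraint manifold and the parameters are not individually
identified at that resolution.

## Liability transformation and subtype comparison

Observed-scale estimates are mapped to the liability scale by
h²_liab = h²_obs · [K(1−K)]² / [P(1−P)z²], with K the population
prevalence, P the sample case proportion and z the standard normal
density at the liability threshold; the SE scales by the same factor.
The transformation is linear in h²_obs and ignores the second-order
ascertainment corrections that matter chiefly for very large h² under
extreme ascertainment.

`compareH2()` tests the difference of two independent estimates with
z = (h²₁ − h²₂)/√(se₁² + se₂²) and a two-sided normal P. We document this
as a z-test: degrees of freedom are not defined for REML estimates and
the large-sample normal approximation is the standard reading of a
"t-test" on such estimates.

## The permutation contrast

`generateSplitPlans()` emits the full design: for each of
`n_control_perms` permutations the controls are split into two
evenly sized non-overlapping halves (sizes differing by at most one when
the count is odd); the subtype-pair plan pairs the fixed BD I and BD II
case groups with the two halves, and `n_case_splits` nested mixed-pair
plans re-split the pooled cases into groups of the same sizes. At the
reference design of 100 × 100 this yields exactly 100 subtype-pair and
10,000 mixed-pair fits. `estimateRgDistributions()` runs one bivariate
fit per plan, keeping (never silently dropping) non-converged fits, and
`compareRgDistributions()` applies a Welch two-sample t-test to the
converged estimates — Welch rather than pooled-variance, because the two
arms have very different sizes and spreads.

Two statistical caveats are intrinsic to this design and are documented
rather than corrected: constraint-at-1 censoring biases the mixed-pair
mean slightly below 1, and the estimates within each arm are positively
correlated (they share case groups and controls), so the t-test's
effective sample size is smaller than the nominal counts and its P-values
are anti-conservative. The package reports the test as specified;
reduced-scale calibration replicates in the test suite quantify how often
a null (shared-architecture) configuration yields small P-values.

The balance gatekeeper `checkSiteSubtypeBalance()` excludes any subtype
with more than 75% of its cases from a single site (strict inequality)
and flags any site whose contribution shares to the two compared subtypes
differ by more than a 3:1 ratio — the "grossly imbalanced" rule made
concrete; the ratio is a parameter because no published value exists.

## Quality control

`snpQCFilter()` applies, in order: SNP missingness > 5% (pass 1),
individual heterozygosity rate > 15% and missingness > 2%, SNP
missingness > 2% (pass 2), MAF < 1%, Hardy–Weinberg exact-test
P < 5×10⁻⁵, and case–control differential missingness (2×2 chi-square,
P < 10⁻³). Three concretizations deserve note: Hardy–Weinberg is tested
in controls only (standard case–control practice, to avoid removing true
associations); differential missingness uses a chi-square without
continuity correction; and the heterozygosity bound is an *absolute*
rate, as printed in the QC protocol this mirrors — an unusual rule that
only makes sense for low-MAF panels, which is why the threshold is
exposed as a parameter. The pipeline is idempotent and its report counts
telescope exactly.

The exact Hardy–Weinberg test enumerates all heterozygote counts
compatible with the allele counts and sums the probabilities of tables no
more probable than the observed one (with a 1+10⁻¹² tolerance on the
comparison to absorb rounding). LD pruning computes variance inflation
factors from the inverse correlation matrix within sliding windows
(window 100, shift 50, VIF ≤ 2 by default) and removes the worst SNP
until the window passes. Ancestry structure uses classical MDS on 1−IBS
distances; outliers are individuals more than 6 SD from the mean on any
of the ten leading components — the "6 SD" rule is our concretization of
an unspecified outlier procedure. Relatedness uses PLINK-style
method-of-moments IBD estimation (PIHAT = P(IBD=2) + P(IBD=1)/2) with
greedy removal of the higher-missingness member of each flagged pair.

A separate GRM-based prune bounds pairwise genome-wide similarity at
0.05. That cutoff presumes genome-wide SNP counts: the null SD of a GRM
off-diagonal entry is 1/√m, so at the desk scales used here
(m ≈ 10³ SNPs) a 0.05 bound would flag most random pairs. Simulated desk-
scale analyses therefore run the prune with a cutoff on the same null
quantile (several multiples of 1/√m) or on clean cohorts where it is a
no-op; the default remains 0.05 for genome-wide data.

## Association, meta-analysis, sign test and polygenic scores

Per-cohort scans are per-SNP logistic regressions (Wald tests) of status
on A1-allele dosage plus covariates; a batched Newton solver handles the
covariate-free complete-data case and is verified against the per-SNP GLM
fit. Monomorphic and separated SNPs are flagged NA with reason codes.
Fixed-effects meta-analysis pools log-odds with inverse-variance weights
after aligning allele orientations (flipping swapped alleles, dropping
strand-ambiguous A/T and C/G SNPs) and reports Cochran's Q with k−1
degrees of freedom. The genomic inflation factor is the median
association chi-square over the null median 0.4549. Index SNPs are
selected greedily (most significant first, removing neighbours within
500 kb with r² > 0.1 — both parameters exposed, since the source protocol
names none). The sign test counts direction concordance of aligned index
SNPs in an independent cohort against a two-sided exact binomial null of
0.5, at thresholds 10⁻³, 10⁻⁴, 10⁻⁵, 10⁻⁶.

Polygenic scores sum effect-weighted dosages over discovery SNPs below
each P-value threshold (default grid 0.001–1.0), after the same allele
harmonization; missing dosages are mean-imputed as twice the allele
frequency. Log-odds weighting is the default, with a unit-weight mode
for pure risk-allele counting. Score–phenotype association is a logistic
regression with covariates; the reported effect is the score
coefficient's t-statistic (coefficient over SE) and the incremental
Nagelkerke R² over covariates alone, computed from the full-likelihood
definition with the intercept-only model as baseline.

## Problem sizes used by the test suite

The acceptance checks run, on one CPU, at these scales (chosen as the
package's reference desk scales): REML oracle equivalence on 20
univariate instances (n ≤ 60, m ≤ 100) and 5 bivariate instances
(n = 40+40, m = 60); parameter recovery at n = 2000, m = 5000 with 20
replicates per heritability value; the permutation contrast at a 10 × 10
design with roughly 1,200 individuals per bivariate fit (ρ = 0.7), with
ten reduced-size 10 × 10 replicates for the ρ = 1 calibration; the full
100 × 100 split-plan bookkeeping at the reference cohort sizes
(2811/1398 cases, 11,164 controls); and a 50,000-SNP null scan at
n = 2000 for inflation and type-I calibration.

## Known limitations

* The liability transformation omits higher-order ascertainment
  corrections; under extreme ascertainment with large h² it can be
  conservative.
* The Welch t-test on the permutation arms inherits the dependence
  structure of the design (shared cases and controls across estimates);
  its P-values overstate evidence, as the calibration replicates show.
  The contrast's direction and effect size are the robust summaries.
* GRM-based analyses here are dense and suited to n up to a few
  thousand; no sparse or out-of-core path is provided.
* The simulator's unlinked SNPs make "SNPs tag all causal variants" true
  by construction; real-data SNP-h² is bounded by imperfect tagging.
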