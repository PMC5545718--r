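# subtypeHerit

Variance-component analysis of genetic heterogeneity between subtypes of
a complex disease, modelled on the bipolar disorder type I / type II
question: do two clinically defined subtypes share their common-variant
genetic architecture?

The package is for statistical geneticists who want the complete
analysis chain as testable R functions rather than a collection of
external binaries: SNP-based heritability and bivariate genetic
correlation by GREML, the control-splitting/case-mixing permutation
contrast that turns a raw genetic correlation into a calibrated
comparison, and the supporting QC, GWAS/meta-analysis, sign-test and
polygenic-scoring machinery. A two-subtype liability-threshold cohort
simulator makes every stage runnable and testable without access to any
human genotype data.

## The statistics at the core

* **SNP-h²** — fit y = Xβ + g + e with Var(y) = σ²g·A + σ²e·I by
  restricted maximum likelihood (one EM step, then average-information
  updates), where A is the genetic relationship matrix
  A_jk = (1/m)·Σᵢ (xᵢⱼ−2pᵢ)(xᵢₖ−2pᵢ)/(2pᵢqᵢ). The observed-scale
  h²_obs = σ²g/(σ²g+σ²e) is mapped to the liability scale by
  h²_liab = h²_obs·[K(1−K)]²/[P(1−P)z²] with K the population
  prevalence, P the sample case proportion, z = φ(Φ⁻¹(1−K)).
* **r_g** — a bivariate GREML model on two *disjoint* case groups, each
  paired with one half of a split control set; the genetic correlation
  is σg12/√(σ²g1·σ²g2), constrained to [−1, 1].
* **The permutation contrast** — r_g between the true subtype case
  groups, repeated over random control splits (*subtype-pair*
  distribution), against r_g between random re-splits of the pooled
  cases at the same group sizes (*mixed-pair* distribution, 100 case
  splits nested in each control split). Under a shared architecture the
  distributions coincide; genuine heterogeneity pushes the subtype-pair
  distribution down. A Welch t-test summarizes the difference.

## Worked example

Simulate an ascertained two-subtype cohort whose causal effects are
correlated at ρ = 0.7, estimate each subtype's liability-scale SNP-h²,
and run a reduced 4 × 4 permutation contrast:

```r
library(subtypeHerit)

cfg <- simConfig(nIndividuals = 40000, nSnps = 600, nCausal = 300,
                 h2Liab1 = 0.35, h2Liab2 = 0.25, rhoEffects = 0.7,
                 prevalence1 = 0.006, prevalence2 = 0.004,
                 targetCases1 = 160, targetCases2 = 110,
                 targetControls = 330, nSites = 2, seed = 7)
coh <- simulateCohort(cfg)
grm <- computeGRM(coh$genotypes)
ph  <- coh$phenotypes

# SNP-h2 for subtype 1 (cases of subtype BD1 vs all controls)
sel <- ph$subtype == "BD1" | ph$status == "control"
y   <- setNames(as.integer(ph$status[sel] == "case"), ph$sample_id[sel])
vc  <- fitGremlUnivariate(grm, y)
h   <- h2Observed(vc)
liabilityTransform(h$estimate, h$se, prevalence_K = 0.006,
                   case_proportion_P = mean(y))
#> SNP heritability estimate
#>   observed scale : 0.4318 (se 0.0673)
#>   liability scale: 0.2416 (se 0.0376)  [K=0.006, P=0.3265]

# permutation contrast: subtype-pair vs mixed-pair genetic correlations
plans <- generateSplitPlans(ph, n_control_perms = 4, n_case_splits = 4,
                            seed = 8)
dist  <- estimateRgDistributions(ph, plans, grm)
cmp   <- compareRgDistributions(dist)
cmp$summary
#>          arm  n n_converged      mean        sd       min max
#> 1 rg_subtype  4           4 0.7717197 0.2443237 0.5569125   1
#> 2     rg_mix 16          16 0.9312019 0.1180570 0.6534650   1
cmp$p_two_sided
#> [1] 0.2852627
```

The subtype-pair genetic correlations centre near the simulated effect
correlation of 0.7 while the mixed-pair estimates pile up near 1: mixing
the case groups erases the subtype distinction, so the gap between the
two distributions — not the raw r_g alone — is the evidence for genetic
heterogeneity. A cohort this small is deliberately noisy: the
liability-scale SNP-h² of 0.24 (se 0.04) sits below the simulated 0.35
by about three standard errors, and the 4 × 4 contrast shows the right
ordering without significance (p ≈ 0.29). The test suite runs the full
designs — 20-replicate recovery at n = 2000 / m = 5000 for unbiasedness
of the heritability estimator, and the 10 × 10 contrast at ~1,200
individuals per fit, where the same configuration gives subtype-pair
mean 0.80, mixed-pair mean 0.93 and Welch p ≈ 8 × 10⁻⁶.

Every stage can also be driven end to end from one configuration:

```r
runPipeline(list(sim = cfg, seed = 7, out_dir = "run1",
                 analysis = list(n_control_perms = 4, n_case_splits = 4,
                                 grm_cutoff = 0.6)))
```

which writes the QC report, GRM (GCTA-compatible text), per-site
association scans with a fixed-effects meta-analysis, the r_g estimate
vectors and a JSON manifest under `run1/`.

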