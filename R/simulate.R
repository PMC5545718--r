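# Liability-threshold cohort simulator: unlinked biallelic autosomal SNPs at
# Hardy-Weinberg proportions, two disease subtypes whose per-SNP causal
# effects are drawn bivariate normal with a configurable correlation, and
# case-control ascertainment to target counts across sites.

#' Simulation configuration
#'
#' Bundles the generative parameters of the two-subtype liability-threshold
#' cohort model. Defaults reflect the epidemiology and architecture the
#' package targets: lifetime prevalences of 0.6% and 0.4% for the two
#' subtypes, liability-scale SNP heritabilities of 0.35 and 0.25, and a
#' between-subtype effect correlation of 0.78.
#'
#' @param nIndividuals population size before ascertainment.
#' @param nSnps number of unlinked biallelic autosomal SNPs.
#' @param mafRange length-2 vector in (0, 0.5]; per-SNP allele frequencies
#'   are drawn uniformly from this interval.
#' @param nCausal number of causal SNPs (must be <= `nSnps`, and >= 2
#'   whenever `rhoEffects != 1`).
#' @param h2Liab1,h2Liab2 liability-scale heritabilities per subtype, in
#'   \[0, 1\].
#' @param rhoEffects correlation of per-SNP causal effects between the two
#'   subtype liabilities, in \[-1, 1\].
#' @param prevalence1,prevalence2 population prevalences in (0, 1) with
#'   `prevalence1 + prevalence2 < 1`.
#' @param targetCases1,targetCases2,targetControls ascertainment targets.
#' @param nSites number of collection sites.
#' @param siteMixing optional `nSites` x 3 matrix of sampling weights with
#'   columns (subtype-1 cases, subtype-2 cases, controls); default uniform.
#' @param ldBlockSize optional SNP-count block size for the block-correlated
#'   genotype mode (used only to exercise LD pruning / index-SNP selection).
#' @param ldRho within-block haplotype correlation for the LD mode.
#' @param popDivergence optional list(frac, fst): a fraction of individuals
#'   drawn from a second population with Balding-Nichols allele-frequency
#'   divergence, for MDS/ancestry testing.
#' @param seed integer seed; every stochastic operation derives its stream
#'   from it.
#' @return a validated list of class `SimulationConfig`.
#' @export
simConfig <- function(nIndividuals = 10000L, nSnps = 1000L,
                      mafRange = c(0.05, 0.5), nCausal = 500L,
                      h2Liab1 = 0.35, h2Liab2 = 0.25, rhoEffects = 0.78,
                      prevalence1 = 0.006, prevalence2 = 0.004,
                      targetCases1 = 250L, targetCases2 = 250L,
                      targetControls = 500L, nSites = 2L,
                      siteMixing = NULL, ldBlockSize = NULL, ldRho = 0,
                      popDivergence = NULL, seed = 1L) {
  stopifnot(nIndividuals >= 1, nSnps >= 1)
  if (length(mafRange) != 2 || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("mafRange must lie within (0, 0.5]")
  if (nCausal > nSnps) stop("nCausal must be <= nSnps")
  if (abs(rhoEffects) > 1) stop("rhoEffects must be in [-1, 1]")
  if (rhoEffects != 1 && nCausal < 2)
    stop("nCausal must be >= 2 when rhoEffects != 1")
  stopifnot(h2Liab1 >= 0, h2Liab1 <= 1, h2Liab2 >= 0, h2Liab2 <= 1)
  if (prevalence1 <= 0 || prevalence1 >= 1 || prevalence2 <= 0 ||
      prevalence2 >= 1 || prevalence1 + prevalence2 >= 1)
    stop("prevalences must lie in (0, 1) and sum to < 1")
  # Achievability check: expected stratum counts must comfortably cover the
  # ascertainment targets (3 binomial SDs of slack).
  for (k in 1:2) {
    K <- c(prevalence1, prevalence2)[k]
    tgt <- c(targetCases1, targetCases2)[k]
    mu <- nIndividuals * K
    if (tgt > 0 && tgt > mu - 3 * sqrt(mu * (1 - K)))
      stop(sprintf("target of %d subtype-%d cases unlikely at prevalence %g in a population of %d",
                   tgt, k, K, nIndividuals))
  }
  if (targetControls > nIndividuals * (1 - prevalence1 - prevalence2) * 0.9)
    stop("targetControls too large for the population")
  if (is.null(siteMixing)) {
    siteMixing <- matrix(1, nSites, 3)
  }
  if (!is.matrix(siteMixing) || nrow(siteMixing) != nSites ||
      ncol(siteMixing) != 3 || any(siteMixing < 0))
    stop("siteMixing must be a non-negative nSites x 3 matrix")
  structure(list(
    nIndividuals = as.integer(nIndividuals), nSnps = as.integer(nSnps),
    mafRange = mafRange, nCausal = as.integer(nCausal),
    h2Liab1 = h2Liab1, h2Liab2 = h2Liab2, rhoEffects = rhoEffects,
    prevalence1 = prevalence1, prevalence2 = prevalence2,
    targetCases1 = as.integer(targetCases1),
    targetCases2 = as.integer(targetCases2),
    targetControls = as.integer(targetControls),
    nSites = as.integer(nSites), siteMixing = siteMixing,
    ldBlockSize = ldBlockSize, ldRho = ldRho,
    popDivergence = popDivergence, seed = as.integer(seed)),
    class = "SimulationConfig")
}

# Spread m SNPs over 22 autosomes with non-decreasing positions.
.snp_map <- function(m) {
  chr <- rep(1:22, length.out = m)
  chr <- sort(chr)
  pos <- integer(m)
  for (c in unique(chr)) {
    idx <- which(chr == c)
    pos[idx] <- seq_along(idx) * 10000L
  }
  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2,
                  byrow = TRUE)
  pick <- ((seq_len(m) - 1L) %% 4L) + 1L
  data.frame(id = sprintf("snp%06d", seq_len(m)), chr = chr, pos = pos,
             A1 = pairs[pick, 1], A2 = pairs[pick, 2],
             stringsAsFactors = FALSE)
}

#' Simulate genotypes at Hardy-Weinberg proportions
#'
#' Each SNP's allele frequency is drawn uniformly from `mafRange`; dosages
#' are sums of two independent Bernoulli draws (HWE). With `ldBlockSize`
#' set, haplotype alleles within a block share a latent Gaussian factor of
#' correlation `ldRho`, yielding positively correlated SNPs for pruning
#' tests. With `popDivergence`, a trailing fraction of individuals is drawn
#' from a Balding-Nichols divergent population.
#'
#' @param config a [simConfig()] object.
#' @return a [GenotypeData-class]; the true allele frequency of each SNP is
#'   kept in `snpInfo(x)$freq_true` and simulated-population membership (if
#'   any) in the sample table.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$nIndividuals; m <- config$nSnps
  withr::with_seed(config$seed, {
    p <- runif(m, config$mafRange[1], config$mafRange[2])
    pop <- rep(1L, n)
    p2 <- NULL
    if (!is.null(config$popDivergence)) {
      fst <- config$popDivergence$fst
      n2 <- round(n * config$popDivergence$frac)
      pop[seq_len(n2) + (n - n2)] <- 2L
      a <- p * (1 - fst) / fst
      b <- (1 - p) * (1 - fst) / fst
      p2 <- stats::rbeta(m, a, b)
    }
    if (is.null(config$ldBlockSize)) {
      X <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
      if (!is.null(p2)) {
        i2 <- which(pop == 2L)
        X[i2, ] <- matrix(rbinom(length(i2) * m, 2L, rep(p2, each = length(i2))),
                          length(i2), m)
      }
    } else {
      bs <- config$ldBlockSize
      block <- ceiling(seq_len(m) / bs)
      rho <- config$ldRho
      thr <- qnorm(p)  # latent < thr => A1 allele
      hap <- function() {
        Z <- matrix(0, n, m)
        for (b in unique(block)) {
          idx <- which(block == b)
          f <- rnorm(n)
          Z[, idx] <- sqrt(rho) * f +
            sqrt(1 - rho) * matrix(rnorm(n * length(idx)), n)
        }
        t(t(Z) < thr) + 0L
      }
      X <- hap() + hap()
    }
  })
  snps <- .snp_map(m)
  snps$freq_true <- p
  samples <- data.frame(sample_id = sprintf("ind%06d", seq_len(n)),
                        population = pop, stringsAsFactors = FALSE)
  GenotypeData(X, snps, samples)
}

#' Simulate correlated subtype causal effects
#'
#' Per causal SNP, the two standardized effects are drawn bivariate normal
#' with correlation `rhoEffects`; each effect vector is then rescaled so the
#' genetic liability variance (over standardized genotypes at the true
#' allele frequencies) equals the configured liability heritability.
#'
#' @param config a [simConfig()] object.
#' @param genotypes the matching [GenotypeData-class].
#' @return list with `causal_indices`, `beta_1`, `beta_2`.
#' @export
simulateSubtypeEffects <- function(config, genotypes) {
  stopifnot(inherits(config, "SimulationConfig"))
  m <- nSnps(genotypes)
  if (config$nCausal > m) stop("nCausal exceeds available SNPs")
  withr::with_seed(config$seed + 1L, {
    causal <- sort(sample.int(m, config$nCausal))
    z1 <- rnorm(config$nCausal)
    rho <- config$rhoEffects
    z2 <- rho * z1 + sqrt(1 - min(rho^2, 1)) * rnorm(config$nCausal)
  })
  rescale <- function(z, h2) {
    if (h2 == 0) return(numeric(length(z)))
    z * sqrt(h2 / sum(z^2))
  }
  list(causal_indices = causal,
       beta_1 = rescale(z1, config$h2Liab1),
       beta_2 = rescale(z2, config$h2Liab2))
}

# genetic liability values from standardized genotypes at true frequencies
.genetic_values <- function(genotypes, effects) {
  p <- snpInfo(genotypes)$freq_true
  if (is.null(p)) stop("genotypes carry no true allele frequencies")
  idx <- effects$causal_indices
  X <- dosages(genotypes)[, idx, drop = FALSE]
  sdv <- sqrt(2 * p[idx] * (1 - p[idx]))
  Xs <- sweep(X, 2, 2 * p[idx], "-")
  Xs <- sweep(Xs, 2, sdv, "/")
  list(g1 = drop(Xs %*% effects$beta_1), g2 = drop(Xs %*% effects$beta_2))
}

#' Assign liability-threshold phenotypes
#'
#' Liability for subtype k is the genetic value plus independent normal
#' noise of variance 1 - h2_k; an individual is a subtype-k case if the
#' liability exceeds the threshold `qnorm(1 - prevalence_k)`. Individuals
#' exceeding both thresholds are assigned the subtype with the larger
#' threshold exceedance (the subtypes are mutually exclusive diagnoses);
#' controls fall below both.
#'
#' @param genotypes a [GenotypeData-class] with true allele frequencies.
#' @param effects output of [simulateSubtypeEffects()].
#' @param config a [simConfig()] object.
#' @return phenotype data.frame: `sample_id`, `status` ("case"/"control"),
#'   `subtype` ("BD1"/"BD2"/"none"), `site` (NA until ascertainment),
#'   liabilities and true genetic values per subtype.
#' @export
assignLiabilityPhenotypes <- function(genotypes, effects, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  g <- .genetic_values(genotypes, effects)
  n <- nSamples(genotypes)
  withr::with_seed(config$seed + 2L, {
    e1 <- rnorm(n, 0, sqrt(1 - config$h2Liab1))
    e2 <- rnorm(n, 0, sqrt(1 - config$h2Liab2))
  })
  l1 <- g$g1 + e1
  l2 <- g$g2 + e2
  t1 <- qnorm(1 - config$prevalence1)
  t2 <- qnorm(1 - config$prevalence2)
  exc1 <- l1 - t1; exc2 <- l2 - t2
  subtype <- rep("none", n)
  subtype[exc1 > 0 & exc1 >= exc2] <- "BD1"
  subtype[exc2 > 0 & exc2 > exc1] <- "BD2"
  data.frame(sample_id = sampleIds(genotypes),
             status = ifelse(subtype == "none", "control", "case"),
             subtype = subtype, site = NA_character_,
             liability_1 = l1, liability_2 = l2,
             genetic_1 = g$g1, genetic_2 = g$g2,
             stringsAsFactors = FALSE)
}

#' Ascertain a case-control cohort from a simulated population
#'
#' Samples the target numbers of subtype-1 cases, subtype-2 cases and
#' controls without replacement and assigns site labels according to the
#' per-stratum site-mixing weights.
#'
#' @param population phenotype table from [assignLiabilityPhenotypes()].
#' @param genotypes the matching population [GenotypeData-class].
#' @param config a [simConfig()] object.
#' @return list with elements `genotypes` and `phenotypes`, row-aligned.
#' @export
ascertainCohort <- function(population, genotypes, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  strata <- list(BD1 = which(population$subtype == "BD1"),
                 BD2 = which(population$subtype == "BD2"),
                 control = which(population$status == "control"))
  targets <- c(config$targetCases1, config$targetCases2,
               config$targetControls)
  for (k in 1:3) {
    if (length(strata[[k]]) < targets[k])
      stop(sprintf("insufficient individuals in stratum %s: have %d, need %d",
                   names(strata)[k], length(strata[[k]]), targets[k]))
  }
  withr::with_seed(config$seed + 3L, {
    pick <- unlist(lapply(1:3, function(k) {
      if (targets[k] == 0) integer(0)
      else sample(strata[[k]], targets[k])
    }))
    site <- unlist(lapply(1:3, function(k) {
      if (targets[k] == 0) return(character(0))
      w <- config$siteMixing[, k]
      sample(sprintf("site%02d", seq_len(config$nSites)), targets[k],
             replace = TRUE, prob = w / sum(w))
    }))
  })
  pheno <- population[pick, , drop = FALSE]
  pheno$site <- site
  rownames(pheno) <- NULL
  list(genotypes = genotypes[pick, ], phenotypes = pheno)
}

#' Simulate a full ascertained cohort
#'
#' Convenience wrapper chaining genotype simulation, effect simulation,
#' liability phenotype assignment and ascertainment.
#'
#' @param config a [simConfig()] object.
#' @param keepPopulation keep the population-level phenotype table (and
#'   population case fractions) for diagnostics.
#' @return list with `genotypes`, `phenotypes`, `effects` and (optionally)
#'   `population`.
#' @export
simulateCohort <- function(config, keepPopulation = FALSE) {
  geno <- simulateGenotypes(config)
  eff <- simulateSubtypeEffects(config, geno)
  pop <- assignLiabilityPhenotypes(geno, eff, config)
  cohort <- ascertainCohort(pop, geno, config)
  out <- list(genotypes = cohort$genotypes, phenotypes = cohort$phenotypes,
              effects = eff)
  if (keepPopulation) out$population <- pop
  out
}

#' Inject missing genotype calls
#'
#' Corruption helper for QC fixtures: sets calls to missing at the given
#' per-SNP and/or per-individual rates. Clean data by default -- the
#' simulator itself never produces missingness.
#'
#' @param genotypes a [GenotypeData-class].
#' @param snpRates scalar or per-SNP vector of missingness probabilities.
#' @param sampleRates scalar or per-individual vector.
#' @param seed integer seed.
#' @return the corrupted [GenotypeData-class].
#' @export
injectMissingness <- function(genotypes, snpRates = 0, sampleRates = 0,
                              seed = 1L) {
  d <- dosages(genotypes)
  n <- nrow(d); m <- ncol(d)
  snpRates <- rep_len(snpRates, m)
  sampleRates <- rep_len(sampleRates, n)
  pr <- 1 - outer(1 - sampleRates, 1 - snpRates)  # union of the two events
  withr::with_seed(seed, {
    d[matrix(runif(n * m), n, m) < pr] <- NA
  })
  GenotypeData(d, snpInfo(genotypes), genotypes@samples)
}

#' Attach imputation-quality metadata
#'
#' @param genotypes a [GenotypeData-class].
#' @param infoScore per-SNP imputation quality (INFO) scores.
#' @param imputationR2 optional per-SNP imputation R2 values.
#' @return the annotated [GenotypeData-class].
#' @export
setImputationQuality <- function(genotypes, infoScore, imputationR2 = NULL) {
  snps <- snpInfo(genotypes)
  snps$info_score <- rep_len(infoScore, nrow(snps))
  if (!is.null(imputationR2))
    snps$imputation_r2 <- rep_len(imputationR2, nrow(snps))
  GenotypeData(dosages(genotypes), snps, genotypes@samples)
}
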