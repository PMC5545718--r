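# The liability-threshold cohort generator: HWE genotype proportions,
# correlated subtype effects, threshold phenotypes and ascertainment.

test_that("genotypes follow HWE proportions and are reproducible", {
  cfg <- simConfig(nIndividuals = 4000, nSnps = 20, mafRange = c(0.5, 0.5),
                   nCausal = 10, targetCases1 = 0, targetCases2 = 0,
                   targetControls = 10, seed = 42)
  g <- simulateGenotypes(cfg)
  tab <- table(factor(dosages(g), levels = 0:2)) / (4000 * 20)
  expect_equal(as.numeric(tab), c(0.25, 0.5, 0.25), tolerance = 0.02)

  g2 <- simulateGenotypes(cfg)
  expect_identical(dosages(g), dosages(g2))

  cfg2 <- simConfig(nIndividuals = 20000, nSnps = 200,
                    mafRange = c(0.05, 0.5), nCausal = 10,
                    targetCases1 = 0, targetCases2 = 0, targetControls = 10,
                    seed = 7)
  g3 <- simulateGenotypes(cfg2)
  emp <- colMeans(dosages(g3)) / 2
  expect_lt(max(abs(emp - snpInfo(g3)$freq_true)), 0.01)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(simConfig(nCausal = 2000, nSnps = 1000), "nCausal")
  expect_error(simConfig(rhoEffects = 1.2), "rhoEffects")
  expect_error(simConfig(prevalence1 = 0.7, prevalence2 = 0.5), "prevalence")
  expect_error(simConfig(nIndividuals = 1000, targetCases1 = 500),
               "unlikely")
})

test_that("subtype effects have the requested correlation and scale", {
  cfg <- simConfig(nIndividuals = 100, nSnps = 6000, nCausal = 5000,
                   h2Liab1 = 0.4, h2Liab2 = 0.4, rhoEffects = 0,
                   targetCases1 = 0, targetCases2 = 0, targetControls = 1,
                   seed = 3)
  g <- simulateGenotypes(cfg)
  eff <- simulateSubtypeEffects(cfg, g)
  expect_lt(abs(cor(eff$beta_1, eff$beta_2)), 0.03)
  expect_equal(sum(eff$beta_1^2), 0.4, tolerance = 1e-12)

  cfg1 <- simConfig(nIndividuals = 100, nSnps = 200, nCausal = 50,
                    h2Liab1 = 0.3, h2Liab2 = 0.3, rhoEffects = 1,
                    targetCases1 = 0, targetCases2 = 0, targetControls = 1,
                    seed = 4)
  g1 <- simulateGenotypes(cfg1)
  eff1 <- simulateSubtypeEffects(cfg1, g1)
  expect_equal(eff1$beta_1, eff1$beta_2)

  cfg0 <- simConfig(nIndividuals = 100, nSnps = 200, nCausal = 50,
                    h2Liab1 = 0, h2Liab2 = 0.3, rhoEffects = 0.5,
                    targetCases1 = 0, targetCases2 = 0, targetControls = 1,
                    seed = 5)
  eff0 <- simulateSubtypeEffects(cfg0, simulateGenotypes(cfg0))
  expect_true(all(eff0$beta_1 == 0))
})

test_that("population case fractions match the configured prevalences", {
  cfg <- simConfig(nIndividuals = 100000, nSnps = 300, nCausal = 150,
                   prevalence1 = 0.006, prevalence2 = 0.004,
                   targetCases1 = 100, targetCases2 = 100,
                   targetControls = 500, seed = 11)
  g <- simulateGenotypes(cfg)
  eff <- simulateSubtypeEffects(cfg, g)
  ph <- assignLiabilityPhenotypes(g, eff, cfg)
  n1 <- sum(ph$subtype == "BD1"); n2 <- sum(ph$subtype == "BD2")
  expect_lt(abs(n1 - 600), 3 * sqrt(100000 * 0.006 * 0.994))
  expect_lt(abs(n2 - 400), 3 * sqrt(100000 * 0.004 * 0.996))
  expect_true(all((ph$subtype == "none") == (ph$status == "control")))
})

test_that("liability regresses on the true genetic score with unit slope", {
  cfg <- simConfig(nIndividuals = 50000, nSnps = 400, nCausal = 300,
                   h2Liab1 = 0.35, h2Liab2 = 0.25, rhoEffects = 0.78,
                   targetCases1 = 100, targetCases2 = 50,
                   targetControls = 100, seed = 13)
  g <- simulateGenotypes(cfg)
  eff <- simulateSubtypeEffects(cfg, g)
  ph <- assignLiabilityPhenotypes(g, eff, cfg)
  fit <- lm(ph$liability_1 ~ ph$genetic_1)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_equal(summary(fit)$r.squared, 0.35, tolerance = 0.02)
  # correlation of the two genetic scores tracks the effect correlation
  expect_equal(cor(ph$genetic_1, ph$genetic_2), 0.78, tolerance = 0.05)
})

test_that("ascertainment honours targets, sites and determinism", {
  cfg <- simConfig(nIndividuals = 30000, nSnps = 100, nCausal = 50,
                   prevalence1 = 0.02, prevalence2 = 0.015,
                   targetCases1 = 150, targetCases2 = 100,
                   targetControls = 400, nSites = 3, seed = 17)
  g <- simulateGenotypes(cfg)
  eff <- simulateSubtypeEffects(cfg, g)
  pop <- assignLiabilityPhenotypes(g, eff, cfg)
  coh <- ascertainCohort(pop, g, cfg)
  expect_equal(as.integer(table(coh$phenotypes$subtype)[c("BD1", "BD2")]),
               c(150L, 100L))
  expect_equal(sum(coh$phenotypes$status == "control"), 400)
  expect_identical(sampleIds(coh$genotypes), coh$phenotypes$sample_id)
  expect_equal(sort(unique(coh$phenotypes$site)),
               c("site01", "site02", "site03"))
  # same seed -> same cohort
  coh2 <- ascertainCohort(pop, g, cfg)
  expect_identical(coh$phenotypes$sample_id, coh2$phenotypes$sample_id)
  # control allele frequencies match the population within sampling error
  ctrl <- coh$genotypes[which(coh$phenotypes$status == "control"), ]
  dp <- abs(colMeans(dosages(ctrl)) / 2 - colMeans(dosages(g)) / 2)
  expect_lt(max(dp), 4 * sqrt(0.5 * 0.5 / (2 * 400)))

  cfg0 <- cfg; cfg0$targetCases1 <- 0L; cfg0$targetCases2 <- 0L
  cfg0$targetControls <- 100L
  coh0 <- ascertainCohort(pop, g, cfg0)
  expect_true(all(coh0$phenotypes$status == "control"))
  cfgbad <- cfg; cfgbad$targetCases1 <- 100000L
  expect_error(ascertainCohort(pop, g, cfgbad), "insufficient")
})

test_that("missingness injection and imputation metadata behave", {
  g <- make_hwe_geno(200, rep(0.3, 50), seed = 2)
  gm <- injectMissingness(g, snpRates = 0.5, seed = 3)
  miss <- colMeans(is.na(dosages(gm)))
  expect_gt(mean(miss), 0.4); expect_lt(mean(miss), 0.6)
  gi <- setImputationQuality(g, infoScore = runif(50), imputationR2 = 0.9)
  expect_equal(length(snpInfo(gi)$info_score), 50)
  expect_true(all(snpInfo(gi)$imputation_r2 == 0.9))
})
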