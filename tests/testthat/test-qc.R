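# Quality control: threshold semantics, exact HWE test, VIF pruning,
# telescoping reports and idempotence.

make_pheno <- function(geno, n_cases) {
  n <- nSamples(geno)
  data.frame(sample_id = sampleIds(geno),
             status = rep(c("case", "control"), c(n_cases, n - n_cases)),
             subtype = rep(c("BD1", "none"), c(n_cases, n - n_cases)),
             site = "site01", stringsAsFactors = FALSE)
}

test_that("SNP missingness passes remove exactly the offenders", {
  withr::with_seed(8, {
    d <- matrix(rbinom(200 * 5, 2, 0.3), 200, 5)
  })
  rates <- c(0, 0.01, 0.03, 0.06, 0.10)
  for (j in 1:5) if (rates[j] > 0)
    d[seq_len(round(200 * rates[j])), j] <- NA
  g <- make_geno(d)
  ph <- make_pheno(g, 100)
  th <- qcThresholds(indiv_missing_max = 1, indiv_het_max = 1,
                     maf_min = 0, hwe_p_min = 0, diff_missing_p_min = 0,
                     snp_missing_pass2 = 1)
  res <- snpQCFilter(g, ph, th)
  expect_equal(nSnps(res$genotypes), 3)
  expect_setequal(attr(res$report, "removed")$snp_missingness_pass1,
                  c("s0004", "s0005"))
})

test_that("MAF filtering respects the 1% boundary", {
  n <- 1000
  d <- cbind(rep(c(1, 0), c(18, n - 18)),   # MAF 0.009
             rep(c(1, 0), c(22, n - 22)),   # MAF 0.011
             rbinom(n, 2, 0.3))
  g <- make_geno(d)
  ph <- make_pheno(g, 0)
  th <- qcThresholds(indiv_het_max = 1, hwe_p_min = 0,
                     diff_missing_p_min = 0)
  res <- snpQCFilter(g, ph, th)
  expect_identical(snpInfo(res$genotypes)$id, c("s0002", "s0003"))
  expect_equal(attr(res$report, "removed")$maf, "s0001")
})

test_that("differential missingness removes case-biased SNPs", {
  withr::with_seed(9, d <- matrix(rbinom(1000 * 3, 2, 0.4), 1000, 3))
  d[1:50, 2] <- NA                       # missing in 10% of the 500 cases
  g <- make_geno(d)
  ph <- make_pheno(g, 500)
  th <- qcThresholds(indiv_het_max = 1, indiv_missing_max = 1,
                     hwe_p_min = 0, snp_missing_pass1 = 1,
                     snp_missing_pass2 = 1)
  res <- snpQCFilter(g, ph, th)
  expect_equal(attr(res$report, "removed")$differential_missingness,
               "s0002")
  # oracle: two-proportion chi-square
  p_or <- chisq.test(matrix(c(50, 450, 0, 500), 2), correct = FALSE)$p.value
  expect_lt(p_or, 1e-3)
})

test_that("individual QC applies the heterozygosity and missingness rules", {
  withr::with_seed(10, d <- matrix(rbinom(100 * 400, 2, 0.05), 100, 400))
  d[1, ] <- 1                            # het rate 1.0
  d[2, 1:20] <- NA                       # missingness 5%
  g <- make_geno(d)
  res <- individualQCFilter(g, qcThresholds())
  ids <- sampleIds(g)
  expect_false(ids[1] %in% sampleIds(res$genotypes))
  expect_false(ids[2] %in% sampleIds(res$genotypes))
  # oracle recomputation of the removed set
  het <- rowSums(d == 1, na.rm = TRUE) / rowSums(!is.na(d))
  miss <- rowMeans(is.na(d))
  expect_setequal(sampleIds(res$genotypes), ids[het <= 0.15 & miss <= 0.02])
  # telescoping
  rep <- res$report
  expect_true(all(rep$n_after == rep$n_before - rep$n_removed))
  expect_equal(rep$n_after[nrow(rep)], nSamples(res$genotypes))
  expect_error(individualQCFilter(make_geno(matrix(1, 5, 10))),
               "every individual")
})

test_that("HWE exact test matches full enumeration", {
  expect_equal(hweExactTest(100, 0, 0), 1.0)
  expect_lt(hweExactTest(0, 100, 0), 1e-20)
  expect_equal(hweExactTest(25, 50, 25), 1.0)
  expect_error(hweExactTest(-1, 5, 5), "negative")
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(3:200, 1)
      nAA <- sample(0:n, 1)
      nAa <- sample(0:(n - nAA), 1)
      naa <- n - nAA - nAa
      expect_equal(hweExactTest(nAA, nAa, naa),
                   enum_hwe_p(nAA, nAa, naa), tolerance = 1e-12)
    }
  })
})

test_that("VIF pruning removes collinear SNPs and keeps independent ones", {
  withr::with_seed(12, d <- matrix(rbinom(1500 * 30, 2, 0.4), 1500, 30))
  # independent SNPs: nothing pruned
  expect_equal(ldPruneVIF(make_geno(d), window = 30, shift = 15),
               sprintf("s%04d", 1:30))
  # exact duplicate: exactly one of the pair removed
  d2 <- cbind(d, d[, 1])
  kept <- ldPruneVIF(make_geno(d2), window = 31, shift = 15)
  expect_equal(length(kept), 30)
  expect_true(xor("s0001" %in% kept, "s0031" %in% kept))
  # copy-with-noise trio at r2 ~ 0.6: some removed, survivors have VIF <= 2
  withr::with_seed(13, {
    base <- rbinom(1500, 2, 0.5)
    noisy <- function() ifelse(runif(1500) < 0.72, base, rbinom(1500, 2, 0.5))
    d3 <- cbind(base, noisy(), noisy(), d[, 1:5])
  })
  g3 <- make_geno(d3)
  kept3 <- ldPruneVIF(g3, window = 8, shift = 4)
  expect_lt(length(kept3), 8)
  X <- scale(dosages(g3)[, kept3])
  vifs <- diag(solve(cor(X)))
  expect_true(all(vifs <= 2 + 1e-8))
  expect_error(ldPruneVIF(g3, window = 10, shift = 20), "window")
})

test_that("post-imputation filter retains INFO > 0.3 and MAF > 0.01", {
  withr::with_seed(14, d <- matrix(rbinom(500 * 6, 2, 0.3), 500, 6))
  g <- setImputationQuality(make_geno(d),
                            infoScore = c(0.29, 0.31, 1, 1, 0.5, 0.2))
  out <- postImputationFilter(g)
  expect_setequal(snpInfo(out)$id, c("s0002", "s0003", "s0004", "s0005"))
  g1 <- setImputationQuality(make_geno(d), infoScore = 1)
  expect_equal(nSnps(postImputationFilter(g1)), 6)
  expect_error(postImputationFilter(make_geno(d)), "info_score")
  # joint grid oracle
  withr::with_seed(15, {
    freqs <- runif(40, 0.001, 0.2)
    dg <- matrix(rbinom(2000 * 40, 2, rep(freqs, each = 2000)), 2000, 40)
  })
  info <- rep(c(0.1, 0.5), 20)
  gg <- setImputationQuality(make_geno(dg), infoScore = info)
  maf <- pmin(colMeans(dg) / 2, 1 - colMeans(dg) / 2)
  expect_equal(nSnps(postImputationFilter(gg)),
               sum(info > 0.3 & maf > 0.01))
})

test_that("QC pipeline is idempotent and reports telescope", {
  cfg <- simConfig(nIndividuals = 800, nSnps = 120, nCausal = 20,
                   mafRange = c(0.05, 0.2), prevalence1 = 0.25,
                   prevalence2 = 0.2, targetCases1 = 50, targetCases2 = 40,
                   targetControls = 150, seed = 21)
  coh <- simulateCohort(cfg)
  geno <- injectMissingness(coh$genotypes, snpRates = runif(120, 0, 0.08),
                            seed = 22)
  th <- qcThresholds(indiv_het_max = 0.5)   # clean HWE panel, maf 0.05-0.2
  res1 <- snpQCFilter(geno, coh$phenotypes, th)
  rep1 <- res1$report
  expect_true(all(rep1$n_after == rep1$n_before - rep1$n_removed))
  # counts chain within each unit
  for (u in c("snp", "individual")) {
    rr <- rep1[rep1$unit == u, ]
    expect_equal(rr$n_before[-1], rr$n_after[-nrow(rr)])
  }
  res2 <- snpQCFilter(res1$genotypes, res1$phenotypes, th)
  expect_equal(res2$report$n_removed, rep(0L, nrow(res2$report)))
  expect_equal(nSnps(res2$genotypes), nSnps(res1$genotypes))
})
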