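# Logistic scans, fixed-effects meta-analysis, genomic inflation, index
# SNPs, sign test and region merging.

test_that("MDS covariate selection keys on phenotype correlation", {
  withr::with_seed(71, {
    comp <- matrix(rnorm(400 * 10), 400, 10)
    y <- rbinom(400, 1, 0.5)
  })
  comp[, 4] <- y + rnorm(400, 0, 0.5)       # strongly associated component
  sel <- selectMdsCovariates(comp, y)
  expect_true(4 %in% sel)
  expect_length(selectMdsCovariates(comp, y, alpha = 0), 0)
  expect_error(selectMdsCovariates(comp, rep(1, 400)), "constant")
})

test_that("association scan finds a planted effect and flags degenerate SNPs", {
  withr::with_seed(72, {
    n <- 2000
    d <- matrix(rbinom(n * 50, 2, 0.3), n, 50)
    d[, 50] <- 1                                # monomorphic
    logit <- -0.5 + log(2) * d[, 7]             # OR = 2 at SNP 7
    y <- rbinom(n, 1, plogis(logit))
  })
  g <- make_geno(d)
  res <- logisticAssocScan(g, y)
  expect_equal(which.min(res$p_value), 7L)
  expect_lt(res$p_value[7], 1e-8)
  expect_equal(res$beta[7], log(2), tolerance = 0.25)
  expect_true(is.na(res$beta[50]))
  expect_equal(res$reason[50], "monomorphic")
  expect_equal(res$n[1], n)
  # Wald results agree with stats::glm on a spot-checked SNP
  fit <- glm(y ~ d[, 7], family = binomial())
  expect_equal(res$beta[7], unname(coef(fit)[2]), tolerance = 1e-6)
  expect_equal(res$se[7], unname(coef(summary(fit))[2, 2]),
               tolerance = 1e-6)
})

test_that("the batched covariate-free scan equals the per-SNP GLM fit", {
  withr::with_seed(70, {
    n <- 400; m <- 60
    d <- matrix(rbinom(n * m, 2, rep(runif(m, 0.05, 0.5), each = n)), n, m)
    y <- rbinom(n, 1, plogis(-0.3 + 0.4 * scale(d[, 5])))
  })
  g <- make_geno(d)
  fast <- logisticAssocScan(g, y)          # complete data: batched path
  d2 <- d; d2[1, 1] <- NA
  slow <- logisticAssocScan(make_geno(d2), y)  # NA forces per-SNP path
  ok <- which(is.finite(fast$beta) & is.finite(slow$beta))[-1]
  expect_lt(max(abs(fast$beta[ok] - slow$beta[ok])), 1e-6)
  expect_lt(max(abs(fast$se[ok] - slow$se[ok])), 1e-4)
})

test_that("null scans are calibrated at the nominal type-I level", {
  withr::with_seed(73, {
    n <- 800
    d <- matrix(rbinom(n * 3000, 2, rep(runif(3000, 0.1, 0.5), each = n)),
                n, 3000)
    y <- rbinom(n, 1, 0.5)
  })
  res <- logisticAssocScan(make_geno(d), y)
  frac <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_equal(frac, 0.05, tolerance = 0.012)
  # median-based lambda has sampling noise ~ 1.3 / sqrt(m) at m = 3000
  lam <- genomicLambda(res$p_value)
  expect_gt(lam, 0.9); expect_lt(lam, 1.1)
})

test_that("fixed-effects meta matches the closed-form pooling rules", {
  s1 <- make_sumstats(c(0.1, 0.1, 0.3), c(0.1, 0.1, 0.15))
  s2 <- make_sumstats(c(0.1, -0.1, 0.1), c(0.1, 0.1, 0.05))
  meta <- metaAnalyzeFixed(list(s1, s2))
  # identical studies: pooled beta unchanged, se / sqrt(2), Q = 0
  expect_equal(meta$beta[1], 0.1)
  expect_equal(meta$se[1], 0.1 / sqrt(2))
  expect_equal(meta$cochran_Q[1], 0)
  expect_equal(meta$p_heterogeneity[1], 1)
  # symmetric effects cancel
  expect_equal(meta$beta[2], 0)
  expect_equal(meta$direction[2], "+-")
  # hand-evaluated inverse-variance pooling for unequal SEs
  w <- c(1 / 0.15^2, 1 / 0.05^2)
  expect_equal(meta$beta[3], sum(w * c(0.3, 0.1)) / sum(w))
  expect_equal(meta$se[3], 1 / sqrt(sum(w)))
  Q <- sum(w * (c(0.3, 0.1) - meta$beta[3])^2)
  expect_equal(meta$cochran_Q[3], Q)
  expect_equal(meta$p_heterogeneity[3], pchisq(Q, 1, lower.tail = FALSE))
  # three studies
  s3 <- make_sumstats(c(0.2, 0, 0.2), c(0.2, 0.2, 0.1))
  m3 <- metaAnalyzeFixed(list(s1, s2, s3))
  expect_equal(m3$k_studies, rep(3L, 3))
  expect_equal(nchar(m3$direction), rep(3L, 3))
  expect_true(all(m3$se <= pmin(s1$se, s2$se, s3$se)))
})

test_that("meta is invariant to allele flips and drops ambiguous SNPs", {
  s1 <- make_sumstats(c(0.2, -0.1), c(0.1, 0.1))
  s2 <- make_sumstats(c(0.15, -0.05), c(0.12, 0.08))
  base <- metaAnalyzeFixed(list(s1, s2))
  s2f <- s2
  s2f$effect_allele <- s1$other_allele
  s2f$other_allele <- s1$effect_allele
  s2f$beta <- -s2$beta
  s2f$effect_allele_freq <- 1 - s2$effect_allele_freq
  flipped <- metaAnalyzeFixed(list(s1, s2f))
  expect_equal(flipped$beta, base$beta)
  expect_equal(flipped$se, base$se)
  expect_equal(flipped$cochran_Q, base$cochran_Q)
  # ambiguous A/T SNP is dropped at alignment
  s1a <- s1; s1a$effect_allele[1] <- "A"; s1a$other_allele[1] <- "T"
  s2a <- s2; s2a$effect_allele[1] <- "A"; s2a$other_allele[1] <- "T"
  m <- metaAnalyzeFixed(list(s1a, s2a))
  expect_equal(nrow(m), 1)
  expect_equal(m$id, "s0002")
})

test_that("genomic lambda behaves on constructed statistics", {
  med <- qchisq(0.5, 1)
  p_at_median <- rep(pchisq(med, 1, lower.tail = FALSE), 101)
  expect_equal(genomicLambda(p_at_median), 1.0)
  withr::with_seed(74, p <- runif(100000))
  expect_equal(genomicLambda(p), 1.0, tolerance = 0.01)
  # inflating every null statistic by 1.11 moves lambda to 1.11
  stat <- qchisq(p, 1, lower.tail = FALSE) * 1.11
  expect_equal(genomicLambda(pchisq(stat, 1, lower.tail = FALSE)), 1.11,
               tolerance = 0.012)
  expect_error(genomicLambda(rep(NA_real_, 5)), "valid")
})

test_that("index-SNP selection collapses LD and keeps independent signals", {
  withr::with_seed(75, {
    base <- rbinom(800, 2, 0.4)
    d <- cbind(base, base,                      # perfect LD pair
               matrix(rbinom(800 * 4, 2, 0.4), 800, 4))
  })
  g <- make_geno(d)
  ss <- make_sumstats(rep(0.3, 6), rep(0.05, 6),
                      p = c(1e-10, 1e-9, 1e-6, 1e-7, 0.5, 1e-8),
                      pos = c(1000, 2000, 3000, 4000, 5000, 6000))
  idx <- selectIndexSnps(ss, 1e-5, r2_max = 0.1, window_kb = 500, g)
  expect_true("s0001" %in% idx)
  expect_false("s0002" %in% idx)              # absorbed by its LD partner
  expect_setequal(idx, c("s0001", "s0003", "s0004", "s0006"))
  # nothing significant -> empty set
  expect_length(selectIndexSnps(ss, 1e-20, genotypes_reference = g), 0)
  # LD-free: everything below threshold is its own index
  ss2 <- ss; idx2 <- selectIndexSnps(ss2[3:6, ], 1e-5,
                                     genotypes_reference = g)
  expect_setequal(idx2, c("s0003", "s0004", "s0006"))
})

test_that("sign test reproduces exact binomial arithmetic", {
  disc <- make_sumstats(rep(0.2, 10), rep(0.05, 10), p = rep(1e-4, 10))
  tgt <- disc
  tgt$beta <- c(rep(0.1, 8), rep(-0.1, 2))    # 8 of 10 concordant
  res <- signTest(disc, tgt, thresholds = 1e-3)
  expect_equal(res$n_concordant, 8)
  expect_equal(res$proportion_concordant, 0.8)
  expect_equal(res$binomial_p_two_sided, 112 / 1024, tolerance = 1e-12)
  # 20 of 20
  d20 <- make_sumstats(rep(0.2, 20), rep(0.05, 20), p = rep(1e-7, 20))
  r20 <- signTest(d20, d20, thresholds = c(1e-3, 1e-6))
  expect_equal(r20$n_index_snps, c(20L, 20L))
  expect_equal(r20$binomial_p_two_sided, rep(2 * 0.5^20, 2),
               tolerance = 1e-9)
  # 50 of 100 folds to p = 1
  d100 <- make_sumstats(c(rep(0.2, 50), rep(-0.2, 50)), rep(0.05, 100),
                        p = rep(1e-4, 100))
  t100 <- d100; t100$beta <- abs(t100$beta)
  r100 <- signTest(d100, t100, thresholds = 1e-3)
  expect_equal(r100$n_concordant, 50)
  expect_equal(r100$binomial_p_two_sided, 1)
  # global sign flip of the target leaves the folded p unchanged
  tflip <- tgt; tflip$beta <- -tflip$beta
  expect_equal(signTest(disc, tflip, thresholds = 1e-3)$binomial_p_two_sided,
               res$binomial_p_two_sided)
  # absent index SNPs are excluded and counted
  tgt2 <- tgt[1:6, ]
  r2 <- signTest(disc, tgt2, thresholds = 1e-3)
  expect_equal(r2$n_index_snps, 6)
  expect_equal(r2$n_excluded, 4)
})

test_that("genome-wide regions merge by distance with correct indexing", {
  ss <- make_sumstats(rep(0.3, 7), rep(0.04, 7),
                      p = c(1e-9, 1e-10, 0.5, 1e-9, 1e-12, 1e-9, 1e-9),
                      chr = c(1, 1, 1, 1, 1, 2, 2),
                      pos = c(100000, 200000, 210000, 900000, 950000,
                              100000, 600000))
  reg <- genomeWideRegions(ss, alpha = 5e-8, merge_kb = 250)
  expect_equal(nrow(reg), 4)
  expect_equal(reg$n_snps, c(2L, 2L, 1L, 1L))
  expect_equal(reg$index_snp[2], "s0005")
  expect_equal(reg$chr, c(1, 1, 2, 2))
  # two significant SNPs 100 kb apart form one region
  ss2 <- make_sumstats(rep(0.3, 2), rep(0.04, 2), p = c(1e-9, 1e-9),
                       pos = c(100000, 200000))
  expect_equal(genomeWideRegions(ss2)$n_snps, 2L)
  # nothing significant: empty frame
  expect_equal(nrow(genomeWideRegions(make_sumstats(0.1, 0.1, p = 0.5))), 0)
})
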