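# Balance gatekeeping, split-plan bookkeeping, and the rg distribution
# comparison.

make_balance_pheno <- function(counts) {
  # counts: named list subtype -> named site counts, plus controls
  rows <- do.call(rbind, lapply(names(counts), function(st) {
    do.call(rbind, lapply(names(counts[[st]]), function(site) {
      n <- counts[[st]][[site]]
      if (n == 0) return(NULL)
      data.frame(subtype = st, site = site, n = n)
    }))
  }))
  ph <- rows[rep(seq_len(nrow(rows)), rows$n), c("subtype", "site")]
  ph$status <- ifelse(ph$subtype == "none", "control", "case")
  ph$sample_id <- sprintf("i%05d", seq_len(nrow(ph)))
  rownames(ph) <- NULL
  ph
}

test_that("subtypes concentrated in a single site are excluded", {
  ph <- make_balance_pheno(list(
    BD1 = c(siteA = 50, siteB = 50),
    BD2 = c(siteA = 45, siteB = 55),
    SAB = c(siteA = 80, siteB = 20)))
  rep <- checkSiteSubtypeBalance(ph)
  expect_equal(rep$excluded_subtypes, "SAB")
  expect_length(rep$excluded_sites, 0)
  # exactly 75% is retained (strict > rule)
  ph2 <- make_balance_pheno(list(
    BD1 = c(siteA = 75, siteB = 25),
    BD2 = c(siteA = 50, siteB = 50)))
  expect_length(checkSiteSubtypeBalance(ph2)$excluded_subtypes, 0)
  # balanced 50/50: nothing excluded
  ph3 <- make_balance_pheno(list(
    BD1 = c(siteA = 50, siteB = 50),
    BD2 = c(siteA = 50, siteB = 50)))
  rep3 <- checkSiteSubtypeBalance(ph3)
  expect_length(rep3$excluded_subtypes, 0)
  expect_length(rep3$excluded_sites, 0)
})

test_that("grossly imbalanced site contributions are flagged", {
  # siteA contributes 60/100 of BD1 but only 5/100 of BD2: ratio 12 > 3
  ph <- make_balance_pheno(list(
    BD1 = c(siteA = 60, siteB = 40),
    BD2 = c(siteA = 5, siteB = 95)))
  rep <- checkSiteSubtypeBalance(ph)
  expect_true("siteA" %in% rep$excluded_sites)
  expect_false("siteB" %in% rep$excluded_sites)
})

test_that("split plans partition controls evenly and count correctly", {
  ph <- data.frame(
    sample_id = sprintf("i%03d", 1:41),
    status = rep(c("case", "case", "control"), c(12, 18, 11)),
    subtype = rep(c("BD1", "BD2", "none"), c(12, 18, 11)),
    stringsAsFactors = FALSE)
  plans <- generateSplitPlans(ph, 5, 4, seed = 61)
  expect_equal(unname(nPlans(plans)), c(5L, 20L))
  for (i in 1:5) {
    pl <- getPlan(plans, "subtype_pair", i)
    expect_length(pl$control_group_A, 6)       # 11 controls -> 6 + 5
    expect_length(pl$control_group_B, 5)
    expect_length(intersect(pl$control_group_A, pl$control_group_B), 0)
    expect_setequal(c(pl$control_group_A, pl$control_group_B),
                    ph$sample_id[ph$status == "control"])
    expect_setequal(pl$case_group_1, ph$sample_id[ph$subtype == "BD1"])
    for (j in 1:4) {
      mx <- getPlan(plans, "mixed_pair", i, j)
      expect_length(mx$case_group_1, 12)       # sized as the subtype groups
      expect_length(mx$case_group_2, 18)
      expect_length(intersect(mx$case_group_1, mx$case_group_2), 0)
      expect_setequal(c(mx$case_group_1, mx$case_group_2),
                      ph$sample_id[ph$status == "case"])
      # control halves are shared with the parent permutation
      expect_identical(mx$control_group_A, pl$control_group_A)
    }
  }
  # reproducibility and distinctness
  plans2 <- generateSplitPlans(ph, 5, 4, seed = 61)
  expect_identical(plans, plans2)
  plansb <- generateSplitPlans(ph, 5, 4, seed = 62)
  expect_false(identical(plans$controls, plansb$controls))
  expect_false(identical(plans$controls[[1]], plans$controls[[2]]))
  # even control count: exact halves
  ph2 <- ph[1:40, ]
  pl2 <- getPlan(generateSplitPlans(ph2, 1, 1, seed = 1), "subtype_pair", 1)
  expect_length(pl2$control_group_A, 5)
  expect_length(pl2$control_group_B, 5)
  expect_error(generateSplitPlans(ph[1:30, ], 2, 2, seed = 1), "control")
})

test_that("mixed-only estimation leaves the subtype vector empty", {
  tr <- make_h2_trait(120, 150, 0.5, 63)
  ids <- names(tr$y)
  ph <- data.frame(sample_id = ids,
                   status = rep(c("case", "control"), c(60, 60)),
                   subtype = rep(c("BD1", "BD2", "none"), c(30, 30, 60)),
                   stringsAsFactors = FALSE)
  grm <- computeGRM(tr$genotypes)
  plans <- generateSplitPlans(ph, 2, 2, seed = 64)
  dist <- estimateRgDistributions(ph, plans, grm, kinds = "mixed_pair")
  expect_length(dist$rg_subtype, 0)
  expect_length(dist$rg_mix, 4)
  expect_length(dist$converged_mix, 4)
})

test_that("rg distribution comparison is a Welch t-test with summaries", {
  v <- c(0.5, 0.6, 0.7, 0.8)
  d0 <- structure(list(rg_subtype = v, se_subtype = rep(0.1, 4),
                       converged_subtype = rep(TRUE, 4),
                       rg_mix = v, se_mix = rep(0.1, 4),
                       converged_mix = rep(TRUE, 4)),
                  class = "RgDistributions")
  cmp0 <- compareRgDistributions(d0)
  expect_equal(cmp0$t_statistic, 0)
  expect_equal(cmp0$p_two_sided, 1)
  # synthetic distributions echoing the reported scales
  withr::with_seed(65, {
    a <- rnorm(100, 0.78, 0.07)
    b <- rnorm(10000, 0.97, 0.05)
  })
  d1 <- structure(list(rg_subtype = a, se_subtype = rep(0.1, 100),
                       converged_subtype = rep(TRUE, 100),
                       rg_mix = b, se_mix = rep(0.1, 10000),
                       converged_mix = rep(TRUE, 10000)),
                  class = "RgDistributions")
  cmp1 <- compareRgDistributions(d1)
  expect_lt(cmp1$p_two_sided, 1e-10)
  # closed-form Welch cross-check
  se2 <- var(a) / 100 + var(b) / 10000
  expect_equal(cmp1$t_statistic, (mean(a) - mean(b)) / sqrt(se2),
               tolerance = 1e-10)
  # summaries mirror the estimate vectors
  expect_equal(cmp1$summary$mean, c(mean(a), mean(b)))
  expect_equal(cmp1$summary$n_converged, c(100L, 10000L))
  # non-converged estimates are excluded but counted
  d2 <- d1
  d2$converged_subtype[1:40] <- FALSE
  cmp2 <- compareRgDistributions(d2)
  expect_equal(cmp2$summary$n_converged[1], 60L)
  expect_equal(cmp2$summary$n[1], 100L)
  d3 <- d1; d3$rg_subtype <- 0.5; d3$se_subtype <- 0.1
  d3$converged_subtype <- TRUE
  expect_error(compareRgDistributions(d3), "at least 2")
})
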