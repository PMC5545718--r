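# Pre-analysis quality control with the standard GWAS thresholds:
# two-pass SNP missingness, individual heterozygosity/missingness, MAF,
# Hardy-Weinberg exact test (in controls), differential missingness,
# VIF-based LD pruning and the post-imputation INFO/MAF filter.

#' Quality-control thresholds
#'
#' Returns the QC threshold set, with defaults equal to the standard
#' pipeline values: SNP missingness >5% (pass 1) and >2% (pass 2),
#' individual heterozygosity rate >15% and missingness >2%, MAF <1%,
#' Hardy-Weinberg exact P < 5e-5, case-control differential missingness
#' P < 1e-3, VIF pruning with window 100 / shift 50 / VIF 2, PIHAT > 0.1
#' relatedness, 10 MDS components, and post-imputation INFO > 0.3 with
#' MAF > 0.01.
#'
#' The heterozygosity bound is an absolute rate (proportion of non-missing
#' calls that are heterozygous), not a deviation-from-mean rule; it is
#' exposed here precisely because an absolute 15% bound only makes sense
#' for low-MAF SNP panels.
#'
#' @param snp_missing_pass1,snp_missing_pass2 SNP missingness bounds.
#' @param indiv_het_max,indiv_missing_max individual QC bounds.
#' @param maf_min minor allele frequency bound.
#' @param hwe_p_min Hardy-Weinberg exact-test P bound (controls only).
#' @param diff_missing_p_min differential-missingness P bound.
#' @param vif_window,vif_shift,vif_max LD pruning parameters.
#' @param pihat_max relatedness bound.
#' @param n_mds_components MDS components for ancestry.
#' @param info_min,post_imputation_maf_min post-imputation filters.
#' @return a named list of class `QCThresholds`.
#' @export
qcThresholds <- function(snp_missing_pass1 = 0.05, indiv_het_max = 0.15,
                         indiv_missing_max = 0.02, snp_missing_pass2 = 0.02,
                         maf_min = 0.01, hwe_p_min = 5e-5,
                         diff_missing_p_min = 1e-3, vif_window = 100L,
                         vif_shift = 50L, vif_max = 2,
                         pihat_max = 0.1, n_mds_components = 10L,
                         info_min = 0.3, post_imputation_maf_min = 0.01) {
  props <- c(snp_missing_pass1, indiv_het_max, indiv_missing_max,
             snp_missing_pass2, maf_min, hwe_p_min, diff_missing_p_min)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (vif_window < vif_shift || vif_shift < 1)
    stop("need vif_window >= vif_shift >= 1")
  structure(list(snp_missing_pass1 = snp_missing_pass1,
                 indiv_het_max = indiv_het_max,
                 indiv_missing_max = indiv_missing_max,
                 snp_missing_pass2 = snp_missing_pass2,
                 maf_min = maf_min, hwe_p_min = hwe_p_min,
                 diff_missing_p_min = diff_missing_p_min,
                 vif_window = as.integer(vif_window),
                 vif_shift = as.integer(vif_shift), vif_max = vif_max,
                 pihat_max = pihat_max,
                 n_mds_components = as.integer(n_mds_components),
                 info_min = info_min,
                 post_imputation_maf_min = post_imputation_maf_min),
            class = "QCThresholds")
}

.report_row <- function(stage, unit, before, removed) {
  data.frame(stage = stage, unit = unit, n_before = before,
             n_removed = length(removed), n_after = before - length(removed),
             stringsAsFactors = FALSE)
}

.bind_report <- function(rows, removed) {
  rep <- do.call(rbind, rows)
  attr(rep, "removed") <- removed
  class(rep) <- c("QCReport", class(rep))
  rep
}

.snp_missingness <- function(d) colMeans(is.na(d))
.sample_maf <- function(d) {
  f <- colMeans(d, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Individual-level QC filter
#'
#' Removes individuals whose heterozygosity rate (proportion of non-missing
#' calls equal to 1) exceeds `indiv_het_max` or whose missingness rate
#' exceeds `indiv_missing_max`.
#'
#' @param genotypes a [GenotypeData-class].
#' @param thresholds a [qcThresholds()] list.
#' @return list(genotypes, report).
#' @export
individualQCFilter <- function(genotypes, thresholds = qcThresholds()) {
  d <- dosages(genotypes)
  if (ncol(d) < 1) stop("no SNPs in genotype matrix")
  nonmiss <- rowSums(!is.na(d))
  het <- rowSums(d == 1, na.rm = TRUE) / pmax(nonmiss, 1)
  miss <- 1 - nonmiss / ncol(d)
  bad_het <- het > thresholds$indiv_het_max
  bad_miss <- miss > thresholds$indiv_missing_max
  drop <- which(bad_het | bad_miss)
  if (length(drop) == nrow(d)) stop("individual QC removed every individual")
  ids <- sampleIds(genotypes)
  removed <- list(heterozygosity = ids[bad_het],
                  indiv_missingness = ids[bad_miss & !bad_het])
  rows <- list(.report_row("heterozygosity", "individual", nrow(d),
                           which(bad_het)),
               .report_row("indiv_missingness", "individual",
                           nrow(d) - sum(bad_het), which(bad_miss & !bad_het)))
  keep <- setdiff(seq_len(nrow(d)), drop)
  list(genotypes = genotypes[keep, ],
       report = .bind_report(rows, removed))
}

#' SNP-level QC pipeline
#'
#' Applies, in order: SNP missingness pass 1 (> `snp_missing_pass1`),
#' individual QC (heterozygosity and missingness, via
#' [individualQCFilter()]), SNP missingness pass 2 (> `snp_missing_pass2`),
#' MAF < `maf_min`, Hardy-Weinberg exact-test P < `hwe_p_min` computed in
#' controls only, and case-control differential missingness (2x2 chi-square
#' P < `diff_missing_p_min`). The report records every stage with
#' telescoping counts.
#'
#' @param genotypes a [GenotypeData-class].
#' @param phenotypes phenotype table aligned to `genotypes` (columns
#'   `sample_id`, `status`).
#' @param thresholds a [qcThresholds()] list.
#' @return list(genotypes, phenotypes, report).
#' @export
snpQCFilter <- function(genotypes, phenotypes,
                        thresholds = qcThresholds()) {
  if (nSamples(genotypes) == 0 || nSnps(genotypes) == 0)
    stop("empty genotype matrix")
  if (!identical(sampleIds(genotypes), phenotypes$sample_id))
    stop("phenotype table not aligned with genotypes")
  rows <- list(); removed <- list()
  snp_stage <- function(geno, keep_mask, stage) {
    ids <- snpInfo(geno)$id
    rows[[length(rows) + 1]] <<- .report_row(stage, "snp", nSnps(geno),
                                             which(!keep_mask))
    removed[[stage]] <<- ids[!keep_mask]
    geno[, which(keep_mask)]
  }

  # pass 1: gross SNP missingness
  miss1 <- .snp_missingness(dosages(genotypes))
  geno <- snp_stage(genotypes, !(miss1 > thresholds$snp_missing_pass1),
                    "snp_missingness_pass1")

  # individual QC between the two SNP passes
  ind <- individualQCFilter(geno, thresholds)
  geno <- ind$genotypes
  rows <- c(rows, split(ind$report, seq_len(nrow(ind$report))))
  removed <- c(removed, attr(ind$report, "removed"))
  phenotypes <- phenotypes[match(sampleIds(geno), phenotypes$sample_id), ,
                           drop = FALSE]
  rownames(phenotypes) <- NULL

  # pass 2: missingness, MAF, HWE (controls), differential missingness
  d <- dosages(geno)
  geno <- snp_stage(geno, !(.snp_missingness(d) > thresholds$snp_missing_pass2),
                    "snp_missingness_pass2")
  d <- dosages(geno)
  geno <- snp_stage(geno, !(.sample_maf(d) < thresholds$maf_min), "maf")
  d <- dosages(geno)

  is_control <- phenotypes$status == "control"
  if (any(is_control)) {
    dc <- d[is_control, , drop = FALSE]
    hwe_p <- vapply(seq_len(ncol(dc)), function(j) {
      g <- dc[, j]
      hweExactTest(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 0, na.rm = TRUE))
    }, numeric(1))
    geno <- snp_stage(geno, !(hwe_p < thresholds$hwe_p_min), "hwe")
    d <- dosages(geno)
  }

  if (any(is_control) && any(!is_control)) {
    p_dm <- .diff_missingness_p(d, !is_control)
    geno <- snp_stage(geno, !(p_dm < thresholds$diff_missing_p_min),
                      "differential_missingness")
  }
  list(genotypes = geno, phenotypes = phenotypes,
       report = .bind_report(rows, removed))
}

# 2x2 chi-square (no continuity correction) on called/missing x case/control
.diff_missingness_p <- function(d, is_case) {
  miss <- is.na(d)
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  a <- colSums(miss[is_case, , drop = FALSE])      # missing in cases
  c_ <- colSums(miss[!is_case, , drop = FALSE])    # missing in controls
  b <- n_case - a; dd <- n_ctrl - c_
  n <- n_case + n_ctrl
  num <- n * (a * dd - b * c_)^2
  den <- (a + c_) * (b + dd) * as.numeric(n_case) * n_ctrl
  stat <- ifelse(den > 0, num / den, 0)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test on genotype counts: the P-value is the sum of the
#' probabilities of all heterozygote counts (given the allele counts) whose
#' conditional probability does not exceed that of the observed table.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, not all zero).
#' @return P-value in (0, 1\].
#' @export
hweExactTest <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts zero")
  nA <- 2 * n_AA + n_Aa              # count of A alleles
  n_rare <- min(nA, 2 * n - nA)      # minor allele count
  # attainable heterozygote counts share the parity of the rare count
  het <- seq(n_rare %% 2, n_rare, by = 2)
  # unnormalized log-probabilities of each heterozygote count
  lp <- lgamma(n + 1) - lgamma((n_rare - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((2 * n - n_rare - het) / 2 + 1) + het * log(2)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  obs <- which(het == n_Aa)
  if (length(obs) != 1) stop("observed heterozygote count not attainable")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' LD pruning by variance inflation factor
#'
#' Slides a window of `window` SNPs by `shift` along each chromosome;
#' within a window the SNP with the largest VIF (1 / (1 - R^2) from the
#' regression on the other retained SNPs in the window) is removed until
#' all VIFs are at most `vif_max`. Deterministic; exact collinearity gives
#' infinite VIF, ties break toward the later SNP.
#'
#' @param genotypes a [GenotypeData-class], SNPs ordered by chromosome and
#'   position.
#' @param window,shift window size and shift in SNP counts.
#' @param vif_max VIF bound.
#' @return character vector of retained SNP ids.
#' @export
ldPruneVIF <- function(genotypes, window = 100L, shift = 50L, vif_max = 2) {
  if (window < shift) stop("window must be >= shift")
  d <- dosages(genotypes)
  snps <- snpInfo(genotypes)
  keep <- rep(TRUE, ncol(d))
  for (chr in unique(snps$chr)) {
    idx <- which(snps$chr == chr)
    starts <- seq(1L, max(1L, length(idx)), by = shift)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        v <- .window_vifs(d[, act, drop = FALSE])
        if (max(v) <= vif_max) break
        worst <- act[max(which(v == max(v)))]
        keep[worst] <- FALSE
      }
      if (s + window - 1L >= length(idx)) break
    }
  }
  snps$id[keep]
}

# VIFs of each column against the others; Inf on exact collinearity
.window_vifs <- function(X) {
  X <- scale(X)
  X[is.na(X)] <- 0
  R <- crossprod(X) / (nrow(X) - 1)
  Ri <- tryCatch(solve(R), error = function(e) NULL)
  if (!is.null(Ri)) return(diag(Ri))
  # singular correlation matrix: per-column R^2 via least squares
  vapply(seq_len(ncol(X)), function(j) {
    ss <- sum(X[, j]^2)
    if (ss == 0) return(1)                 # constant column: VIF 1
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / ss
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Post-imputation SNP filter
#'
#' Retains SNPs with imputation INFO score above `info_min` and sample MAF
#' above `maf_min`.
#'
#' @param genotypes a [GenotypeData-class] whose SNP table carries
#'   `info_score` (error if absent).
#' @param info_min INFO bound (exclusive).
#' @param maf_min MAF bound (exclusive).
#' @return the filtered [GenotypeData-class].
#' @export
postImputationFilter <- function(genotypes, info_min = 0.3, maf_min = 0.01) {
  info <- snpInfo(genotypes)$info_score
  if (is.null(info)) stop("genotypes carry no info_score field")
  maf <- .sample_maf(dosages(genotypes))
  genotypes[, which(info > info_min & maf > maf_min)]
}
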