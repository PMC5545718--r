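# Logistic association scans, inverse-variance fixed-effects meta-analysis
# with Cochran's Q, genomic inflation, index-SNP selection, and the
# direction-of-effect sign test.

.AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")
.is_ambiguous <- function(a1, a2) paste(a1, a2, sep = "/") %in% .AMBIGUOUS

#' Select phenotype-associated MDS covariates
#'
#' Regresses the phenotype on each of the leading (at most ten) MDS
#' components in turn (logistic regression) and selects those with
#' P < `alpha`.
#'
#' @param mds_components matrix from [ibsMDS()].
#' @param phenotype binary 0/1 vector.
#' @param alpha significance level (default 0.05).
#' @return integer indices of the selected components.
#' @export
selectMdsCovariates <- function(mds_components, phenotype, alpha = 0.05) {
  if (ncol(mds_components) < 1) stop("need at least one component")
  if (length(unique(phenotype)) < 2) stop("constant phenotype")
  use <- seq_len(min(10L, ncol(mds_components)))
  p <- vapply(use, function(j) {
    fit <- glm(phenotype ~ mds_components[, j], family = binomial())
    coef(summary(fit))[2, 4]
  }, numeric(1))
  use[p < alpha]
}

#' Per-SNP logistic association scan
#'
#' Logistic regression of case status on the allele dosage (count of A1,
#' the effect allele) plus covariates, per SNP, with Wald statistics.
#' Monomorphic SNPs and fits showing separation are returned as flagged
#' `NA` rows, not errors. Fractional (imputed) dosages are accepted.
#'
#' @param genotypes a [GenotypeData-class] or dosage matrix.
#' @param phenotype binary 0/1 vector aligned to the rows.
#' @param covariates optional covariate matrix.
#' @return a `SummaryStats` data.frame: `id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `effect_allele_freq`, `beta`, `se`,
#'   `p_value`, `n`, optional `info_score`, and a `reason` column for
#'   flagged SNPs.
#' @export
logisticAssocScan <- function(genotypes, phenotype, covariates = NULL) {
  stopifnot(all(phenotype %in% 0:1))
  d <- dosages(genotypes)
  snps <- snpInfo(genotypes)
  if (is.null(covariates) && !anyNA(d))
    return(.fast_logistic_scan(d, phenotype, snps))
  base <- cbind(rep(1, nrow(d)), covariates)
  if (qr(base)$rank < ncol(base)) stop("covariates not full rank")
  m <- ncol(d)
  beta <- se <- p <- freq <- rep(NA_real_, m)
  nn <- integer(m)
  reason <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    x <- d[, j]
    ok <- !is.na(x)
    nn[j] <- sum(ok)
    freq[j] <- mean(x[ok]) / 2
    if (var(x[ok]) == 0) { reason[j] <- "monomorphic"; next }
    X <- cbind(base[ok, , drop = FALSE], dose = x[ok])
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, phenotype[ok], family = binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { reason[j] <- "nonconverged"; next }
    k <- ncol(X)
    # Wald SE from the unscaled covariance of the IRLS working model
    W <- fit$weights
    XtWX <- crossprod(X * sqrt(W))
    Vb <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(Vb)) { reason[j] <- "singular"; next }
    b <- fit$coefficients[k]
    s <- sqrt(Vb[k, k])
    if (!is.finite(s) || s > 100 || abs(b) > 20) {
      reason[j] <- "separation"; next
    }
    beta[j] <- b; se[j] <- s
    p[j] <- 2 * pnorm(-abs(b / s))
  }
  out <- data.frame(id = snps$id, chr = snps$chr, pos = snps$pos,
                    effect_allele = snps$A1, other_allele = snps$A2,
                    effect_allele_freq = freq, beta = beta, se = se,
                    p_value = p, n = nn, reason = reason,
                    stringsAsFactors = FALSE)
  if (!is.null(snps$info_score)) out$info_score <- snps$info_score
  out
}

# Covariate-free complete-data scan: Newton iterations on the per-SNP
# (intercept, dosage) logistic model, vectorized across blocks of SNPs.
# Identical to the per-SNP IRLS fit (same MLE and Wald statistics), just
# batched; used automatically for large null/calibration scans.
.fast_logistic_scan <- function(d, y, snps, block = 4000L) {
  n <- nrow(d); m <- ncol(d)
  storage.mode(d) <- "double"
  beta <- se <- p <- rep(NA_real_, m)
  freq <- colMeans(d) / 2
  mono <- colSums((d - rep(colMeans(d), each = n))^2) == 0
  reason <- rep(NA_character_, m)
  reason[mono] <- "monomorphic"
  pbar <- mean(y)
  for (s in seq(1L, m, by = block)) {
    cols <- s:min(s + block - 1L, m)
    cols <- cols[!mono[cols]]
    if (!length(cols)) next
    B <- d[, cols, drop = FALSE]
    k <- length(cols)
    b0 <- rep(log(pbar / (1 - pbar)), k); b1 <- rep(0, k)
    h00 <- h01 <- h11 <- rep(NA_real_, k)
    for (it in 1:30) {
      ETA <- sweep(B, 2, b1, "*")
      ETA <- sweep(ETA, 2, b0, "+")
      MU <- 1 / (1 + exp(-ETA))
      W <- MU * (1 - MU)
      R <- y - MU
      g0 <- colSums(R); g1 <- colSums(R * B)
      h00 <- colSums(W); h01 <- colSums(W * B); h11 <- colSums(W * B * B)
      det <- h00 * h11 - h01^2
      db0 <- (h11 * g0 - h01 * g1) / det
      db1 <- (h00 * g1 - h01 * g0) / det
      step_cap <- pmax(1, pmax(abs(db0), abs(db1)) / 5)  # damp huge steps
      b0 <- b0 + db0 / step_cap; b1 <- b1 + db1 / step_cap
      if (max(abs(db0), abs(db1)) < 1e-10) break
    }
    sej <- sqrt(h00 / det)
    bad <- !is.finite(sej) | sej > 100 | abs(b1) > 20
    beta[cols] <- ifelse(bad, NA, b1)
    se[cols] <- ifelse(bad, NA, sej)
    p[cols] <- ifelse(bad, NA, 2 * pnorm(-abs(b1 / sej)))
    reason[cols][bad] <- "separation"
  }
  out <- data.frame(id = snps$id, chr = snps$chr, pos = snps$pos,
                    effect_allele = snps$A1, other_allele = snps$A2,
                    effect_allele_freq = freq, beta = beta, se = se,
                    p_value = p, n = rep(n, m), reason = reason,
                    stringsAsFactors = FALSE)
  if (!is.null(snps$info_score)) out$info_score <- snps$info_score
  out
}

# Align `stats` to the orientation of `ref` (matching by SNP id): flips
# beta/freq when effect and other alleles are swapped, drops mismatches
# and (optionally) strand-ambiguous SNPs. Returns the aligned subset of
# `stats` in ref order, with attribute "dropped".
.align_summary <- function(ref, stats, drop_ambiguous = TRUE) {
  idx <- match(ref$id, stats$id)
  keep <- !is.na(idx)
  s <- stats[idx[keep], , drop = FALSE]
  r <- ref[keep, , drop = FALSE]
  same <- s$effect_allele == r$effect_allele & s$other_allele == r$other_allele
  swap <- s$effect_allele == r$other_allele & s$other_allele == r$effect_allele
  amb <- .is_ambiguous(r$effect_allele, r$other_allele)
  use <- (same | swap) & (!drop_ambiguous | !amb)
  s <- s[use, , drop = FALSE]
  flip <- swap[use]
  s$beta[flip] <- -s$beta[flip]
  if (!is.null(s$effect_allele_freq))
    s$effect_allele_freq[flip] <- 1 - s$effect_allele_freq[flip]
  s$effect_allele <- r$effect_allele[use]
  s$other_allele <- r$other_allele[use]
  attr(s, "ref_rows") <- which(keep)[use]
  s
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools per-study log-odds with weights 1/se^2 after aligning every study
#' to the first study's allele orientation (beta signs flipped for swapped
#' alleles; strand-ambiguous A/T and C/G SNPs dropped). Reports Cochran's
#' Q with its chi-square heterogeneity P (df = contributing studies - 1)
#' and a +/-/? direction string.
#'
#' @param studies list of >= 2 `SummaryStats` data.frames.
#' @param min_studies minimum number of contributing studies per SNP.
#' @return `MetaResult` data.frame with pooled `beta`, `se`, `p_value`,
#'   `cochran_Q`, `p_heterogeneity`, `k_studies`, `direction`.
#' @export
metaAnalyzeFixed <- function(studies, min_studies = 2L) {
  if (length(studies) < 2) stop("need at least two studies")
  ref <- studies[[1]]
  ref <- ref[!.is_ambiguous(ref$effect_allele, ref$other_allele), ,
             drop = FALSE]
  k <- length(studies)
  B <- SE <- matrix(NA_real_, nrow(ref), k)
  ok1 <- is.finite(ref$beta) & is.finite(ref$se)
  B[ok1, 1] <- ref$beta[ok1]; SE[ok1, 1] <- ref$se[ok1]
  for (s in 2:k) {
    al <- .align_summary(ref, studies[[s]])
    rows <- attr(al, "ref_rows")
    good <- is.finite(al$beta) & is.finite(al$se)
    B[rows[good], s] <- al$beta[good]
    SE[rows[good], s] <- al$se[good]
  }
  contrib <- rowSums(!is.na(B))
  keep <- contrib >= min_studies
  if (!any(keep)) stop("no SNPs shared by enough studies")
  B <- B[keep, , drop = FALSE]; SE <- SE[keep, , drop = FALSE]
  ref <- ref[keep, , drop = FALSE]
  W <- 1 / SE^2
  W[is.na(W)] <- 0
  Bz <- B; Bz[is.na(Bz)] <- 0
  sw <- rowSums(W)
  pooled <- rowSums(W * Bz) / sw
  pooled_se <- 1 / sqrt(sw)
  Q <- rowSums(W * (Bz - pooled)^2 * (!is.na(B)))
  kc <- rowSums(!is.na(B))
  p_het <- pchisq(Q, df = kc - 1, lower.tail = FALSE)
  dir <- apply(B, 1, function(b)
    paste(ifelse(is.na(b), "?", ifelse(b >= 0, "+", "-")), collapse = ""))
  data.frame(id = ref$id, chr = ref$chr, pos = ref$pos,
             effect_allele = ref$effect_allele,
             other_allele = ref$other_allele,
             beta = pooled, se = pooled_se,
             p_value = 2 * pnorm(-abs(pooled / pooled_se)),
             cochran_Q = Q, p_heterogeneity = p_het,
             k_studies = kc, direction = dir,
             stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' lambda = median of the association chi-square statistics divided by the
#' null chi-square(1) median (0.4549...).
#'
#' @param p_values vector of association P-values (NAs dropped).
#' @return lambda (unrounded; conventionally reported to 3 decimals).
#' @export
genomicLambda <- function(p_values) {
  p <- p_values[is.finite(p_values)]
  if (!length(p)) stop("no valid P-values")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Greedy index-SNP selection (LD clumping)
#'
#' Repeatedly takes the most significant remaining SNP with P below
#' `p_threshold` and removes all SNPs within `window_kb` on the same
#' chromosome whose squared correlation with it (in the reference
#' genotypes) exceeds `r2_max`.
#'
#' @param summary a `SummaryStats` data.frame.
#' @param p_threshold significance bound.
#' @param r2_max squared-correlation bound defining approximate linkage
#'   equilibrium (default 0.1).
#' @param window_kb clumping window in kilobases (default 500).
#' @param genotypes_reference [GenotypeData-class] covering the summary
#'   SNPs.
#' @return character vector of index SNP ids (empty when nothing is
#'   significant).
#' @export
selectIndexSnps <- function(summary, p_threshold, r2_max = 0.1,
                            window_kb = 500, genotypes_reference) {
  cand <- summary[is.finite(summary$p_value) &
                    summary$p_value < p_threshold, , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  cand <- cand[order(cand$p_value), , drop = FALSE]
  ref <- dosages(genotypes_reference)
  refsnps <- snpInfo(genotypes_reference)
  active <- rep(TRUE, nrow(cand))
  index <- character(0)
  for (i in seq_len(nrow(cand))) {
    if (!active[i]) next
    index <- c(index, cand$id[i])
    near <- which(active & cand$chr == cand$chr[i] &
                    abs(cand$pos - cand$pos[i]) <= window_kb * 1000)
    near <- setdiff(near, i)
    if (length(near)) {
      xi <- ref[, match(cand$id[i], refsnps$id)]
      r2 <- vapply(near, function(jj) {
        xj <- ref[, match(cand$id[jj], refsnps$id)]
        suppressWarnings(cor(xi, xj, use = "complete.obs"))^2
      }, numeric(1))
      active[near[!is.na(r2) & r2 > r2_max]] <- FALSE
    }
    active[i] <- FALSE
  }
  index
}

#' Direction-of-effect sign test
#'
#' For the discovery index SNPs below each P-value threshold, counts how
#' often the allele-aligned effect direction agrees in the target study
#' and tests the concordant proportion against 0.5 with a two-sided exact
#' binomial test. Index SNPs absent from the target (or strand-ambiguous)
#' are excluded and counted.
#'
#' @param discovery_index `SummaryStats` of discovery index SNPs.
#' @param target `SummaryStats` of the target cohort.
#' @param thresholds P-value cutoffs (default 1e-3, 1e-4, 1e-5, 1e-6).
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_index_snps`, `n_excluded`, `n_concordant`,
#'   `proportion_concordant`, `binomial_p_two_sided`.
#' @export
signTest <- function(discovery_index, target,
                     thresholds = c(1e-3, 1e-4, 1e-5, 1e-6)) {
  al <- .align_summary(discovery_index, target)
  rows <- attr(al, "ref_rows")
  res <- lapply(thresholds, function(thr) {
    sel <- which(is.finite(discovery_index$p_value) &
                   discovery_index$p_value < thr)
    used <- intersect(sel, rows)
    conc <- sum(sign(discovery_index$beta[used]) ==
                  sign(al$beta[match(used, rows)]))
    n <- length(used)
    pv <- if (n > 0) binom.test(conc, n, 0.5)$p.value else NA_real_
    data.frame(threshold = thr, n_index_snps = n,
               n_excluded = length(sel) - n, n_concordant = conc,
               proportion_concordant = if (n > 0) conc / n else NA_real_,
               binomial_p_two_sided = pv)
  })
  do.call(rbind, res)
}

#' Genome-wide significant regions
#'
#' Merges SNPs below `alpha` into regions when consecutive significant
#' SNPs on a chromosome lie within `merge_kb`; each region reports its
#' index SNP (minimum P), bounds and SNP count.
#'
#' @param meta a `MetaResult` or `SummaryStats` data.frame.
#' @param alpha genome-wide significance threshold (default 5e-8).
#' @param merge_kb merge distance in kilobases (default 250).
#' @return data.frame of regions (possibly empty): `chr`, `start`, `end`,
#'   `n_snps`, `index_snp`, `min_p`.
#' @export
genomeWideRegions <- function(meta, alpha = 5e-8, merge_kb = 250) {
  sig <- meta[is.finite(meta$p_value) & meta$p_value < alpha, , drop = FALSE]
  out <- data.frame(chr = integer(0), start = integer(0), end = integer(0),
                    n_snps = integer(0), index_snp = character(0),
                    min_p = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(out)
  sig <- sig[order(sig$chr, sig$pos), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(sig$pos) > merge_kb * 1000 |
                    diff(as.integer(factor(sig$chr))) != 0))
  for (g in unique(grp)) {
    r <- sig[grp == g, , drop = FALSE]
    out <- rbind(out, data.frame(
      chr = r$chr[1], start = min(r$pos), end = max(r$pos),
      n_snps = nrow(r), index_snp = r$id[which.min(r$p_value)],
      min_p = min(r$p_value), stringsAsFactors = FALSE))
  }
  out
}
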