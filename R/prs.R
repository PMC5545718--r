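# Polygenic risk scoring across P-value thresholds and covariate-adjusted
# Nagelkerke delta-R2 tests for case-control and case-case contrasts.

#' Compute polygenic scores across P-value thresholds
#'
#' For each threshold pT, sums effect-weighted dosages over discovery SNPs
#' with P < pT after aligning target dosages to the discovery effect
#' allele (flipping 2 - dosage for swapped alleles; dropping
#' strand-ambiguous and unmatched SNPs). Weights are the discovery
#' log-odds (default) or 1 per allele (`weighting = "unit"`). Missing
#' dosages are imputed as twice the target allele frequency.
#'
#' @param target a [GenotypeData-class].
#' @param discovery a `SummaryStats` data.frame.
#' @param thresholds ordered P-value cutoffs (default 0.001, 0.01, 0.05,
#'   0.1, 0.2, 0.5, 1.0).
#' @param weighting `"logodds"` or `"unit"`.
#' @return list of class `ScoreProfile`: `scores` (individuals x
#'   thresholds), `n_snps_used` per threshold, `thresholds`.
#' @export
computeScores <- function(target, discovery,
                          thresholds = c(0.001, 0.01, 0.05, 0.1, 0.2,
                                         0.5, 1.0),
                          weighting = c("logodds", "unit")) {
  weighting <- match.arg(weighting)
  thresholds <- sort(thresholds)
  tsnps <- snpInfo(target)
  ref <- data.frame(id = tsnps$id, effect_allele = tsnps$A1,
                    other_allele = tsnps$A2, stringsAsFactors = FALSE)
  al <- .align_summary(ref, discovery)      # discovery in target orientation
  rows <- attr(al, "ref_rows")              # columns of the target matrix
  if (!nrow(al)) stop("no alignable SNPs between target and discovery")
  d <- dosages(target)[, rows, drop = FALSE]
  freq <- colMeans(d, na.rm = TRUE) / 2
  for (j in seq_len(ncol(d))) {
    mj <- is.na(d[, j])
    if (any(mj)) d[mj, j] <- 2 * freq[j]
  }
  w <- if (weighting == "logodds") al$beta else rep(1, nrow(al))
  ok <- is.finite(al$p_value) & is.finite(w)
  scores <- matrix(0, nrow(d), length(thresholds),
                   dimnames = list(sampleIds(target),
                                   paste0("pT_", thresholds)))
  nused <- integer(length(thresholds))
  for (t in seq_along(thresholds)) {
    sel <- ok & al$p_value < thresholds[t]
    nused[t] <- sum(sel)
    if (any(sel))
      scores[, t] <- drop(d[, sel, drop = FALSE] %*% w[sel])
  }
  structure(list(scores = scores, n_snps_used = nused,
                 thresholds = thresholds),
            class = "ScoreProfile")
}

#' Nagelkerke delta-R2 of a polygenic score
#'
#' Nagelkerke's R2 of a logistic model is
#' \[1 - exp((2/n)(l0 - l1))\] / \[1 - exp((2/n) l0)\] with l0 the
#' intercept-only log-likelihood. The returned delta is the R2 of
#' covariates + score minus the R2 of covariates alone.
#'
#' @param phenotype binary 0/1 vector.
#' @param score numeric score vector.
#' @param covariates optional covariate matrix.
#' @return delta R2, with attribute `"r2"` holding both model R2 values.
#' @export
nagelkerkeDeltaR2 <- function(phenotype, score, covariates = NULL) {
  stopifnot(all(phenotype %in% 0:1))
  n <- length(phenotype)
  pbar <- mean(phenotype)
  ll0 <- sum(phenotype) * log(pbar) + sum(1 - phenotype) * log(1 - pbar)
  llm <- function(X) {
    fit <- suppressWarnings(glm.fit(X, phenotype, family = binomial()))
    if (!fit$converged) stop("logistic fit did not converge")
    p <- fit$fitted.values
    sum(phenotype * log(p) + (1 - phenotype) * log(1 - p))
  }
  r2 <- function(ll) (1 - exp(2 / n * (ll0 - ll))) / (1 - exp(2 / n * ll0))
  Xc <- cbind(rep(1, n), covariates)
  r2_cov <- if (ncol(Xc) > 1) r2(llm(Xc)) else 0
  r2_full <- r2(llm(cbind(Xc, score)))
  structure(r2_full - r2_cov, r2 = c(covariates = r2_cov, full = r2_full))
}

.prs_test <- function(y, scores, covariates, group_hi, group_lo) {
  out <- lapply(seq_along(scores$thresholds), function(t) {
    s <- scores$scores[, t]
    n <- length(y)
    X <- cbind(rep(1, n), covariates, score = s)
    if (var(s) == 0) {
      return(data.frame(threshold = scores$thresholds[t],
                        n_snps_used = scores$n_snps_used[t],
                        t_statistic = NA_real_, p_value = NA_real_,
                        delta_nagelkerke_r2 = 0,
                        direction = NA_character_,
                        n_group_1 = sum(y == 1), n_group_0 = sum(y == 0)))
    }
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    k <- ncol(X)
    Vb <- solve(crossprod(X * sqrt(fit$weights)))
    tstat <- fit$coefficients[k] / sqrt(Vb[k, k])
    dr2 <- as.numeric(nagelkerkeDeltaR2(y, s, covariates))
    data.frame(threshold = scores$thresholds[t],
               n_snps_used = scores$n_snps_used[t],
               t_statistic = tstat,
               p_value = 2 * pnorm(-abs(tstat)),
               delta_nagelkerke_r2 = dr2,
               direction = if (tstat >= 0) group_hi else group_lo,
               n_group_1 = sum(y == 1), n_group_0 = sum(y == 0))
  })
  do.call(rbind, out)
}

#' Case-control polygenic score test
#'
#' Per threshold: logistic regression of case status on the score plus
#' covariates (typically site indicators and MDS components); reports the
#' score coefficient's t-statistic (coefficient / SE), Wald P, and the
#' Nagelkerke delta-R2 over covariates alone.
#'
#' @param scores a `ScoreProfile` from [computeScores()].
#' @param phenotypes phenotype table aligned with the score rows
#'   (`status` column), or a binary 0/1 vector.
#' @param covariates optional covariate matrix.
#' @return `PrsTestResult` data.frame, one row per threshold.
#' @export
prsCaseControlTest <- function(scores, phenotypes, covariates = NULL) {
  y <- if (is.data.frame(phenotypes))
    as.integer(phenotypes$status == "case") else as.integer(phenotypes)
  if (!any(y == 1) || !any(y == 0)) stop("both groups must be non-empty")
  .prs_test(y, scores, covariates, "case", "control")
}

#' Case-case polygenic score subtype contrast
#'
#' Logistic regression of subtype membership (subtype_a = 1, subtype_b =
#' 0) on the score plus covariates, restricted to cases of the two
#' subtypes; the direction reports which subtype carries the higher
#' scores.
#'
#' @param scores a `ScoreProfile` (rows covering at least the two subtype
#'   groups).
#' @param phenotypes phenotype table with `sample_id` and `subtype`.
#' @param subtype_a,subtype_b the two disjoint subtype labels.
#' @param covariates optional covariate matrix (rows aligned with
#'   `phenotypes`).
#' @return `PrsTestResult` data.frame, one row per threshold.
#' @export
prsCaseCaseTest <- function(scores, phenotypes, subtype_a, subtype_b,
                            covariates = NULL) {
  sel <- phenotypes$subtype %in% c(subtype_a, subtype_b)
  if (!any(phenotypes$subtype == subtype_a) ||
      !any(phenotypes$subtype == subtype_b))
    stop("both subtypes must be non-empty")
  idx <- match(phenotypes$sample_id[sel], rownames(scores$scores))
  if (anyNA(idx)) stop("phenotype individuals missing from the scores")
  sub <- scores
  sub$scores <- scores$scores[idx, , drop = FALSE]
  y <- as.integer(phenotypes$subtype[sel] == subtype_a)
  cv <- if (is.null(covariates)) NULL else covariates[sel, , drop = FALSE]
  .prs_test(y, sub, cv, subtype_a, subtype_b)
}
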