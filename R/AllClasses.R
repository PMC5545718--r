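#' @import methods
#' @importFrom stats var cor sd median qnorm pnorm dnorm qchisq pchisq rnorm
#'   runif rbinom rbeta binom.test t.test setNames cmdscale as.dist glm
#'   glm.fit lm.fit binomial coef
#' @importFrom withr with_seed
#' @importFrom jsonlite write_json
NULL

#' Genotype matrix with per-SNP and per-sample metadata
#'
#' Container for additive allele dosages (individuals x SNPs, values 0/1/2
#' or `NA` for missing) together with the SNP map and sample table. Dosages
#' count copies of the A1 allele, following the PLINK convention in which A1
#' is the counted/effect allele throughout.
#'
#' @slot dosages numeric or integer matrix, individuals in rows, SNPs in
#'   columns; `NA` encodes a missing call.
#' @slot snps data.frame with columns `id`, `chr`, `pos`, `A1`, `A2` and
#'   optionally `freq_true` (simulation truth), `info_score`,
#'   `imputation_r2`.
#' @slot samples data.frame with column `sample_id` and optional extra
#'   columns (for example `population` for simulated divergent cohorts).
#'
#' @export
setClass("GenotypeData",
  slots = c(dosages = "matrix", snps = "data.frame", samples = "data.frame"))

setValidity("GenotypeData", function(object) {
  d <- object@dosages
  msg <- character()
  if (nrow(d) != nrow(object@samples))
    msg <- c(msg, "nrow(dosages) must equal nrow(samples)")
  if (ncol(d) != nrow(object@snps))
    msg <- c(msg, "ncol(dosages) must equal nrow(snps)")
  req <- c("id", "chr", "pos", "A1", "A2")
  if (!all(req %in% names(object@snps)))
    msg <- c(msg, paste("snps must have columns:", paste(req, collapse = ", ")))
  else {
    if (anyDuplicated(object@snps$id))
      msg <- c(msg, "duplicate SNP ids")
    ord <- order(object@snps$chr, object@snps$pos)
    if (is.unsorted(ord) && !identical(ord, seq_len(nrow(object@snps))))
      msg <- c(msg, "positions must be non-decreasing within chromosome")
    if (any(object@snps$A1 == object@snps$A2))
      msg <- c(msg, "A1 and A2 must differ")
  }
  if (!"sample_id" %in% names(object@samples))
    msg <- c(msg, "samples must have a sample_id column")
  else if (anyDuplicated(object@samples$sample_id))
    msg <- c(msg, "duplicate sample ids")
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosages individuals x SNPs dosage matrix (0/1/2/NA, or fractional
#'   dosages in \[0, 2\] for imputed data).
#' @param snps per-SNP data.frame (`id`, `chr`, `pos`, `A1`, `A2`, ...).
#' @param samples per-sample data.frame (`sample_id`, ...) or a character
#'   vector of sample ids.
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosages, snps, samples) {
  if (is.character(samples)) samples <- data.frame(sample_id = samples)
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- snps$id
  rownames(snps) <- NULL
  rownames(samples) <- NULL
  new("GenotypeData", dosages = dosages, snps = snps, samples = samples)
}

#' Genetic relationship matrix
#'
#' Symmetric matrix of allele-frequency-standardized genome-wide genotype
#' similarity between individuals, with the per-pair count of SNPs that
#' entered each entry.
#'
#' @slot values symmetric numeric matrix (individuals x individuals).
#' @slot nSnpsUsed integer matrix of per-pair non-missing SNP counts.
#' @slot sampleIds character vector of individual ids.
#' @export
setClass("GRM",
  slots = c(values = "matrix", nSnpsUsed = "matrix", sampleIds = "character"))

setValidity("GRM", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (length(object@sampleIds) != nrow(v))
    msg <- c(msg, "sampleIds length must match matrix dimension")
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "duplicate sample ids")
  if (any(!is.finite(v))) msg <- c(msg, "non-finite GRM entries")
  else if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "values must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Univariate REML variance components
#'
#' @slot sigmaG2 additive genetic variance on the analysis (observed) scale.
#' @slot sigmaE2 residual variance.
#' @slot samplingCov 2x2 sampling covariance of (sigmaG2, sigmaE2) from the
#'   inverse average-information matrix.
#' @slot logLik restricted log-likelihood at the optimum (constant terms
#'   omitted).
#' @slot nIterations iterations used.
#' @slot converged logical convergence flag.
#' @slot trajectory restricted log-likelihood after each iteration.
#' @export
setClass("VarianceComponents",
  slots = c(sigmaG2 = "numeric", sigmaE2 = "numeric",
            samplingCov = "matrix", logLik = "numeric",
            nIterations = "integer", converged = "logical",
            trajectory = "numeric"))

#' Bivariate REML variance components
#'
#' Components of the stacked two-trait model on disjoint individual sets:
#' per-trait genetic and residual variances plus the genetic covariance.
#' The residual covariance is structurally zero because no individual
#' carries both traits.
#'
#' @slot varG1,varG2 per-trait genetic variances.
#' @slot covG12 genetic covariance between the traits.
#' @slot varE1,varE2 per-trait residual variances.
#' @slot samplingCov 5x5 sampling covariance of
#'   (varG1, varG2, covG12, varE1, varE2).
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot nIterations iterations used.
#' @slot converged logical convergence flag.
#' @slot trajectory restricted log-likelihood after each iteration.
#' @export
setClass("BivariateComponents",
  slots = c(varG1 = "numeric", varG2 = "numeric", covG12 = "numeric",
            varE1 = "numeric", varE2 = "numeric", samplingCov = "matrix",
            logLik = "numeric", nIterations = "integer",
            converged = "logical", trajectory = "numeric"))

#' SNP heritability estimate on observed and liability scales
#'
#' @slot h2Observed,seObserved estimate and standard error on the observed
#'   (0/1 analysis) scale.
#' @slot h2Liability,seLiability estimate and standard error after the
#'   liability-scale transformation.
#' @slot prevalence population prevalence K assumed for the transformation.
#' @slot caseProportion proportion of cases P in the analysed sample.
#' @slot zDensity standard normal density at the liability threshold.
#' @export
setClass("HeritabilityEstimate",
  slots = c(h2Observed = "numeric", seObserved = "numeric",
            h2Liability = "numeric", seLiability = "numeric",
            prevalence = "numeric", caseProportion = "numeric",
            zDensity = "numeric"))

#' Genetic correlation estimate
#'
#' @slot rg genetic correlation sigma_g12 / sqrt(sigma_g1^2 sigma_g2^2).
#' @slot se delta-method standard error.
#' @slot source `"subtype_pair"` or `"mixed_pair"`.
#' @export
setClass("GeneticCorrelationEstimate",
  slots = c(rg = "numeric", se = "numeric", source = "character"))

setValidity("GeneticCorrelationEstimate", function(object) {
  if (!object@source %in% c("subtype_pair", "mixed_pair", "unspecified"))
    "source must be subtype_pair, mixed_pair or unspecified" else TRUE
})
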