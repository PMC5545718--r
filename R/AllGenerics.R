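# Accessor generics and show methods for the central S4 containers.

#' @rdname GenotypeData-class
#' @param object,x a `GenotypeData` object
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname GenotypeData-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname GenotypeData-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname GenotypeData-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname GenotypeData-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GenotypeData-class
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)
#' @rdname GenotypeData-class
#' @export
setMethod("snpInfo", "GenotypeData", function(x) x@snps)
#' @rdname GenotypeData-class
#' @export
setMethod("sampleIds", "GenotypeData", function(x) x@samples$sample_id)
#' @rdname GenotypeData-class
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@dosages))
#' @rdname GenotypeData-class
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@dosages))

#' @rdname GenotypeData-class
#' @param i sample index (integer, logical or sample ids)
#' @param j SNP index (integer, logical or SNP ids)
#' @param drop ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (missing(j)) j <- seq_len(nSnps(x))
  if (is.character(i)) i <- match(i, x@samples$sample_id)
  if (is.character(j)) j <- match(j, x@snps$id)
  GenotypeData(x@dosages[i, j, drop = FALSE],
               x@snps[j, , drop = FALSE],
               x@samples[i, , drop = FALSE])
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nSamples(object), "individuals x",
      nSnps(object), "SNPs\n")
  nm <- sum(is.na(object@dosages))
  cat(sprintf("  missing calls: %d (%.3f%%)\n", nm,
              100 * nm / length(object@dosages)))
  extra <- setdiff(names(object@snps), c("id", "chr", "pos", "A1", "A2"))
  if (length(extra)) cat("  SNP metadata:", paste(extra, collapse = ", "), "\n")
})

#' @rdname GRM-class
#' @param x a `GRM` object
#' @export
setGeneric("grmValues", function(x) standardGeneric("grmValues"))
#' @rdname GRM-class
#' @export
setMethod("grmValues", "GRM", function(x) x@values)
#' @rdname GRM-class
#' @export
setGeneric("grmSnpCounts", function(x) standardGeneric("grmSnpCounts"))
#' @rdname GRM-class
#' @export
setMethod("grmSnpCounts", "GRM", function(x) x@nSnpsUsed)
#' @rdname GRM-class
#' @export
setMethod("sampleIds", "GRM", function(x) x@sampleIds)

#' @rdname GRM-class
#' @param i,j individual index (integer, logical or ids); `j` must be
#'   missing or equal to `i` -- a GRM subset keeps both dimensions aligned
#' @param drop ignored
#' @export
setMethod("[", "GRM", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleIds)
  if (anyNA(i)) stop("unknown sample ids in GRM subset")
  new("GRM", values = x@values[i, i, drop = FALSE],
      nSnpsUsed = x@nSnpsUsed[i, i, drop = FALSE],
      sampleIds = x@sampleIds[i])
})

setMethod("show", "GRM", function(object) {
  n <- nrow(object@values)
  off <- object@values[upper.tri(object@values)]
  cat("GRM:", n, "individuals\n")
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.5f, max off-diagonal %.4f\n",
              mean(diag(object@values)), mean(off), if (length(off)) max(off) else NA))
})

setMethod("show", "VarianceComponents", function(object) {
  se <- sqrt(pmax(diag(object@samplingCov), 0))
  cat("REML variance components (observed scale)\n")
  cat(sprintf("  sigma_g^2 = %.4f (se %.4f)\n", object@sigmaG2, se[1]))
  cat(sprintf("  sigma_e^2 = %.4f (se %.4f)\n", object@sigmaE2, se[2]))
  h <- h2Observed(object)
  cat(sprintf("  h2_observed = %.4f (se %.4f)\n", h$estimate, h$se))
  cat(sprintf("  logLik %.4f after %d iterations; converged: %s\n",
              object@logLik, object@nIterations, object@converged))
})

setMethod("show", "BivariateComponents", function(object) {
  cat("Bivariate REML components\n")
  cat(sprintf("  varG1 %.4f  varG2 %.4f  covG12 %.4f\n",
              object@varG1, object@varG2, object@covG12))
  cat(sprintf("  varE1 %.4f  varE2 %.4f\n", object@varE1, object@varE2))
  cat(sprintf("  rg = %.4f\n", object@covG12 / sqrt(object@varG1 * object@varG2)))
  cat(sprintf("  logLik %.4f after %d iterations; converged: %s\n",
              object@logLik, object@nIterations, object@converged))
})

setMethod("show", "HeritabilityEstimate", function(object) {
  cat("SNP heritability estimate\n")
  cat(sprintf("  observed scale : %.4f (se %.4f)\n",
              object@h2Observed, object@seObserved))
  cat(sprintf("  liability scale: %.4f (se %.4f)  [K=%.4g, P=%.4g]\n",
              object@h2Liability, object@seLiability,
              object@prevalence, object@caseProportion))
})

setMethod("show", "GeneticCorrelationEstimate", function(object) {
  cat(sprintf("rg = %.4f (se %.4f) [%s]\n",
              object@rg, object@se, object@source))
})

#' Observed-scale heritability from fitted variance components
#'
#' Computes sigma_g^2 / (sigma_g^2 + sigma_e^2) with a delta-method
#' standard error from the sampling covariance of the components.
#'
#' @param vc a [VarianceComponents-class] object
#' @return list with `estimate` and `se`
#' @export
h2Observed <- function(vc) {
  s <- vc@sigmaG2 + vc@sigmaE2
  h2 <- vc@sigmaG2 / s
  grad <- c(vc@sigmaE2, -vc@sigmaG2) / s^2
  se <- sqrt(max(0, drop(t(grad) %*% vc@samplingCov %*% grad)))
  list(estimate = h2, se = se)
}

#' Genetic correlation implied by bivariate components
#'
#' @param bc a [BivariateComponents-class] object
#' @param source label recorded in the estimate
#'   (`"subtype_pair"`, `"mixed_pair"` or `"unspecified"`)
#' @return a [GeneticCorrelationEstimate-class]
#' @export
rgEstimate <- function(bc, source = "unspecified") {
  g1 <- bc@varG1; g2 <- bc@varG2; g12 <- bc@covG12
  rg <- g12 / sqrt(g1 * g2)
  grad <- c(-rg / (2 * g1), -rg / (2 * g2), 1 / sqrt(g1 * g2))
  C <- bc@samplingCov[1:3, 1:3]
  se <- sqrt(max(0, drop(t(grad) %*% C %*% grad)))
  new("GeneticCorrelationEstimate", rg = rg, se = se, source = source)
}
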