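# Identity-by-state distances, classical MDS for ancestry, ancestry
# outlier detection, and method-of-moments IBD (PIHAT) relatedness.

# Pairwise genotype-combination counts via indicator cross-products; the
# workhorse for both IBS distances and IBD moment estimation.
.genotype_pair_counts <- function(d) {
  I0 <- (!is.na(d) & d == 0) + 0
  I1 <- (!is.na(d) & d == 1) + 0
  I2 <- (!is.na(d) & d == 2) + 0
  M <- (!is.na(d)) + 0
  list(
    nonmiss = tcrossprod(M),
    ibs2 = tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2),
    ibs1 = tcrossprod(I0, I1) + tcrossprod(I1, I0) +
      tcrossprod(I1, I2) + tcrossprod(I2, I1),
    ibs0 = tcrossprod(I0, I2) + tcrossprod(I2, I0))
}

#' Identity-by-state multidimensional scaling
#'
#' Computes the pairwise IBS similarity (mean over jointly non-missing SNPs
#' of 1 - |x_i - x_j| / 2), converts it to the distance 1 - IBS, and
#' extracts the leading components by classical (Torgerson) MDS --
#' eigendecomposition of the double-centred squared-distance matrix.
#' Components are ordered by eigenvalue and defined up to sign.
#'
#' @param genotypes a [GenotypeData-class]; an LD-pruned SNP set is
#'   recommended (not enforced).
#' @param n_components number of components to return.
#' @return matrix (individuals x components) with sample ids as row names
#'   and the MDS eigenvalues in attribute `"eigenvalues"`.
#' @export
ibsMDS <- function(genotypes, n_components = 10L) {
  d <- dosages(genotypes)
  n <- nrow(d)
  if (n < n_components)
    stop("fewer individuals than requested components")
  cnt <- .genotype_pair_counts(d)
  # sum |xi - xj| = 1*IBS1-pairs + 2*IBS0-pairs
  ibs <- 1 - (cnt$ibs1 + 2 * cnt$ibs0) / (2 * pmax(cnt$nonmiss, 1))
  dist <- 1 - ibs
  fit <- cmdscale(stats::as.dist(dist), k = n_components, eig = TRUE)
  comp <- fit$points
  if (ncol(comp) < n_components)  # degenerate geometry: pad with zeros
    comp <- cbind(comp, matrix(0, n, n_components - ncol(comp)))
  rownames(comp) <- sampleIds(genotypes)
  colnames(comp) <- paste0("C", seq_len(ncol(comp)))
  attr(comp, "eigenvalues") <- fit$eig
  comp
}

#' Ancestry outlier detection on MDS components
#'
#' Flags any individual whose value on one of the leading components (at
#' most ten) deviates from the component mean by more than `k_sd` standard
#' deviations. Constant components are skipped.
#'
#' @param mds_components matrix from [ibsMDS()].
#' @param k_sd deviation bound in SD units (default 6).
#' @return character vector of flagged sample ids.
#' @export
detectAncestryOutliers <- function(mds_components, k_sd = 6) {
  if (nrow(mds_components) < 10) stop("need at least 10 individuals")
  use <- seq_len(min(10L, ncol(mds_components)))
  flagged <- rep(FALSE, nrow(mds_components))
  for (j in use) {
    v <- mds_components[, j]
    s <- sd(v)
    if (!is.finite(s) || s == 0) next
    flagged <- flagged | abs(v - mean(v)) > k_sd * s
  }
  rownames(mds_components)[flagged]
}

#' Method-of-moments IBD estimation and PIHAT relatedness filter
#'
#' Estimates P(IBD = 0, 1, 2) for every pair from genome-wide IBS counts
#' given sample allele frequencies (the standard moment equations), forms
#' PIHAT = P(IBD=2) + P(IBD=1) / 2 truncated to \[0, 1\], and greedily
#' removes one member of each pair with PIHAT above `pihat_max` -- the
#' member with the higher missingness, ties broken toward the
#' lexicographically larger id.
#'
#' @param genotypes a [GenotypeData-class]; monomorphic SNPs are excluded
#'   from estimation (error if none remain).
#' @param pihat_max relatedness bound (default 0.1).
#' @return list with `retained` (sample ids), `flagged_pairs` (data.frame
#'   id1, id2, pihat) and the full `pihat` matrix.
#' @export
ibdPihatFilter <- function(genotypes, pihat_max = 0.1) {
  d <- dosages(genotypes)
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs for IBD estimation")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]; q <- 1 - p
  m <- ncol(d)
  # per-SNP expected IBS-class probabilities given IBD state, summed
  e0_ibs0 <- sum(2 * p^2 * q^2)
  e0_ibs1 <- sum(4 * p^3 * q + 4 * p * q^3)
  e0_ibs2 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibs1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e1_ibs2 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  cnt <- .genotype_pair_counts(d)
  frac <- cnt$nonmiss / m   # scale expectations to jointly observed SNPs
  P0 <- cnt$ibs0 / (e0_ibs0 * frac)
  P1 <- (cnt$ibs1 - P0 * e0_ibs1 * frac) / (e1_ibs1 * frac)
  P2 <- (cnt$ibs2 - P0 * e0_ibs2 * frac - P1 * e1_ibs2 * frac) /
    pmax(cnt$nonmiss, 1)
  P0 <- pmin(pmax(P0, 0), 1); P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmin(pmax(P2, 0), 1)
  pihat <- pmin(pmax(P2 + 0.5 * P1, 0), 1)
  ids <- sampleIds(genotypes)
  dimnames(pihat) <- list(ids, ids)
  ut <- which(upper.tri(pihat) & pihat > pihat_max, arr.ind = TRUE)
  flagged <- data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                        pihat = pihat[ut], stringsAsFactors = FALSE)
  miss <- setNames(rowMeans(is.na(dosages(genotypes))), ids)
  retained <- ids
  if (nrow(flagged)) {
    for (k in seq_len(nrow(flagged))) {
      a <- flagged$id1[k]; b <- flagged$id2[k]
      if (!(a %in% retained) || !(b %in% retained)) next
      drop <- if (miss[a] > miss[b]) a
      else if (miss[b] > miss[a]) b
      else max(a, b)
      retained <- setdiff(retained, drop)
    }
  }
  list(retained = retained, flagged_pairs = flagged, pihat = pihat)
}
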