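# Genetic relationship matrix: allele-frequency-standardized genome-wide
# similarity, A_jk = (1/m_jk) sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i q_i)
# over SNPs non-missing in both individuals, and the greedy relatedness
# prune that bounds pairwise similarity.

#' Compute a genetic relationship matrix
#'
#' Standardizes each SNP by its sample allele frequency (cases and controls
#' combined) and averages the cross-products over the SNPs jointly
#' non-missing in each pair. The diagonal uses the same standardized
#' formula by default; `diagonal = "gcta"` uses the alternative diagonal
#' estimator 1 + (1/m) sum (x^2 - (1 + 2p) x + 2 p^2) / (2 p q).
#'
#' @param genotypes a [GenotypeData-class] with no monomorphic SNPs
#'   (filter first; error otherwise). Missing dosages are allowed.
#' @param diagonal `"standard"` (default) or `"gcta"`.
#' @return a [GRM-class].
#' @export
computeGRM <- function(genotypes, diagonal = c("standard", "gcta")) {
  diagonal <- match.arg(diagonal)
  d <- dosages(genotypes)
  storage.mode(d) <- "double"
  p <- colMeans(d, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNPs present; filter before computing the GRM")
  sdv <- sqrt(2 * p * (1 - p))
  W <- sweep(d, 2, 2 * p, "-")
  W <- sweep(W, 2, sdv, "/")
  miss <- is.na(W)
  W[miss] <- 0
  M <- 1 - miss
  mjk <- tcrossprod(M)
  A <- tcrossprod(W) / pmax(mjk, 1)
  if (diagonal == "gcta") {
    num <- d^2 - sweep(d, 2, 1 + 2 * p, "*")
    num <- sweep(num, 2, 2 * p^2, "+")
    num <- sweep(num, 2, 2 * p * (1 - p), "/")
    num[miss] <- 0
    diag(A) <- 1 + rowSums(num) / pmax(diag(mjk), 1)
  }
  A <- (A + t(A)) / 2
  new("GRM", values = A, nSnpsUsed = mjk, sampleIds = sampleIds(genotypes))
}

#' Prune individuals by pairwise genetic relationship
#'
#' Greedily removes the individual participating in the most pairs with
#' relationship above `cutoff` (ties broken toward the later sample id)
#' until no off-diagonal entry exceeds the cutoff.
#'
#' @param grm a [GRM-class].
#' @param cutoff relationship bound (default 0.05; must be positive).
#' @return character vector of retained sample ids.
#' @export
grmRelatednessPrune <- function(grm, cutoff = 0.05) {
  if (cutoff <= 0) stop("cutoff must be positive")
  A <- grmValues(grm)
  diag(A) <- -Inf
  keep <- rep(TRUE, nrow(A))
  repeat {
    over <- A > cutoff & outer(keep, keep)
    deg <- rowSums(over)
    if (all(deg == 0)) break
    worst <- max(which(deg == max(deg)))   # tie -> higher id removed
    keep[worst] <- FALSE
  }
  sampleIds(grm)[keep]
}
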