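# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; oracles deliberately use naive formulations (double
# loops, dense solves, full enumeration) independent of the package's
# computational paths.

# small genotype container from a plain dosage matrix
make_geno <- function(d, chr = NULL, pos = NULL, A1 = "A", A2 = "G",
                      freq_true = NULL) {
  m <- ncol(d)
  snps <- data.frame(id = sprintf("s%04d", seq_len(m)),
                     chr = if (is.null(chr)) rep(1L, m) else chr,
                     pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
                     A1 = rep_len(A1, m), A2 = rep_len(A2, m),
                     stringsAsFactors = FALSE)
  if (!is.null(freq_true)) snps$freq_true <- freq_true
  GenotypeData(d, snps, sprintf("i%04d", seq_len(nrow(d))))
}

# HWE genotypes at given frequencies
make_hwe_geno <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    d <- matrix(rbinom(n * length(p), 2L, rep(p, each = n)), n, length(p))
  })
  make_geno(d, freq_true = p)
}

# naive double-loop GRM (oracle)
naive_grm <- function(d) {
  p <- colMeans(d, na.rm = TRUE) / 2
  n <- nrow(d)
  A <- matrix(0, n, n); cnt <- matrix(0L, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0; m <- 0L
    for (i in seq_len(ncol(d))) {
      if (is.na(d[j, i]) || is.na(d[k, i])) next
      s <- s + (d[j, i] - 2 * p[i]) * (d[k, i] - 2 * p[i]) /
        (2 * p[i] * (1 - p[i]))
      m <- m + 1L
    }
    A[j, k] <- if (m > 0) s / m else 0
    cnt[j, k] <- m
  }
  list(values = A, counts = cnt)
}

# naive dense REML log-likelihood (oracle; constant omitted, matching the
# package's reported value)
naive_reml_ll <- function(V, X, y) {
  Vi <- solve(V)
  C <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(C, t(X) %*% Vi)
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(C)$modulus) +
            drop(t(y) %*% P %*% y))
}

# grid-search REML oracle for the univariate model (two-stage refinement)
grid_reml_univariate <- function(A, y, res = 1e-3) {
  n <- length(y); X <- matrix(1, n, 1)
  Vp <- var(y)
  ll_fun <- function(sg, se) {
    V <- sg * A + diag(se, n)
    out <- tryCatch(naive_reml_ll(V, X, y), error = function(e) -Inf)
    if (!is.finite(out)) -Inf else out
  }
  best <- c(Vp / 2, Vp / 2)
  stages <- list(c(Vp / 10, 1.3 * Vp), c(0.01, 0.15), c(res, 0.015))
  for (st in stages) {
    sp <- st[1]; half <- st[2]
    sg <- seq(max(0, best[1] - half), best[1] + half, by = sp)
    se <- seq(max(res, best[2] - half), best[2] + half, by = sp)
    gr <- as.matrix(expand.grid(sg = sg, se = se))
    ll <- apply(gr, 1, function(r) ll_fun(r[1], r[2]))
    best <- gr[which.max(ll), ]
  }
  best
}

# grid-search oracle over the three genetic parameters of the bivariate
# model (residual variances held fixed), refined to `res`
grid_reml_bivariate <- function(A, n1, n2, y, e1, e2, start = NULL,
                                res = 1e-3) {
  n <- n1 + n2
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  X <- matrix(0, n, 2); X[i1, 1] <- 1; X[i2, 2] <- 1
  ll_fun <- function(g1, g2, g12) {
    V <- matrix(0, n, n)
    V[i1, i1] <- g1 * A[i1, i1] + diag(e1, n1)
    V[i2, i2] <- g2 * A[i2, i2] + diag(e2, n2)
    V[i1, i2] <- g12 * A[i1, i2]
    V[i2, i1] <- t(V[i1, i2])
    out <- tryCatch(naive_reml_ll(V, X, y), error = function(e) -Inf)
    if (!is.finite(out)) -Inf else out
  }
  Vp <- c(var(y[i1]), var(y[i2]))
  best <- if (is.null(start)) c(Vp[1] / 2, Vp[2] / 2, 0) else start
  mv <- max(Vp)
  stages <- list(c(mv / 8, 1.3 * mv), c(0.02, 0.2), c(5e-3, 0.03),
                 c(res, 0.0075))
  for (st in stages) {
    sp <- st[1]; half <- st[2]
    gr <- as.matrix(expand.grid(
      g1 = seq(max(0, best[1] - half), best[1] + half, by = sp),
      g2 = seq(max(0, best[2] - half), best[2] + half, by = sp),
      g12 = seq(best[3] - half, best[3] + half, by = sp)))
    # same parameter space as the fit: implied |rg| <= 1
    gr <- gr[gr[, 3]^2 <= gr[, 1] * gr[, 2], , drop = FALSE]
    ll <- apply(gr, 1, function(r) ll_fun(r[1], r[2], r[3]))
    best <- gr[which.max(ll), ]
  }
  unname(unlist(best))
}

# continuous phenotype with a given observed-scale h2 on simulated genotypes
make_h2_trait <- function(n, m, h2, seed, n_causal = max(2L, round(m / 5))) {
  cfg <- simConfig(nIndividuals = n, nSnps = m, nCausal = n_causal,
                   h2Liab1 = h2, h2Liab2 = h2, rhoEffects = 1,
                   targetCases1 = 0, targetCases2 = 0, targetControls = 1,
                   seed = seed)
  g <- simulateGenotypes(cfg)
  eff <- simulateSubtypeEffects(cfg, g)
  p <- snpInfo(g)$freq_true
  idx <- eff$causal_indices
  Xs <- scale(dosages(g)[, idx, drop = FALSE], center = 2 * p[idx],
              scale = sqrt(2 * p[idx] * (1 - p[idx])))
  gv <- drop(Xs %*% eff$beta_1)
  y <- withr::with_seed(seed + 5000L, gv + rnorm(n, 0, sqrt(1 - h2)))
  list(genotypes = g, y = setNames(y, sampleIds(g)), genetic = gv)
}

# full-enumeration HWE exact test oracle
enum_hwe_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nr <- min(nA, 2 * n - nA)
  hets <- seq(nr %% 2, nr, by = 2)
  pr <- vapply(hets, function(h) {
    hom_r <- (nr - h) / 2
    hom_c <- (2 * n - nr - h) / 2
    exp(lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) -
          lgamma(hom_c + 1) + h * log(2) +
          lgamma(nr + 1) + lgamma(2 * n - nr + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# a small deterministic summary-stats table
make_sumstats <- function(beta, se, p = NULL, ids = NULL,
                          A1 = "A", A2 = "G", chr = 1L, pos = NULL) {
  m <- length(beta)
  data.frame(id = if (is.null(ids)) sprintf("s%04d", seq_len(m)) else ids,
             chr = rep_len(chr, m),
             pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
             effect_allele = rep_len(A1, m), other_allele = rep_len(A2, m),
             effect_allele_freq = rep(0.3, m), beta = beta, se = se,
             p_value = if (is.null(p)) 2 * pnorm(-abs(beta / se)) else p,
             n = rep(1000L, m), stringsAsFactors = FALSE)
}
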