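# GREML: restricted maximum likelihood variance components on a GRM.
# Univariate fits use the eigendecomposition of the GRM, under which every
# REML quantity is O(n) per iteration; the bivariate fit on disjoint
# individual sets works with the dense stacked covariance. Both follow the
# same schedule: one EM step, then average-information (AI) updates with
# step-halving, non-negativity by projection, and SEs from the inverse AI
# matrix. The restricted log-likelihood is reported without its constant.

.align_pheno <- function(grm, phenotype) {
  ids <- sampleIds(grm)
  if (!is.null(names(phenotype))) {
    idx <- match(names(phenotype), ids)
    if (anyNA(idx)) stop("phenotype names not all present in the GRM")
  } else {
    if (length(phenotype) != length(ids))
      stop("unnamed phenotype must cover every GRM individual")
    idx <- seq_along(ids)
  }
  list(idx = idx, y = as.numeric(phenotype))
}

#' Univariate GREML variance-component fit
#'
#' Fits y = X beta + g + e with V = sigma_g^2 A + sigma_e^2 I by REML.
#' One EM step initializes, then average-information updates run to
#' convergence (|delta logLik| < `tol`, at most `maxIter` iterations) with
#' step-halving whenever a step would decrease the restricted likelihood.
#' Variance components are constrained non-negative by projection onto a
#' small positive floor; the case-control 0/1 phenotype is fitted directly
#' on the observed scale (transform afterwards with
#' [liabilityTransform()]).
#'
#' @param grm a [GRM-class].
#' @param phenotype numeric vector; if named, names select (a subset of)
#'   GRM individuals.
#' @param covariates optional numeric matrix of covariates (no intercept
#'   column; one is added).
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param maxIter maximum iterations.
#' @param eigenA optional precomputed `eigen(grmValues(grm), symmetric =
#'   TRUE)` for the *full* GRM -- a performance hook for fitting several
#'   phenotypes on one GRM; only valid when the phenotype covers every
#'   GRM individual.
#' @return a [VarianceComponents-class].
#' @export
fitGremlUnivariate <- function(grm, phenotype, covariates = NULL,
                               tol = 1e-6, maxIter = 100L, eigenA = NULL) {
  al <- .align_pheno(grm, phenotype)
  y <- al$y
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(X)$rank < ncol(X)) stop("singular covariate design")
  if (is.null(eigenA)) {
    A <- grmValues(grm)[al$idx, al$idx, drop = FALSE]
    eg <- eigen(A, symmetric = TRUE)
  } else {
    if (length(al$idx) != length(sampleIds(grm)) ||
        is.unsorted(al$idx, strictly = TRUE))
      stop("eigenA can only be reused when the phenotype covers the full GRM")
    eg <- eigenA
  }
  lam <- eg$values
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, X)
  Vp <- var(y)
  floorv <- 1e-6 * Vp

  eval_point <- function(th) {
    dvec <- th[1] * lam + th[2]
    if (any(dvec < 1e-12 * Vp)) return(NULL)
    XtD <- Xt / dvec
    XtViX <- crossprod(Xt, XtD)
    ch <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Ci <- chol2inv(ch)
    beta <- Ci %*% crossprod(XtD, yt)
    u <- (yt - drop(Xt %*% beta)) / dvec          # P y in the eigenbasis
    yPy <- sum(yt * u)
    ll <- -0.5 * (sum(log(dvec)) + 2 * sum(log(diag(ch))) + yPy)
    list(th = th, dvec = dvec, XtD = XtD, Ci = Ci, u = u, ll = ll)
  }

  derived <- function(st) {
    wg <- lam / st$dvec
    trPg <- sum(wg) - sum(st$Ci * crossprod(Xt, st$XtD * wg))
    trPe <- sum(1 / st$dvec) - sum(st$Ci * crossprod(Xt, st$XtD / st$dvec))
    uGu <- c(sum(lam * st$u^2), sum(st$u^2))
    Pq <- function(q) q / st$dvec -
      st$XtD %*% (st$Ci %*% crossprod(Xt, q / st$dvec))
    q1 <- lam * st$u; q2 <- st$u
    P1 <- Pq(q1); P2 <- Pq(q2)
    AI <- 0.5 * matrix(c(sum(q1 * P1), sum(q1 * P2),
                         sum(q2 * P1), sum(q2 * P2)), 2, 2)
    AI <- (AI + t(AI)) / 2
    grad <- -0.5 * (c(trPg, trPe) - uGu)
    list(AI = AI, grad = grad, uGu = uGu, trPG = c(trPg, trPe))
  }

  th <- c(Vp / 2, Vp / 2)
  st <- eval_point(th)
  if (is.null(st)) stop("REML likelihood not computable at the start value")
  traj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    dv <- derived(st)
    em_step <- th^2 * (dv$uGu - dv$trPG) / n
    ai_step <- tryCatch(drop(solve(dv$AI, dv$grad)),
                        error = function(e) c(0, 0))
    grad_step <- dv$grad * Vp^2 / n
    # AI direction first (EM on the first sweep), then EM, then a scaled
    # gradient step, each with step-halving; stop only when no direction
    # improves the restricted likelihood
    dirs <- if (iter == 1L) list(em_step, ai_step, grad_step)
    else list(ai_step, em_step, grad_step)
    ll_prev <- st$ll
    accepted <- FALSE
    for (step in dirs) {
      if (all(step == 0)) next
      for (h in 0:30) {
        prop <- pmax(th + step / 2^h, floorv)
        cand <- eval_point(prop)
        if (!is.null(cand) && cand$ll > ll_prev + 1e-12) {
          th <- prop; st <- cand; accepted <- TRUE; break
        }
      }
      if (accepted) break
    }
    if (!accepted) { converged <- TRUE; break }   # no uphill step remains
    traj <- c(traj, st$ll)
    if (abs(st$ll - ll_prev) < tol && iter > 1L) { converged <- TRUE; break }
  }
  dv <- derived(st)
  cov <- tryCatch(solve(dv$AI), error = function(e)
    matrix(NA_real_, 2, 2))
  new("VarianceComponents", sigmaG2 = th[1], sigmaE2 = th[2],
      samplingCov = cov, logLik = st$ll, nIterations = iter,
      converged = converged, trajectory = traj)
}

#' Bivariate GREML on disjoint individual sets
#'
#' Fits the stacked two-trait model with covariance
#' V = \[\[A11 vG1 + I vE1, A12 cG12\], \[A21 cG12, A22 vG2 + I vE2\]\];
#' the residual covariance is structurally zero because the traits are
#' measured on disjoint individuals (overlap raises an error). The genetic
#' correlation is constrained to \[-1, 1\] by bounding the covariance
#' parameter at +/- sqrt(vG1 vG2).
#'
#' @param grm a [GRM-class] covering all individuals of both traits.
#' @param pheno1,pheno2 named numeric vectors (names are GRM sample ids).
#' @param covariates1,covariates2 optional per-trait covariate matrices.
#' @param fixCovG optionally fix the genetic covariance at this value
#'   (e.g. 0) instead of estimating it -- a diagnostic mode under which the
#'   fit decouples into the two univariate fits.
#' @param source label passed to the returned correlation estimate.
#' @param tol,maxIter convergence control as in [fitGremlUnivariate()].
#' @return list with `components` ([BivariateComponents-class]) and `rg`
#'   ([GeneticCorrelationEstimate-class]; `NULL` when `fixCovG` is given).
#' @export
fitGremlBivariate <- function(grm, pheno1, pheno2, covariates1 = NULL,
                              covariates2 = NULL, fixCovG = NULL,
                              source = "unspecified",
                              tol = 1e-6, maxIter = 100L) {
  if (is.null(names(pheno1)) || is.null(names(pheno2)))
    stop("pheno1 and pheno2 must be named by sample id")
  if (length(intersect(names(pheno1), names(pheno2))))
    stop("traits must be defined on disjoint individual sets")
  ids <- sampleIds(grm)
  idx <- match(c(names(pheno1), names(pheno2)), ids)
  if (anyNA(idx)) stop("phenotype individuals missing from the GRM")
  A <- grmValues(grm)[idx, idx, drop = FALSE]
  n1 <- length(pheno1); n2 <- length(pheno2); n <- n1 + n2
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  A11 <- A[i1, i1]; A22 <- A[i2, i2]; A12 <- A[i1, i2, drop = FALSE]
  y <- c(as.numeric(pheno1), as.numeric(pheno2))
  X <- matrix(0, n, 2)
  X[i1, 1] <- 1; X[i2, 2] <- 1
  if (!is.null(covariates1) || !is.null(covariates2)) {
    pad <- function(cv, rows) {
      if (is.null(cv)) return(NULL)
      cv <- as.matrix(cv)
      out <- matrix(0, n, ncol(cv)); out[rows, ] <- cv; out
    }
    X <- cbind(X, pad(covariates1, i1), pad(covariates2, i2))
  }
  if (qr(X)$rank < ncol(X)) stop("singular covariate design")
  Vp1 <- var(y[i1]); Vp2 <- var(y[i2])
  floors <- c(1e-6 * Vp1, 1e-6 * Vp2, NA, 1e-6 * Vp1, 1e-6 * Vp2)
  free <- if (is.null(fixCovG)) 1:5 else c(1, 2, 4, 5)

  build_chol <- function(th) {
    V <- matrix(0, n, n)
    V[i1, i1] <- th[1] * A11 + diag(th[4], n1)
    V[i2, i2] <- th[2] * A22 + diag(th[5], n2)
    V[i1, i2] <- th[3] * A12
    V[i2, i1] <- t(th[3] * A12)
    tryCatch(chol(V), error = function(e) NULL)
  }

  # restricted likelihood only -- used inside line searches; returns the
  # Cholesky factor alongside so an accepted step can reuse it
  eval_ll <- function(th) {
    ch <- build_chol(th)
    if (is.null(ch)) return(NULL)
    W <- backsolve(ch, cbind(X, y), transpose = TRUE)
    Wx <- W[, seq_len(ncol(X)), drop = FALSE]
    wy <- W[, ncol(X) + 1L]
    XtViX <- crossprod(Wx)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    Xty <- crossprod(Wx, wy)
    beta <- backsolve(chX, backsolve(chX, Xty, transpose = TRUE))
    yPy <- sum(wy^2) - sum(Xty * beta)
    list(ll = -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                        yPy),
         ch = ch)
  }

  # full state (projection matrix, Py) -- once per accepted step
  eval_point <- function(th, ch = NULL) {
    if (is.null(ch)) ch <- build_chol(th)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    VX <- Vi %*% X
    XtViX <- crossprod(X, VX)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    Ci <- chol2inv(chX)
    P <- Vi - VX %*% tcrossprod(Ci, VX)
    u <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                  sum(y * u))
    list(th = th, P = P, u = u, ll = ll)
  }

  derived <- function(st) {
    P <- st$P; u <- st$u
    u1 <- u[i1]; u2 <- u[i2]
    A11u <- drop(A11 %*% u1); A22u <- drop(A22 %*% u2)
    A12u2 <- drop(A12 %*% u2); A21u1 <- drop(crossprod(A12, u1))
    trPG <- c(sum(P[i1, i1] * A11), sum(P[i2, i2] * A22),
              2 * sum(P[i1, i2] * A12), sum(diag(P)[i1]), sum(diag(P)[i2]))
    uGu <- c(sum(u1 * A11u), sum(u2 * A22u), 2 * sum(u1 * A12u2),
             sum(u1^2), sum(u2^2))
    Q <- cbind(c(A11u, rep(0, n2)), c(rep(0, n1), A22u),
               c(A12u2, A21u1), c(u1, rep(0, n2)), c(rep(0, n1), u2))
    PQ <- P %*% Q
    AI <- 0.5 * crossprod(Q, PQ)
    AI <- (AI + t(AI)) / 2
    grad <- -0.5 * (trPG - uGu)
    list(AI = AI, grad = grad, uGu = uGu, trPG = trPG)
  }

  project <- function(th) {
    th[c(1, 2, 4, 5)] <- pmax(th[c(1, 2, 4, 5)], floors[c(1, 2, 4, 5)])
    bound <- sqrt(th[1] * th[2]) * (1 - 1e-9)
    if (is.null(fixCovG)) th[3] <- min(max(th[3], -bound), bound)
    else th[3] <- fixCovG
    th
  }

  nvec <- c(n1, n2, n, n1, n2)
  run_from <- function(th0) {
    th <- project(th0)
    st <- eval_point(th)
    if (is.null(st)) return(NULL)
    traj <- numeric(0)
    converged <- FALSE
    iter <- 0L
    clamped <- 0L
    for (iter in seq_len(maxIter)) {
      dv <- derived(st)
      em_step <- numeric(5)
      em <- c(1, 2, 4, 5)
      em_step[em] <- th[em]^2 * (dv$uGu[em] - dv$trPG[em]) / nvec[em]
      ai_step <- numeric(5)
      ai_step[free] <- tryCatch(
        drop(solve(dv$AI[free, free, drop = FALSE], dv$grad[free])),
        error = function(e) rep(0, length(free)))
      grad_step <- numeric(5)
      grad_step[free] <- dv$grad[free] *
        c(Vp1, Vp2, sqrt(Vp1 * Vp2), Vp1, Vp2)[free]^2 / n
      # AI direction first (EM on the first sweep), then EM, then a scaled
      # gradient step; step-halving within each. Only when no direction
      # yields ascent is the point accepted as a (local) maximum.
      dirs <- if (iter == 1L) list(em_step, ai_step, grad_step)
      else list(ai_step, em_step, grad_step)
      ll_prev <- st$ll
      accepted <- FALSE
      acc_ch <- NULL
      for (step in dirs) {
        if (all(step == 0)) next
        for (h in 0:15) {
          prop <- project(th + step / 2^h)
          cand <- eval_ll(prop)
          if (!is.null(cand) && cand$ll > ll_prev + 1e-12) {
            th <- prop; acc_ch <- cand$ch; accepted <- TRUE; break
          }
        }
        if (accepted) break
      }
      if (!accepted) { converged <- TRUE; break }
      st <- eval_point(th, acc_ch)
      traj <- c(traj, st$ll)
      if (abs(st$ll - ll_prev) < tol && iter > 1L) {
        converged <- TRUE; break
      }
      # crawling along the active |rg| <= 1 clamp: hand over to the
      # boundary Newton phase instead of zigzagging against the projection
      clamped <- if (is.null(fixCovG) &&
                     abs(th[3]) >= 0.999 * sqrt(th[1] * th[2]))
        clamped + 1L else 0L
      if (clamped >= 3L) { converged <- TRUE; break }
    }
    list(th = th, st = st, traj = traj, iter = iter, converged = converged)
  }

  # Haseman-Elston moment start: regress phenotype cross-products on the
  # corresponding relationship entries, clamped into the interior
  he_start <- function() {
    y1c <- y[i1] - mean(y[i1]); y2c <- y[i2] - mean(y[i2])
    slope <- function(prod, a) {
      va <- var(as.vector(a))
      if (!is.finite(va) || va == 0) return(0)
      stats::cov(as.vector(prod), as.vector(a)) / va
    }
    off1 <- upper.tri(A11); off2 <- upper.tri(A22)
    g1 <- slope(tcrossprod(y1c)[off1], A11[off1])
    g2 <- slope(tcrossprod(y2c)[off2], A22[off2])
    g12 <- slope(outer(y1c, y2c), A12)
    g1 <- min(max(g1, 0.05 * Vp1), 0.95 * Vp1)
    g2 <- min(max(g2, 0.05 * Vp2), 0.95 * Vp2)
    g12 <- min(max(g12, -0.9 * sqrt(g1 * g2)), 0.9 * sqrt(g1 * g2))
    c(g1, g2, g12, Vp1 - g1, Vp2 - g2)
  }

  # With the correlation constraint active (|rg| = 1) the optimum lies on
  # the manifold g12 = s sqrt(g1 g2); Newton steps in the reduced
  # four-parameter space (chain rule on the AI matrix and gradient) slide
  # along the boundary to its constrained maximum.
  polish_boundary <- function(fit, sgn) {
    th <- fit$th; st <- fit$st
    traj <- fit$traj
    pin <- function(th) {
      th[3] <- sgn * sqrt(th[1] * th[2]) * (1 - 1e-9)
      th
    }
    th <- pin(th); st2 <- eval_point(th)
    if (is.null(st2)) return(fit)
    st <- st2
    iters <- fit$iter
    for (it in seq_len(min(maxIter, 40L))) {
      dv <- derived(st)
      J <- matrix(0, 5, 4)
      J[1, 1] <- J[2, 2] <- J[4, 3] <- J[5, 4] <- 1
      J[3, 1] <- sgn * 0.5 * sqrt(th[2] / th[1])
      J[3, 2] <- sgn * 0.5 * sqrt(th[1] / th[2])
      g4 <- drop(crossprod(J, dv$grad))
      A4 <- crossprod(J, dv$AI %*% J)
      s4 <- tryCatch(drop(solve(A4, g4)), error = function(e) g4 * 1e-3)
      ll_prev <- st$ll
      accepted <- FALSE
      acc_ch <- NULL
      for (dir in list(s4, g4 * c(Vp1, Vp2, Vp1, Vp2)^2 / n)) {
        for (h in 0:15) {
          prop <- th
          prop[c(1, 2, 4, 5)] <- pmax(th[c(1, 2, 4, 5)] + dir / 2^h,
                                      floors[c(1, 2, 4, 5)])
          prop <- pin(prop)
          cand <- eval_ll(prop)
          if (!is.null(cand) && cand$ll > ll_prev + 1e-12) {
            th <- prop; acc_ch <- cand$ch; accepted <- TRUE; break
          }
        }
        if (accepted) break
      }
      if (!accepted) break
      st <- eval_point(th, acc_ch)
      iters <- iters + 1L
      traj <- c(traj, st$ll)
      if (abs(st$ll - ll_prev) < tol) break
    }
    if (st$ll > fit$st$ll)
      list(th = th, st = st, traj = traj, iter = iters,
           converged = fit$converged)
    else fit
  }

  fit <- run_from(he_start())
  # second start from a neutral variance split only when the moment start
  # failed, stalled, or ended on a variance floor
  need_second <- is.null(fit) || !fit$converged ||
    fit$th[1] <= 1.5 * floors[1] || fit$th[2] <= 1.5 * floors[2]
  if (need_second) {
    fit0 <- run_from(c(Vp1 / 2, Vp2 / 2, 0, Vp1 / 2, Vp2 / 2))
    if (is.null(fit) || (!is.null(fit0) && fit0$st$ll > fit$st$ll))
      fit <- fit0
  }
  if (is.null(fixCovG) && !is.null(fit) &&
      abs(fit$th[3]) >= 0.99 * sqrt(fit$th[1] * fit$th[2]))
    fit <- polish_boundary(fit, sign(fit$th[3] + 1e-300))
  if (is.null(fit)) stop("REML likelihood not computable at the start value")
  # a genetic variance pinned at its floor together with the |rg| <= 1
  # bound can trap the covariance at zero; restart from interior points
  # with a non-zero covariance and keep the best restricted likelihood
  at_boundary <- function(f) {
    f$th[1] <= 1.5 * floors[1] || f$th[2] <= 1.5 * floors[2] ||
      (is.null(fixCovG) &&
         abs(f$th[3]) >= 0.99 * sqrt(f$th[1] * f$th[2]))
  }
  if (at_boundary(fit)) {
    for (sgn in c(1, -1)) {
      alt <- run_from(c(0.6 * Vp1, 0.6 * Vp2,
                        sgn * 0.45 * sqrt(0.36 * Vp1 * Vp2),
                        0.4 * Vp1, 0.4 * Vp2))
      if (!is.null(alt) && alt$st$ll > fit$st$ll) fit <- alt
    }
  }
  th <- fit$th; st <- fit$st; traj <- fit$traj
  iter <- fit$iter; converged <- fit$converged
  dv <- derived(st)
  cov <- matrix(0, 5, 5)
  covf <- tryCatch(solve(dv$AI[free, free, drop = FALSE]),
                   error = function(e) matrix(NA_real_, length(free),
                                              length(free)))
  cov[free, free] <- covf
  comp <- new("BivariateComponents", varG1 = th[1], varG2 = th[2],
              covG12 = th[3], varE1 = th[4], varE2 = th[5],
              samplingCov = cov, logLik = st$ll, nIterations = iter,
              converged = converged, trajectory = traj)
  rg <- if (is.null(fixCovG)) rgEstimate(comp, source = source) else NULL
  list(components = comp, rg = rg)
}

#' Observed-to-liability scale transformation
#'
#' Converts an observed-scale case-control heritability to the liability
#' scale: h2_liab = h2_obs * \[K (1 - K)\]^2 / \[P (1 - P) z^2\], where K is
#' the population prevalence, P the proportion of cases in the analysed
#' sample, and z the standard normal density at the liability threshold
#' qnorm(1 - K). The standard error scales by the same factor.
#'
#' @param h2_observed,se_observed observed-scale estimate and SE.
#' @param prevalence_K population prevalence in (0, 1).
#' @param case_proportion_P sample case proportion in (0, 1).
#' @return a [HeritabilityEstimate-class].
#' @export
liabilityTransform <- function(h2_observed, se_observed, prevalence_K,
                               case_proportion_P) {
  K <- prevalence_K; P <- case_proportion_P
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop("prevalence and case proportion must lie strictly in (0, 1)")
  z <- dnorm(qnorm(1 - K))
  fac <- (K * (1 - K))^2 / (P * (1 - P) * z^2)
  new("HeritabilityEstimate",
      h2Observed = h2_observed, seObserved = se_observed,
      h2Liability = h2_observed * fac, seLiability = se_observed * fac,
      prevalence = K, caseProportion = P, zDensity = z)
}

#' Compare two independent heritability estimates
#'
#' Normal z-test on the difference of two independent estimates:
#' z = (h2_1 - h2_2) / sqrt(se_1^2 + se_2^2), two-sided P from the standard
#' normal (the usual large-sample "t-test" on REML estimates, documented
#' here as a z-test since no degrees of freedom are defined).
#'
#' @param est_1,est_2 [HeritabilityEstimate-class] objects (compared on the
#'   liability scale) or numeric `c(h2, se)` pairs.
#' @return list with `statistic` and `p_two_sided`.
#' @export
compareH2 <- function(est_1, est_2) {
  pick <- function(e) {
    if (is(e, "HeritabilityEstimate")) c(e@h2Liability, e@seLiability)
    else if (is.numeric(e) && length(e) == 2) e
    else stop("estimates must be HeritabilityEstimate or c(h2, se)")
  }
  a <- pick(est_1); b <- pick(est_2)
  if (a[2] <= 0 || b[2] <= 0) stop("standard errors must be positive")
  z <- (a[1] - b[1]) / sqrt(a[2]^2 + b[2]^2)
  list(statistic = z, p_two_sided = 2 * pnorm(-abs(z)))
}
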