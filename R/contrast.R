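# The permutation contrast between subtype-pair genetic correlations
# (rg between the two subtype case groups, each paired with one half of a
# random split of the shared controls) and mixed-pair correlations (the
# pooled cases randomly re-split to the same group sizes), plus the
# site/subtype balance gatekeeping applied before any subtype comparison.

#' Site/subtype balance check
#'
#' Flags any subtype for which more than `subtype_site_share_max` of its
#' cases derive from a single site (strict inequality: a share of exactly
#' the bound is retained), and any site whose relative contribution to the
#' two compared subtypes is grossly imbalanced -- concretized as a ratio of
#' contribution shares above `site_imbalance_ratio_max`.
#'
#' @param phenotypes phenotype table with `status`, `subtype`, `site`.
#' @param subtype_site_share_max maximal single-site case share (default
#'   0.75).
#' @param site_imbalance_ratio_max maximal ratio between a site's
#'   contribution shares to the two compared subtypes (default 3).
#' @param subtypes the two subtypes being compared.
#' @return list of class `BalanceReport`: per-subtype max single-site
#'   share, per-site contribution ratios, `excluded_subtypes`,
#'   `excluded_sites`.
#' @export
checkSiteSubtypeBalance <- function(phenotypes,
                                    subtype_site_share_max = 0.75,
                                    site_imbalance_ratio_max = 3,
                                    subtypes = c("BD1", "BD2")) {
  cases <- phenotypes[phenotypes$status == "case", , drop = FALSE]
  if (length(unique(cases$site)) < 2) stop("need at least 2 sites")
  present <- unique(cases$subtype)
  if (length(present) < 2) stop("need at least 2 subtypes among cases")
  tab <- table(cases$subtype, cases$site)
  if (any(rowSums(tab) == 0)) stop("empty subtype stratum")
  shares <- sweep(tab, 1, rowSums(tab), "/")
  max_share <- apply(shares, 1, max)
  excluded_subtypes <- names(max_share)[max_share > subtype_site_share_max]
  # contribution of each site to the two compared subtypes
  excluded_sites <- character(0)
  ratios <- NULL
  if (all(subtypes %in% rownames(tab))) {
    contrib <- sweep(tab[subtypes, , drop = FALSE], 1,
                     rowSums(tab[subtypes, , drop = FALSE]), "/")
    r <- contrib[1, ] / contrib[2, ]
    ratios <- pmax(r, 1 / r)
    excluded_sites <- colnames(tab)[is.finite(ratios) &
                                      ratios > site_imbalance_ratio_max]
    excluded_sites <- union(excluded_sites,
                            colnames(tab)[!is.finite(ratios) &
                                            colSums(tab[subtypes, ,
                                                        drop = FALSE]) > 0])
  }
  structure(list(subtype_site_share = as.matrix(shares),
                 max_single_site_share = max_share,
                 site_contribution_ratio = ratios,
                 excluded_subtypes = excluded_subtypes,
                 excluded_sites = excluded_sites),
            class = "BalanceReport")
}

#' Generate control-split and case-mix permutation plans
#'
#' Emits `n_control_perms` subtype-pair plans -- the fixed subtype case
#' groups, each paired with one half of a fresh random split of the
#' controls into two evenly sized non-overlapping groups -- and, for each
#' control permutation, `n_case_splits` mixed-pair plans in which the
#' pooled cases are randomly divided into two non-overlapping groups sized
#' according to the subtype case groups. Fully reproducible from `seed`.
#'
#' @param phenotypes phenotype table (`sample_id`, `status`, `subtype`).
#' @param n_control_perms number of control-split permutations.
#' @param n_case_splits number of case splits per control permutation.
#' @param seed integer seed.
#' @param subtypes the two subtype labels.
#' @return object of class `SplitPlans`; use [getPlan()] to materialize a
#'   single plan and [nPlans()] for the counts.
#' @export
generateSplitPlans <- function(phenotypes, n_control_perms = 100L,
                               n_case_splits = 100L, seed = 1L,
                               subtypes = c("BD1", "BD2")) {
  ids <- phenotypes$sample_id
  controls <- which(phenotypes$status == "control")
  case1 <- which(phenotypes$subtype == subtypes[1])
  case2 <- which(phenotypes$subtype == subtypes[2])
  if (length(controls) < 2) stop("need at least 2 controls")
  if (!length(case1) || !length(case2)) stop("empty subtype case group")
  nA <- ceiling(length(controls) / 2)
  pool <- c(case1, case2)
  n1 <- length(case1)
  withr::with_seed(seed, {
    ctrl <- lapply(seq_len(n_control_perms), function(i) {
      perm <- sample(controls)
      list(A = sort(perm[seq_len(nA)]), B = sort(perm[-seq_len(nA)]))
    })
    mixes <- lapply(seq_len(n_control_perms), function(i) {
      lapply(seq_len(n_case_splits), function(j) {
        perm <- sample(pool)
        list(g1 = sort(perm[seq_len(n1)]), g2 = sort(perm[-seq_len(n1)]))
      })
    })
  })
  structure(list(ids = ids, controls = ctrl, case1 = sort(case1),
                 case2 = sort(case2), caseSplits = mixes,
                 n_control_perms = as.integer(n_control_perms),
                 n_case_splits = as.integer(n_case_splits),
                 subtypes = subtypes, seed = as.integer(seed)),
            class = "SplitPlans")
}

#' Number of plans by kind
#' @param plans a `SplitPlans` object.
#' @return named vector with `subtype_pair` and `mixed_pair` counts.
#' @export
nPlans <- function(plans) {
  c(subtype_pair = plans$n_control_perms,
    mixed_pair = plans$n_control_perms * plans$n_case_splits)
}

#' Materialize one split plan
#'
#' @param plans a `SplitPlans` object.
#' @param kind `"subtype_pair"` or `"mixed_pair"`.
#' @param control_perm control permutation index.
#' @param case_split case split index (mixed plans only).
#' @return list with `case_group_1`, `case_group_2`, `control_group_A`,
#'   `control_group_B` (sample ids) and `kind`.
#' @export
getPlan <- function(plans, kind = c("subtype_pair", "mixed_pair"),
                    control_perm, case_split = NULL) {
  kind <- match.arg(kind)
  ctl <- plans$controls[[control_perm]]
  if (kind == "subtype_pair") {
    g1 <- plans$case1; g2 <- plans$case2
  } else {
    sp <- plans$caseSplits[[control_perm]][[case_split]]
    g1 <- sp$g1; g2 <- sp$g2
  }
  list(kind = kind, permutation_index = control_perm,
       case_split_index = if (is.null(case_split)) NA_integer_ else case_split,
       case_group_1 = plans$ids[g1], case_group_2 = plans$ids[g2],
       control_group_A = plans$ids[ctl$A], control_group_B = plans$ids[ctl$B])
}

#' Estimate the subtype-pair and mixed-pair rg distributions
#'
#' For every plan, trait 1 is case group 1 versus control half A and
#' trait 2 is case group 2 versus control half B; a bivariate GREML fit
#' yields one genetic correlation per plan. Non-converged fits are kept
#' and flagged, never dropped.
#'
#' @param phenotypes phenotype table aligned with the GRM individuals.
#' @param plans a `SplitPlans` object from [generateSplitPlans()].
#' @param grm a [GRM-class] covering all plan individuals.
#' @param kinds which plan kinds to run (both by default).
#' @param verbose print a progress line per control permutation.
#' @return list of class `RgDistributions`: vectors `rg_subtype`,
#'   `rg_mix`, matching `se_*` and `converged_*` vectors.
#' @export
estimateRgDistributions <- function(phenotypes, plans, grm,
                                    kinds = c("subtype_pair", "mixed_pair"),
                                    verbose = FALSE) {
  run_plan <- function(plan) {
    y1 <- setNames(c(rep(1, length(plan$case_group_1)),
                     rep(0, length(plan$control_group_A))),
                   c(plan$case_group_1, plan$control_group_A))
    y2 <- setNames(c(rep(1, length(plan$case_group_2)),
                     rep(0, length(plan$control_group_B))),
                   c(plan$case_group_2, plan$control_group_B))
    fit <- fitGremlBivariate(grm, y1, y2, source = plan$kind)
    c(rg = fit$rg@rg, se = fit$rg@se,
      conv = as.numeric(fit$components@converged))
  }
  rg_subtype <- se_subtype <- conv_subtype <- numeric(0)
  if ("subtype_pair" %in% kinds) {
    res <- vapply(seq_len(plans$n_control_perms), function(i) {
      if (verbose) message("subtype-pair plan ", i)
      run_plan(getPlan(plans, "subtype_pair", i))
    }, numeric(3))
    rg_subtype <- res["rg", ]; se_subtype <- res["se", ]
    conv_subtype <- res["conv", ] > 0
  }
  rg_mix <- se_mix <- conv_mix <- numeric(0)
  if ("mixed_pair" %in% kinds) {
    res <- vapply(seq_len(plans$n_control_perms), function(i) {
      if (verbose) message("mixed-pair plans, control perm ", i)
      vapply(seq_len(plans$n_case_splits), function(j)
        run_plan(getPlan(plans, "mixed_pair", i, j)), numeric(3))
    }, matrix(0, 3, plans$n_case_splits))
    res <- matrix(res, nrow = 3)
    rg_mix <- res[1, ]; se_mix <- res[2, ]; conv_mix <- res[3, ] > 0
  }
  structure(list(rg_subtype = rg_subtype, se_subtype = se_subtype,
                 converged_subtype = conv_subtype,
                 rg_mix = rg_mix, se_mix = se_mix,
                 converged_mix = conv_mix),
            class = "RgDistributions")
}

#' Compare the rg distributions
#'
#' Welch two-sample t-test on the converged estimates of the subtype-pair
#' and mixed-pair rg distributions, with summary statistics (mean, SD,
#' range, convergence counts) for each arm.
#'
#' @param dist an `RgDistributions` object.
#' @return list with `t_statistic`, `p_two_sided` and a `summary`
#'   data.frame.
#' @export
compareRgDistributions <- function(dist) {
  a <- dist$rg_subtype[dist$converged_subtype]
  b <- dist$rg_mix[dist$converged_mix]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 converged estimates in each arm")
  tt <- t.test(a, b)
  summ <- data.frame(
    arm = c("rg_subtype", "rg_mix"),
    n = c(length(dist$rg_subtype), length(dist$rg_mix)),
    n_converged = c(length(a), length(b)),
    mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b)),
    min = c(min(a), min(b)), max = c(max(a), max(b)))
  list(t_statistic = unname(tt$statistic), p_two_sided = tt$p.value,
       summary = summ)
}
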