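# End-to-end orchestration: simulate (or read) -> QC -> GRM -> univariate
# GREML with liability transform -> rg permutation contrast -> per-site
# association scans -> fixed-effects meta -> polygenic scoring.

#' Validate a pipeline configuration
#'
#' A configuration is a nested list: either `sim` (a [simConfig()]) or
#' `genotype_prefix`/`phenotype_file` paths; optional `qc` overrides (a
#' [qcThresholds()]); an `analysis` block with `prevalence1`,
#' `prevalence2`, `n_control_perms`, `n_case_splits`, `grm_cutoff`,
#' `prs_thresholds`; an integer `seed`; and `out_dir`.
#'
#' @param config the configuration list.
#' @return the completed configuration (defaults filled in).
#' @export
validatePipelineConfig <- function(config) {
  if (is.null(config$sim) && is.null(config$genotype_prefix))
    stop("config needs either a sim block or a genotype_prefix")
  if (!is.null(config$genotype_prefix)) {
    for (ext in c(".bed", ".bim", ".fam"))
      if (!file.exists(paste0(config$genotype_prefix, ext)))
        stop("missing genotype file: ", config$genotype_prefix, ext)
    if (is.null(config$phenotype_file) ||
        !file.exists(config$phenotype_file))
      stop("missing phenotype_file")
  }
  if (is.null(config$seed)) stop("seed is mandatory")
  an <- config$analysis
  if (is.null(an)) an <- list()
  if (is.null(an$prevalence1))
    an$prevalence1 <- if (!is.null(config$sim)) config$sim$prevalence1
    else stop("analysis$prevalence1 required for the liability transform")
  if (is.null(an$prevalence2))
    an$prevalence2 <- if (!is.null(config$sim)) config$sim$prevalence2
    else stop("analysis$prevalence2 required for the liability transform")
  if (is.null(an$n_control_perms)) an$n_control_perms <- 10L
  if (is.null(an$n_case_splits)) an$n_case_splits <- 10L
  if (is.null(an$grm_cutoff)) an$grm_cutoff <- 0.05
  if (is.null(an$prs_thresholds))
    an$prs_thresholds <- c(0.001, 0.01, 0.05, 0.1, 0.2, 0.5, 1.0)
  config$analysis <- an
  if (is.null(config$qc)) config$qc <- qcThresholds()
  if (is.null(config$out_dir)) stop("out_dir is required")
  config
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing per-stage outputs and a
#' machine-readable JSON manifest (inputs, thresholds, seeds, per-stage
#' output files and headline numbers) into the run directory. Any stage
#' failure aborts with the stage name; outputs of completed stages are
#' left in place.
#'
#' @param config configuration list, see [validatePipelineConfig()].
#' @return the run directory, invisibly; the manifest is
#'   `<out_dir>/manifest.json`.
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  finish_stage <- function(name, info) {
    manifest$stages[[name]] <<- info
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs -------------------------------------------------------------
  cohort <- stage("input", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- config$seed
      simulateCohort(sim)
    } else {
      geno <- readPlink(config$genotype_prefix)
      ph <- readPhenotypes(config$phenotype_file)
      list(genotypes = geno,
           phenotypes = ph[match(sampleIds(geno), ph$sample_id), ])
    }
  })
  finish_stage("input", list(n_individuals = nSamples(cohort$genotypes),
                             n_snps = nSnps(cohort$genotypes)))

  # --- qc -----------------------------------------------------------------
  qc <- stage("qc", snpQCFilter(cohort$genotypes, cohort$phenotypes,
                                config$qc))
  utils::write.table(qc$report[, 1:5],
                     file.path(config$out_dir, "qc_report.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  finish_stage("qc", list(n_individuals = nSamples(qc$genotypes),
                          n_snps = nSnps(qc$genotypes),
                          report = "qc_report.tsv"))
  geno <- qc$genotypes; pheno <- qc$phenotypes

  # --- grm ----------------------------------------------------------------
  grmres <- stage("grm", {
    grm <- computeGRM(geno)
    kept <- grmRelatednessPrune(grm, config$analysis$grm_cutoff)
    list(grm = grm[kept], kept = kept)
  })
  writeGrmText(grmres$grm, file.path(config$out_dir, "cohort"))
  finish_stage("grm", list(n_individuals = length(grmres$kept),
                           cutoff = config$analysis$grm_cutoff,
                           files = c("cohort.grm", "cohort.grm.id")))
  grm <- grmres$grm
  pheno <- pheno[match(sampleIds(grm), pheno$sample_id), , drop = FALSE]

  # --- univariate heritability per subtype --------------------------------
  h2 <- stage("greml", {
    lapply(c(BD1 = "BD1", BD2 = "BD2"), function(st) {
      sel <- pheno$subtype == st | pheno$status == "control"
      y <- setNames(as.integer(pheno$status[sel] == "case"),
                    pheno$sample_id[sel])
      vc <- fitGremlUnivariate(grm, y)
      h <- h2Observed(vc)
      K <- if (st == "BD1") config$analysis$prevalence1
      else config$analysis$prevalence2
      liabilityTransform(h$estimate, h$se, K, mean(y))
    })
  })
  finish_stage("greml", list(
    h2_liab_BD1 = h2$BD1@h2Liability, se_BD1 = h2$BD1@seLiability,
    h2_liab_BD2 = h2$BD2@h2Liability, se_BD2 = h2$BD2@seLiability,
    h2_diff_p = compareH2(h2$BD1, h2$BD2)$p_two_sided))

  # --- rg contrast --------------------------------------------------------
  contrast <- stage("rg_contrast", {
    plans <- generateSplitPlans(pheno, config$analysis$n_control_perms,
                                config$analysis$n_case_splits,
                                seed = config$seed + 101L)
    dist <- estimateRgDistributions(pheno, plans, grm)
    list(dist = dist, cmp = compareRgDistributions(dist))
  })
  utils::write.table(
    data.frame(kind = c(rep("subtype_pair", length(contrast$dist$rg_subtype)),
                        rep("mixed_pair", length(contrast$dist$rg_mix))),
               rg = c(contrast$dist$rg_subtype, contrast$dist$rg_mix),
               converged = c(contrast$dist$converged_subtype,
                             contrast$dist$converged_mix)),
    file.path(config$out_dir, "rg_estimates.tsv"),
    quote = FALSE, sep = "\t", row.names = FALSE)
  finish_stage("rg_contrast", list(
    mean_rg_subtype = contrast$cmp$summary$mean[1],
    mean_rg_mix = contrast$cmp$summary$mean[2],
    p_two_sided = contrast$cmp$p_two_sided,
    estimates = "rg_estimates.tsv"))

  # --- association scans per site + meta ----------------------------------
  assoc <- stage("assoc_meta", {
    sites <- unique(pheno$site)
    y <- as.integer(pheno$status == "case")
    per_site <- lapply(sites, function(s) {
      sel <- pheno$site == s
      logisticAssocScan(geno[which(sel), ], y[sel])
    })
    if (length(sites) >= 2) {
      meta <- metaAnalyzeFixed(per_site)
      lam <- genomicLambda(meta$p_value)
    } else {
      meta <- per_site[[1]]
      lam <- genomicLambda(meta$p_value)
    }
    list(meta = meta, lambda = lam,
         regions = genomeWideRegions(meta))
  })
  writeSummaryStats(assoc$meta, file.path(config$out_dir, "meta.tsv"))
  finish_stage("assoc_meta", list(lambda = assoc$lambda,
                                  n_regions = nrow(assoc$regions),
                                  summary_stats = "meta.tsv"))

  # --- polygenic scores: discovery = site 1 scan, target = the rest -------
  prs <- stage("prs", {
    sites <- unique(pheno$site)
    disc_sel <- pheno$site == sites[1]
    if (all(disc_sel) || !any(disc_sel)) return(NULL)
    disc <- logisticAssocScan(geno[which(disc_sel), ],
                              as.integer(pheno$status[disc_sel] == "case"))
    tgt <- geno[which(!disc_sel), ]
    sc <- computeScores(tgt, disc, config$analysis$prs_thresholds)
    prsCaseControlTest(sc, pheno[!disc_sel, , drop = FALSE])
  })
  if (!is.null(prs)) {
    utils::write.table(prs, file.path(config$out_dir, "prs_tests.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
    best <- prs[which.max(prs$delta_nagelkerke_r2), ]
    finish_stage("prs", list(best_threshold = best$threshold,
                             delta_r2 = best$delta_nagelkerke_r2,
                             tests = "prs_tests.tsv"))
  }
  invisible(config$out_dir)
}
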