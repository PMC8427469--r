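## Configuration-driven orchestration: simulate (or read) -> polygenic
## scores -> baseline TSO fit -> association stages -> report, with a
## JSON manifest recording parameters, derived seeds and output
## checksums at every stage.

.default_run_config <- function() {
  list(seed = 1L,
       simulate = NULL,
       inputs = NULL,
       pgs = list(r2_threshold = 0.10, window_kb = 250, p_threshold = 1),
       model = list(spec = NULL),
       assoc = list(alpha = 0.05, family = "per_factor",
                    categories = NULL),
       log_level = "info")
}

#' Read a pipeline run configuration
#'
#' Loads a YAML configuration and merges it over the defaults. Exactly
#' one of `simulate:` (a [simConfig()] block) or `inputs:` (paths to
#' genotype/sumstats/phenotype files) must be present.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- modifyList(.default_run_config(), yaml::read_yaml(path))
  validateRunConfig(cfg)
}

#' Validate a pipeline run configuration
#'
#' @param config config list.
#' @return the config, invisibly; errors on invalid configuration.
#' @export
validateRunConfig <- function(config) {
  has_sim <- !is.null(config$simulate)
  has_in <- !is.null(config$inputs)
  if (has_sim == has_in)
    stop("config must contain exactly one of 'simulate' or 'inputs'",
         call. = FALSE)
  if (has_in) {
    need <- c("genotypes", "snp_meta", "sumstats", "phenotypes")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stop("inputs block lacks: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  invisible(config)
}

.manifest_entry <- function(stage, inputs, params, seed, outputs) {
  list(stage = stage, inputs = inputs, params = params, seed = seed,
       outputs = lapply(outputs, function(f)
         list(path = f, md5 = unname(tools::md5sum(f)))))
}

.log <- function(level, config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message("[", level, "] ", ...)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order: data (simulate or read),
#' polygenic scoring per GWAS, baseline TSO fit with fit indices and
#' variance decomposition, single-PGS associations with FDR selection,
#' multivariable models, and a report juxtaposing ground truth (when
#' simulated) with estimates. Every stage derives its own seed from the
#' global seed and appends a manifest entry with parameter values and
#' output checksums; on stage failure the partial manifest is written
#' before the error propagates.
#'
#' @param config config list (see [readRunConfig()]) or YAML path.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return list with the association tables, fit summary, selection,
#'   and the manifest (also written to `manifest.json`).
#' @export
runPipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- modifyList(.default_run_config(), config)
  validateRunConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(global_seed = config$seed, stages = list())
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      flush_manifest()
      stop("pipeline halted at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  ## -- data ----------------------------------------------------------
  truth <- NULL
  stage_data <- run_stage("data", function() {
    if (!is.null(config$simulate)) {
      sim_seed <- derive_seed(config$seed, "simulate")
      sc <- do.call(simConfig, modifyList(config$simulate,
                                          list(seed = sim_seed)))
      study <- simulateStudy(sc)
      ddir <- file.path(out_dir, "data")
      dir.create(ddir, showWarnings = FALSE)
      writeGenotypes(studyGenotypes(study),
                     file.path(ddir, "genotypes.tsv"),
                     file.path(ddir, "snp_meta.tsv"))
      ssfiles <- character(0)
      for (tr in names(studySumstats(study))) {
        f <- file.path(ddir, paste0("sumstats_", tr, ".tsv"))
        writeSumstats(studySumstats(study)[[tr]], f)
        ssfiles <- c(ssfiles, f)
      }
      writePhenotypes(studyPhenotypes(study),
                      file.path(ddir, "phenotypes.csv"))
      tj <- studyTruth(study)
      writeTruth(list(pgs_effects = tj$pgs_effects,
                      lambda_common = tj$lambda_common,
                      lambda_specific = tj$lambda_specific,
                      residual_sds = tj$residual_sds,
                      seed = config$seed),
                 file.path(ddir, "truth.json"))
      manifest$stages <- c(manifest$stages, list(.manifest_entry(
        "data", "simulated", config$simulate, sim_seed,
        c(file.path(ddir, c("genotypes.tsv", "snp_meta.tsv",
                            "phenotypes.csv", "truth.json")), ssfiles))))
      manifest <<- manifest
      list(genotypes = studyGenotypes(study),
           sumstats = studySumstats(study),
           phenotypes = studyPhenotypes(study),
           truth = studyTruth(study))
    } else {
      gp <- readGenotypes(config$inputs$genotypes,
                          config$inputs$snp_meta)
      ss <- lapply(names(config$inputs$sumstats), function(tr)
        readSumstats(config$inputs$sumstats[[tr]], trait = tr))
      names(ss) <- names(config$inputs$sumstats)
      ph <- readPhenotypes(config$inputs$phenotypes)
      manifest$stages <- c(manifest$stages, list(.manifest_entry(
        "data", unlist(config$inputs, use.names = TRUE), list(),
        config$seed, character(0))))
      manifest <<- manifest
      list(genotypes = gp, sumstats = ss, phenotypes = ph,
           truth = NULL)
    }
  })
  truth <- stage_data$truth
  pheno <- stage_data$phenotypes
  .log("info", config, "data stage: ", nrow(pheno), " individuals, ",
       length(stage_data$sumstats), " GWAS")

  ## -- polygenic scores ----------------------------------------------
  pgs_names <- names(stage_data$sumstats)
  stage_pgs <- run_stage("pgs", function() {
    pdir <- file.path(out_dir, "pgs")
    dir.create(pdir, showWarnings = FALSE)
    ids <- rownames(dosages(stage_data$genotypes))
    outputs <- character(0)
    reports <- list()
    for (tr in pgs_names) {
      built <- buildPGS(stage_data$genotypes, stage_data$sumstats[[tr]],
                        r2_threshold = config$pgs$r2_threshold,
                        window_kb = config$pgs$window_kb,
                        p_threshold = config$pgs$p_threshold)
      f <- file.path(pdir, paste0(tr, ".csv"))
      data.table::fwrite(data.frame(id = ids, score = built$score), f)
      outputs <- c(outputs, f)
      reports[[tr]] <- built$report
      idx <- match(pheno$id, ids)
      pheno[[paste0("pgs_", tr)]] <<- built$score[idx]
    }
    rf <- file.path(pdir, "pgs_report.json")
    jsonlite::write_json(reports, rf, auto_unbox = TRUE, digits = NA)
    manifest$stages <- c(manifest$stages, list(.manifest_entry(
      "pgs", "data stage", config$pgs, config$seed,
      c(outputs, rf))))
    manifest <<- manifest
    reports
  })
  .log("info", config, "pgs stage: ", length(pgs_names), " scores")

  ## -- baseline TSO fit ----------------------------------------------
  spec <- if (!is.null(config$model$spec)) readTSOSpec(config$model$spec)
          else buildTSOSpec(4, 3)
  stage_fit <- run_stage("fit", function() {
    fdir <- file.path(out_dir, "fit")
    dir.create(fdir, showWarnings = FALSE)
    fit <- fitTSO(spec, pheno, se = "robust")
    idx <- fitIndices(fit, pheno)
    std <- standardisedSolution(fit)
    std$se_naive <- seTSO(fit, "naive")[std$name]
    ptab <- file.path(fdir, "parameters.tsv")
    data.table::fwrite(std[, c("name", "type", "lhs", "rhs", "est",
                               "se_naive", "se", "est_std", "se_std")],
                       ptab, sep = "\t")
    vd <- varianceDecomposition(fit)
    vfile <- file.path(fdir, "variance_decomposition.tsv")
    data.table::fwrite(vd$table, vfile, sep = "\t")
    sfile <- file.path(fdir, "fit_summary.json")
    jsonlite::write_json(
      c(idx[c("chisq", "df", "pvalue", "cfi", "rmsea", "srmr",
              "baseline_chisq", "baseline_df", "n")],
        list(loglik = fit@loglik, converged = fit@converged,
             average_shares = as.list(vd$average))),
      sfile, auto_unbox = TRUE, digits = NA)
    manifest$stages <- c(manifest$stages, list(.manifest_entry(
      "fit", "phenotypes", list(df = modelDf(spec)), config$seed,
      c(ptab, vfile, sfile))))
    manifest <<- manifest
    list(fit = fit, indices = idx, decomposition = vd)
  })
  .log("info", config, "fit stage: chisq(", stage_fit$indices$df, ") = ",
       round(stage_fit$indices$chisq, 2), ", CFI = ",
       round(stage_fit$indices$cfi, 3))

  ## -- association stages --------------------------------------------
  covariates <- intersect(c("sex", paste0("pc", 1:10)), colnames(pheno))
  categories <- config$assoc$categories
  if (is.null(categories)) {
    categories <- defaultPgsCategories()[pgs_names]
    categories[is.na(categories)] <- "trait"
    names(categories) <- paste0("pgs_", pgs_names)
  } else categories <- unlist(categories)
  stage_assoc <- run_stage("assoc", function() {
    adir <- file.path(out_dir, "assoc")
    dir.create(adir, showWarnings = FALSE)
    single <- runSinglePGS(pheno, spec, paste0("pgs_", pgs_names),
                           covariates = covariates,
                           family = config$assoc$family)
    f1 <- file.path(adir, "single_pgs.tsv")
    writeAssociationTable(single, f1)
    sel <- selectSignificant(single, alpha = config$assoc$alpha,
                             categories = categories)
    multi <- runMultiPGS(pheno, spec, sel, covariates = covariates)
    f2 <- file.path(adir, "multi_pgs.tsv")
    writeAssociationTable(multi, f2)
    mfile <- file.path(adir, "assoc_manifest.json")
    jsonlite::write_json(list(alpha = config$assoc$alpha,
                              family = config$assoc$family,
                              selected = sel, seed = config$seed),
                         mfile, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    manifest$stages <- c(manifest$stages, list(.manifest_entry(
      "assoc", "fit stage", config$assoc[c("alpha", "family")],
      config$seed, c(f1, f2, mfile))))
    manifest <<- manifest
    list(single = single, selected = sel, multi = multi)
  })
  .log("info", config, "assoc stage: ", nrow(stage_assoc$single),
       " single-PGS rows, ", nrow(stage_assoc$multi), " multi-PGS rows")

  ## -- report ---------------------------------------------------------
  report <- run_stage("report", function() {
    rdir <- file.path(out_dir, "report")
    dir.create(rdir, showWarnings = FALSE)
    single <- stage_assoc$single
    rep_tab <- single[, c("model", "pgs", "factor", "b_std", "ci_low",
                          "ci_high", "p_raw", "p_fdr")]
    rep_tab$b_true <- NA_real_
    if (!is.null(truth)) {
      for (r in seq_len(nrow(rep_tab))) {
        tr <- sub("^pgs_", "", rep_tab$pgs[r])
        if (tr %in% colnames(truth$pgs_effects))
          rep_tab$b_true[r] <- truth$pgs_effects[rep_tab$factor[r], tr]
      }
    }
    f <- file.path(rdir, "truth_vs_estimates.tsv")
    data.table::fwrite(rep_tab, f, sep = "\t")
    manifest$stages <- c(manifest$stages, list(.manifest_entry(
      "report", "assoc stage", list(), config$seed, f)))
    manifest <<- manifest
    rep_tab
  })
  flush_manifest()
  invisible(list(single = stage_assoc$single,
                 selected = stage_assoc$selected,
                 multi = stage_assoc$multi,
                 fit = stage_fit$fit, indices = stage_fit$indices,
                 decomposition = stage_fit$decomposition,
                 report = report, manifest = manifest,
                 phenotypes = pheno))
}

#' Recovery scatter of true versus estimated coefficients
#'
#' Draws the report table's true structural coefficients against the
#' estimated standardised coefficients (base graphics).
#'
#' @param report report table from [runPipeline()].
#' @return invisibly, the plotted data.
#' @export
plotRecovery <- function(report) {
  ok <- !is.na(report$b_true)
  plot(report$b_true[ok], report$b_std[ok],
       xlab = "true coefficient", ylab = "estimated (standardised)",
       main = "PGS effect recovery", pch = 19)
  graphics::abline(0, 1, lty = 2)
  invisible(report[ok, ])
}
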