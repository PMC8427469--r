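#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Genotype panel of effect-allele dosages
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' biallelic dosage matrix (SNPs in rows, individuals in columns, assay
#' `"dosage"`) together with SNP metadata as `rowRanges`: chromosome,
#' 1-based position, reference/alternate coding alleles (`A1` = counted
#' effect allele, `A2` = other allele) and the allele frequency used at
#' simulation or import time.
#'
#' Use [GenotypePanel()] to construct one from an individuals-by-SNPs
#' matrix, and [dosages()] / [snpInfo()] to get the statistical view
#' back (individuals in rows).
#'
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!is.numeric(d)) msg <- c(msg, "dosages must be numeric")
    else if (any(!is.na(d) & (d < 0 | d > 2)))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  need <- c("snp", "A1", "A2", "MAF")
  have <- colnames(SummarizedExperiment::rowData(object))
  if (!all(need %in% have))
    msg <- c(msg, paste0("rowData must contain ",
                         paste(setdiff(need, have), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' GWAS summary statistics
#'
#' Per-SNP association results used as polygenic-score weights: SNP id,
#' genomic location, effect/other allele, signed effect size per copy of
#' the effect allele, standard error and p-value. `harmonised` records
#' whether the table has been aligned to a genotype panel, and `report`
#' carries the harmonisation bookkeeping (matched / flipped / dropped).
#'
#' @slot stats data.frame with columns `snp`, `chr`, `bp`, `A1`, `A2`,
#'   `beta`, `se`, `p`.
#' @slot trait single string naming the GWAS trait.
#' @slot harmonised logical flag.
#' @slot report list; harmonisation counts when `harmonised`.
#' @aliases GwasSumstats-class
#' @exportClass GwasSumstats
setClass("GwasSumstats",
         representation(stats = "data.frame", trait = "character",
                        harmonised = "logical", report = "list"),
         prototype(trait = "trait", harmonised = FALSE, report = list()))

setValidity("GwasSumstats", function(object) {
  msg <- character()
  need <- c("snp", "chr", "bp", "A1", "A2", "beta", "p")
  if (!all(need %in% colnames(object@stats)))
    msg <- c(msg, paste0("stats must contain columns ",
                         paste(setdiff(need, colnames(object@stats)),
                               collapse = ", ")))
  else {
    s <- object@stats
    if (anyDuplicated(s$snp)) msg <- c(msg, "snp ids must be unique")
    if (any(!is.finite(s$p) | s$p <= 0 | s$p > 1))
      msg <- c(msg, "p-values must lie in (0, 1]")
    bad <- !(s$A1 %in% c("A", "C", "G", "T")) |
      !(s$A2 %in% c("A", "C", "G", "T")) | s$A1 == s$A2
    if (any(bad)) msg <- c(msg, "alleles must be distinct single bases ACGT")
  }
  if (length(msg)) msg else TRUE
})

#' Trait-state-occasion model specification
#'
#' Defines the latent structure of the TSO model: a common liability
#' factor loading on all indicators, one specific factor per substance
#' loading on that substance's repeated scores, and one occasion factor
#' per measurement wave with loadings fixed to 1 on the same-wave
#' indicators. All factor (residual) variances are fixed to 1 and the
#' factors are mutually orthogonal; residual variances and intercepts of
#' the indicators are free. Latent factors may additionally be regressed
#' on observed exogenous predictors (polygenic scores, sex, principal
#' components), in which case the regressed factor's residual variance
#' stays fixed at 1 and the factor's total variance is model-implied.
#'
#' @slot nSubstances,nOccasions integer dimensions.
#' @slot substances,occasions,indicators,factorNames character labels;
#'   indicators are substance-major (`cig_17, cig_20, ..., oth_22`).
#' @slot lambdaTemplate indicators x factors matrix; `NA` = free
#'   loading, numeric = fixed value, 0 = absent path.
#' @slot predictors character; exogenous predictor column names.
#' @slot structural named list: factor name -> character vector of
#'   predictors that factor is regressed on.
#' @slot paramTable data.frame indexing the free parameter vector.
#' @slot df model degrees of freedom of the covariance structure.
#' @aliases TSOSpec-class
#' @exportClass TSOSpec
setClass("TSOSpec",
         representation(nSubstances = "integer", nOccasions = "integer",
                        substances = "character", occasions = "character",
                        indicators = "character", factorNames = "character",
                        lambdaTemplate = "matrix", predictors = "character",
                        structural = "list", paramTable = "data.frame",
                        df = "integer"))

setValidity("TSOSpec", function(object) {
  msg <- character()
  p <- length(object@indicators)
  if (!identical(dim(object@lambdaTemplate),
                 c(p, length(object@factorNames))))
    msg <- c(msg, "lambdaTemplate dimensions must match indicators x factors")
  if (!all(names(object@structural) %in% object@factorNames))
    msg <- c(msg, "structural map references unknown factor")
  if (!all(unlist(object@structural) %in% object@predictors))
    msg <- c(msg, "structural map references unknown predictor")
  if (length(msg)) msg else TRUE
})

#' Fitted trait-state-occasion model
#'
#' Result of [fitTSO()]: maximum-likelihood estimates (full-information
#' over incomplete rows), log-likelihood, model-implied moments, naive
#' and sandwich-robust covariance matrices of the estimates, and
#' convergence diagnostics.
#'
#' @slot spec the [TSOSpec-class] that was fitted.
#' @slot theta named numeric vector of free-parameter estimates on the
#'   natural scale (loadings, residual variances, intercepts, structural
#'   coefficients).
#' @slot loglik FIML log-likelihood at the optimum.
#' @slot nUsed number of rows contributing to the likelihood.
#' @slot converged logical; scaled gradient criterion met.
#' @slot heywood logical; TRUE when a residual variance hit the lower
#'   boundary.
#' @slot vcovNaive,vcovRobust covariance matrices of theta (robust may
#'   be a 0 x 0 matrix if not requested).
#' @slot impliedMu,impliedSigma model-implied marginal moments of the
#'   indicators (predictors integrated over their sample distribution).
#' @slot predictorStats list with `mean` and `cov` of the predictors
#'   (empty when the model has none).
#' @slot optim list of optimiser diagnostics.
#' @aliases TSOFit-class
#' @exportClass TSOFit
setClass("TSOFit",
         representation(spec = "TSOSpec", theta = "numeric",
                        loglik = "numeric", nUsed = "integer",
                        converged = "logical", heywood = "logical",
                        vcovNaive = "matrix", vcovRobust = "matrix",
                        impliedMu = "numeric", impliedSigma = "matrix",
                        predictorStats = "list", optim = "list"))

#' Simulated study with ground truth
#'
#' Container returned by [simulateStudy()]: a [GenotypePanel-class], one
#' [GwasSumstats-class] per simulated discovery GWAS, a phenotype table,
#' and a `truth` list recording every latent quantity used to generate
#' the data (true per-individual polygenic values, latent factor scores,
#' loadings, structural coefficients, the continuous pre-discretisation
#' indicators, and the seed).
#'
#' @slot genotypes GenotypePanel.
#' @slot sumstats named list of GwasSumstats.
#' @slot phenotypes data.frame (id, sex, pc1..pc10, 12 indicators).
#' @slot truth list of ground-truth records.
#' @aliases SimulatedStudy-class
#' @exportClass SimulatedStudy
setClass("SimulatedStudy",
         representation(genotypes = "GenotypePanel", sumstats = "list",
                        phenotypes = "data.frame", truth = "list"))

setValidity("SimulatedStudy", function(object) {
  nG <- ncol(object@genotypes)
  nP <- nrow(object@phenotypes)
  if (nP > nG)
    return("phenotype rows exceed genotyped individuals")
  TRUE
})
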