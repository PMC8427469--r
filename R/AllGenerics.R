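#' Dosage matrix of a genotype panel
#'
#' Returns the dosage matrix in the statistical orientation, individuals
#' in rows and SNPs in columns.
#'
#' @param x a [GenotypePanel-class].
#' @return numeric matrix, individuals x SNPs.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' SNP metadata of a genotype panel
#'
#' @param x a [GenotypePanel-class].
#' @return data.frame with columns `snp`, `chr`, `bp`, `A1`, `A2`, `MAF`.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' Summary-statistics table
#'
#' @param x a [GwasSumstats-class].
#' @return the per-SNP data.frame.
#' @export
setGeneric("sumstatsTable", function(x) standardGeneric("sumstatsTable"))

#' Fit indices of a fitted TSO model
#'
#' @param fit a [TSOFit-class].
#' @param data the data the model was fitted to.
#' @param ... further arguments (see methods).
#' @return list with `chisq`, `df`, `pvalue`, `cfi`, `rmsea`, `srmr`,
#'   `baseline_chisq`, `baseline_df`.
#' @export
setGeneric("fitIndices", function(fit, data, ...) standardGeneric("fitIndices"))

#' Fully standardised solution of a fitted TSO model
#'
#' @param fit a [TSOFit-class].
#' @param ... further arguments (see methods).
#' @return data.frame of raw and standardised estimates with
#'   delta-method standard errors.
#' @export
setGeneric("standardisedSolution",
           function(fit, ...) standardGeneric("standardisedSolution"))

#' Variance decomposition of the indicators
#'
#' @param fit a [TSOFit-class] from a baseline (no-predictor) model.
#' @param ... further arguments (see methods).
#' @return list with a per-indicator share table and per-source averages.
#' @export
setGeneric("varianceDecomposition",
           function(fit, ...) standardGeneric("varianceDecomposition"))

#' Sandwich robust standard errors
#'
#' @param fit a converged [TSOFit-class].
#' @param data the data the model was fitted to.
#' @param ... further arguments (see methods).
#' @return the fit, updated with a robust covariance matrix.
#' @export
setGeneric("robustSE", function(fit, data, ...) standardGeneric("robustSE"))
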