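#' Construct a GenotypePanel
#'
#' @param dosages numeric matrix of effect-allele dosages in `[0, 2]`,
#'   individuals in rows, SNPs in columns. Column names, when present,
#'   must match `snp_info$snp`.
#' @param snp_info data.frame with columns `snp`, `chr`, `bp`, `A1`,
#'   `A2`, `MAF` (one row per SNP, in column order of `dosages`).
#' @param sample_ids optional character vector of individual ids;
#'   defaults to `ind1..indN`.
#' @return a [GenotypePanel-class].
#' @examples
#' snp <- data.frame(snp = c("rs1", "rs2"), chr = "1", bp = c(100L, 200L),
#'                   A1 = c("A", "C"), A2 = c("G", "T"), MAF = c(0.3, 0.4))
#' gp <- GenotypePanel(matrix(c(0, 1, 2, 1), 2, 2), snp)
#' dosages(gp)
#' @export
GenotypePanel <- function(dosages, snp_info, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(snp_info) != ncol(dosages))
    stop("snp_info rows must match dosage columns", call. = FALSE)
  if (is.null(sample_ids))
    sample_ids <- paste0("ind", seq_len(nrow(dosages)))
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(snp_info$chr),
    ranges = IRanges::IRanges(start = as.integer(snp_info$bp), width = 1L))
  S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
    snp = as.character(snp_info$snp), A1 = as.character(snp_info$A1),
    A2 = as.character(snp_info$A2), MAF = as.numeric(snp_info$MAF))
  names(rr) <- snp_info$snp
  m <- t(dosages)
  dimnames(m) <- list(snp_info$snp, sample_ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = m), rowRanges = rr)
  new("GenotypePanel", se)
}

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypePanel", function(x)
  t(SummarizedExperiment::assay(x, "dosage")))

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "GenotypePanel", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(snp = S4Vectors::mcols(rr)$snp,
             chr = as.character(GenomicRanges::seqnames(rr)),
             bp = GenomicRanges::start(rr),
             A1 = S4Vectors::mcols(rr)$A1, A2 = S4Vectors::mcols(rr)$A2,
             MAF = S4Vectors::mcols(rr)$MAF,
             row.names = NULL)
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", ncol(object), "individuals x", nrow(object),
      "SNPs\n")
  info <- snpInfo(object)
  cat("  chromosomes:", paste(unique(info$chr), collapse = ", "), "\n")
  cat("  MAF range: [", round(min(info$MAF), 3), ",",
      round(max(info$MAF), 3), "]\n")
})

#' Construct a GwasSumstats object
#'
#' @param stats data.frame with columns `snp`, `chr`, `bp`, `A1`, `A2`,
#'   `beta`, `p` (and optionally `se`).
#' @param trait single string naming the trait.
#' @return a [GwasSumstats-class].
#' @export
GwasSumstats <- function(stats, trait = "trait") {
  stats <- as.data.frame(stats)
  if (!"se" %in% colnames(stats)) stats$se <- NA_real_
  stats$chr <- as.character(stats$chr)
  new("GwasSumstats", stats = stats, trait = trait)
}

#' @rdname sumstatsTable
#' @export
setMethod("sumstatsTable", "GwasSumstats", function(x) x@stats)

setMethod("show", "GwasSumstats", function(object) {
  cat("GwasSumstats for trait '", object@trait, "': ",
      nrow(object@stats), " SNPs", sep = "")
  if (object@harmonised)
    cat(" (harmonised: ", object@report$n_matched, " matched, ",
        object@report$n_flipped, " flipped, ", object@report$n_dropped,
        " dropped)", sep = "")
  cat("\n")
})

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy:", nrow(object@phenotypes), "phenotyped individuals,",
      nrow(object@genotypes), "SNPs,", length(object@sumstats),
      "simulated GWAS\n")
})

#' Accessors for SimulatedStudy components
#'
#' @param x a [SimulatedStudy-class].
#' @return `studyGenotypes()` the [GenotypePanel-class];
#'   `studySumstats()` the named list of [GwasSumstats-class];
#'   `studyPhenotypes()` the phenotype data.frame; `studyTruth()` the
#'   ground-truth list.
#' @name study-accessors
NULL

#' @rdname study-accessors
#' @export
studyGenotypes <- function(x) x@genotypes

#' @rdname study-accessors
#' @export
studySumstats <- function(x) x@sumstats

#' @rdname study-accessors
#' @export
studyPhenotypes <- function(x) x@phenotypes

#' @rdname study-accessors
#' @export
studyTruth <- function(x) x@truth
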