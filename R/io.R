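## Text-format I/O: genotype dosage TSV + SNP metadata TSV (optional
## VCF with a DS genotype field), GWAS summary-statistics TSV, phenotype
## CSV with empty-cell missing values, ground-truth JSON. Readers
## validate and report offending line numbers.

.file_lines <- function(rows) paste(rows + 1L, collapse = ", ")  # + header

#' Write / read a genotype panel as TSV
#'
#' The dosage file has individuals in rows (first column `id`) and SNPs
#' in columns; the metadata file has columns `snp`, `chr`, `bp`, `A1`,
#' `A2`, `MAF`.
#'
#' @param panel a [GenotypePanel-class].
#' @param dosage_file,meta_file output/input paths.
#' @return `writeGenotypes`: the paths, invisibly. `readGenotypes`: a
#'   [GenotypePanel-class].
#' @export
writeGenotypes <- function(panel, dosage_file, meta_file) {
  D <- dosages(panel)
  dt <- data.table::data.table(id = rownames(D))
  for (j in seq_len(ncol(D))) dt[[colnames(D)[j]]] <- D[, j]
  data.table::fwrite(dt, dosage_file, sep = "\t")
  data.table::fwrite(snpInfo(panel), meta_file, sep = "\t")
  invisible(c(dosage_file, meta_file))
}

#' @rdname writeGenotypes
#' @export
readGenotypes <- function(dosage_file, meta_file) {
  dt <- data.table::fread(dosage_file, sep = "\t", data.table = FALSE)
  if (colnames(dt)[1] != "id")
    stop("genotype file header must start with 'id'", call. = FALSE)
  meta <- data.table::fread(meta_file, sep = "\t", data.table = FALSE)
  need <- c("snp", "chr", "bp", "A1", "A2", "MAF")
  if (!all(need %in% colnames(meta)))
    stop("SNP metadata lacks columns: ",
         paste(setdiff(need, colnames(meta)), collapse = ", "),
         call. = FALSE)
  ids <- dt$id
  D <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(D)) {
    bad <- which(apply(dt[, -1, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(
                         as.numeric(r))) & !is.na(r))))
    stop("non-numeric dosages at line(s) ", .file_lines(bad),
         call. = FALSE)
  }
  if (!identical(colnames(D), meta$snp))
    stop("dosage columns do not match SNP metadata order", call. = FALSE)
  bad <- which(rowSums(!is.na(D) & (D < 0 | D > 2)) > 0)
  if (length(bad))
    stop("dosages outside [0, 2] at line(s) ", .file_lines(bad),
         call. = FALSE)
  GenotypePanel(D, meta, sample_ids = ids)
}

#' Write / read GWAS summary statistics as TSV
#'
#' Columns `SNP, CHR, BP, A1, A2, BETA, SE, P`.
#'
#' @param sumstats a [GwasSumstats-class].
#' @param path file path.
#' @param trait trait label attached on read.
#' @return `writeSumstats`: the path, invisibly. `readSumstats`: a
#'   [GwasSumstats-class].
#' @export
writeSumstats <- function(sumstats, path) {
  s <- sumstatsTable(sumstats)
  out <- data.frame(SNP = s$snp, CHR = s$chr, BP = s$bp, A1 = s$A1,
                    A2 = s$A2, BETA = s$beta, SE = s$se, P = s$p)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname writeSumstats
#' @export
readSumstats <- function(path, trait = "trait") {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P")
  if (!all(need %in% colnames(dt)))
    stop("sumstats header lacks columns: ",
         paste(setdiff(need, colnames(dt)), collapse = ", "),
         call. = FALSE)
  bad <- which(!(dt$A1 %in% c("A", "C", "G", "T")) |
                 !(dt$A2 %in% c("A", "C", "G", "T")))
  if (length(bad))
    stop("allele code outside {A,C,G,T} at line(s) ", .file_lines(bad),
         call. = FALSE)
  bad <- which(!is.finite(dt$BETA) | !is.finite(dt$P) | dt$P <= 0 |
                 dt$P > 1)
  if (length(bad))
    stop("invalid BETA/P at line(s) ", .file_lines(bad), call. = FALSE)
  GwasSumstats(data.frame(snp = dt$SNP, chr = as.character(dt$CHR),
                          bp = dt$BP, A1 = dt$A1, A2 = dt$A2,
                          beta = dt$BETA,
                          se = if ("SE" %in% colnames(dt)) dt$SE else NA,
                          p = dt$P),
               trait = trait)
}

#' Write / read the phenotype table as CSV
#'
#' Empty cells encode missing values. On read, indicator columns are
#' validated as numeric and rows with all indicators missing are
#' dropped (ids reported via message and the `"dropped_ids"` attribute).
#'
#' @param phenotypes data.frame (id, sex, pc1..pc10, indicators).
#' @param path file path.
#' @return `writePhenotypes`: the path, invisibly. `readPhenotypes`: the
#'   validated data.frame.
#' @export
writePhenotypes <- function(phenotypes, path) {
  data.table::fwrite(phenotypes, path, sep = ",", na = "")
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  dt <- data.table::fread(path, sep = ",", data.table = FALSE,
                          na.strings = "")
  ind <- intersect(indicatorNames(), colnames(dt))
  if (!length(ind))
    stop("phenotype file has no recognised indicator columns",
         call. = FALSE)
  for (cn in ind) {
    if (!is.numeric(dt[[cn]])) {
      bad <- which(!is.na(dt[[cn]]) &
                     is.na(suppressWarnings(as.numeric(dt[[cn]]))))
      stop("non-numeric phenotype '", cn, "' at line(s) ",
           .file_lines(bad), call. = FALSE)
    }
  }
  all_missing <- rowSums(!is.na(dt[, ind, drop = FALSE])) == 0L
  if (any(all_missing)) {
    message(sum(all_missing), " all-missing phenotype rows dropped: ",
            paste(head(dt$id[all_missing], 5), collapse = ", "),
            if (sum(all_missing) > 5) ", ...")
    dropped <- dt$id[all_missing]
    dt <- dt[!all_missing, , drop = FALSE]
    rownames(dt) <- NULL
    attr(dt, "dropped_ids") <- dropped
  }
  dt
}

#' Write ground truth as JSON
#'
#' @param truth truth list from a [SimulatedStudy-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, matrix = "columnmajor")
  invisible(path)
}

#' Read a ground-truth JSON file
#'
#' @param path file written by [writeTruth()].
#' @return truth list (matrices restored where unambiguous).
#' @export
readTruth <- function(path) jsonlite::fromJSON(path)

#' Export a genotype panel as VCF with dosage field
#'
#' Writes a minimal VCFv4.2 file carrying the effect-allele dosage in a
#' `DS` FORMAT field (REF = other allele, ALT = effect allele).
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportVCF <- function(panel, path) {
  info <- snpInfo(panel)
  D <- dosages(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(D)),
                     collapse = "\t")), con)
  body <- vapply(seq_len(nrow(info)), function(i)
    paste(c(info$chr[i], info$bp[i], info$snp[i], info$A2[i],
            info$A1[i], ".", "PASS", ".", "DS",
            format(D[, i], trim = TRUE)), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read dosages from a VCF with a DS field
#'
#' Uses VariantAnnotation to parse the file; the effect allele is the
#' ALT allele.
#'
#' @param path VCF path.
#' @return a [GenotypePanel-class].
#' @export
readVcfDosages <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  ds <- VariantAnnotation::geno(vcf)$DS
  if (is.null(ds)) stop("VCF has no DS genotype field", call. = FALSE)
  ds <- apply(ds, 2, as.numeric)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(S4Vectors::mcols(rr)$ALT))
  ref <- as.character(S4Vectors::mcols(rr)$REF)
  dos <- t(ds)
  f <- colMeans(dos, na.rm = TRUE) / 2
  info <- data.frame(snp = names(rr),
                     chr = as.character(GenomicRanges::seqnames(rr)),
                     bp = GenomicRanges::start(rr), A1 = alt, A2 = ref,
                     MAF = pmin(f, 1 - f))
  GenotypePanel(dos, info, sample_ids = rownames(dos))
}

#' Write an association table as TSV
#'
#' Mirrors the reporting layout of the association stages: one row per
#' (model, PGS, factor) with standardised estimate, CI, robust SE and
#' raw/FDR p-values.
#'
#' @param table association table from [runSinglePGS()] /
#'   [runMultiPGS()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeAssociationTable <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}
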