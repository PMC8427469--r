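## Polygenic scoring: harmonisation of GWAS summary statistics to the
## genotype panel, greedy LD clumping, weighted allele-dosage scoring at
## a p-value threshold, and standardisation.

#' Harmonise summary statistics to a genotype panel
#'
#' Aligns each summary-statistic row to the panel's allele coding: SNPs
#' absent from the panel are dropped; rows whose effect allele equals
#' the panel's other allele have the beta sign flipped and the alleles
#' swapped; strand-ambiguous SNPs (A/T, C/G) and rows whose alleles do
#' not match the panel at all are dropped. A report of counts is stored
#' on the returned object.
#'
#' @param sumstats a [GwasSumstats-class].
#' @param genotypes a [GenotypePanel-class] (or its [snpInfo()] table).
#' @return harmonised [GwasSumstats-class] whose rows are a subset of
#'   the panel SNPs, all expressed on the panel's A1 allele.
#' @export
harmoniseSumstats <- function(sumstats, genotypes) {
  s <- sumstatsTable(sumstats)
  panel <- if (is(genotypes, "GenotypePanel")) snpInfo(genotypes)
           else as.data.frame(genotypes)
  m <- match(s$snp, panel$snp)
  n_absent <- sum(is.na(m))
  keep <- !is.na(m)
  s <- s[keep, , drop = FALSE]
  pm <- panel[m[keep], , drop = FALSE]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- s$A1 == comp[s$A2]
  aligned <- s$A1 == pm$A1 & s$A2 == pm$A2
  flipped <- s$A1 == pm$A2 & s$A2 == pm$A1
  mismatch <- !aligned & !flipped
  s$beta[flipped] <- -s$beta[flipped]
  s$A1[flipped] <- pm$A1[flipped]
  s$A2[flipped] <- pm$A2[flipped]
  ok <- !ambiguous & !mismatch
  out <- s[ok, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("harmonisation left no overlapping SNPs between sumstats and panel",
         call. = FALSE)
  rownames(out) <- NULL
  res <- GwasSumstats(out, trait = sumstats@trait)
  res@harmonised <- TRUE
  res@report <- list(n_input = nrow(sumstatsTable(sumstats)),
                     n_matched = nrow(out),
                     n_flipped = sum(flipped & ok),
                     n_dropped = n_absent + sum(!ok),
                     n_ambiguous = sum(ambiguous),
                     n_allele_mismatch = sum(mismatch & !ambiguous))
  res
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the dosage vectors of two panel SNPs
#' across individuals.
#'
#' @param genotypes a [GenotypePanel-class].
#' @param snp_i,snp_j SNP ids or column indices.
#' @return r-squared in `[0, 1]`.
#' @export
ldR2 <- function(genotypes, snp_i, snp_j) {
  G <- dosages(genotypes)
  info <- snpInfo(genotypes)
  pick <- function(s) if (is.character(s)) match(s, info$snp) else s
  i <- pick(snp_i); j <- pick(snp_j)
  if (is.na(i) || is.na(j)) stop("SNP not in panel", call. = FALSE)
  vi <- stats::var(G[, i]); vj <- stats::var(G[, j])
  if (vi == 0 || vj == 0)
    stop("undefined LD: zero-variance SNP", call. = FALSE)
  stats::cor(G[, i], G[, j])^2
}

#' Greedy LD clumping
#'
#' Sorts SNPs by ascending p-value (ties broken by position, then SNP
#' id), then repeatedly takes the most significant remaining SNP as an
#' index SNP and removes every remaining same-chromosome SNP within
#' `window_kb` kilobases whose r-squared with the index exceeds
#' `r2_threshold`. The retained set is the index SNPs.
#'
#' @param sumstats harmonised [GwasSumstats-class].
#' @param genotypes a [GenotypePanel-class].
#' @param r2_threshold LD pruning threshold (default 0.10).
#' @param window_kb physical window in kilobases (default 250).
#' @return character vector of retained SNP ids.
#' @export
clumpSnps <- function(sumstats, genotypes, r2_threshold = 0.10,
                      window_kb = 250) {
  s <- sumstatsTable(sumstats)
  G <- dosages(genotypes)
  info <- snpInfo(genotypes)
  col <- match(s$snp, info$snp)
  stopifnot(!anyNA(col))
  ord <- order(s$p, s$bp, s$snp)
  s <- s[ord, , drop = FALSE]
  col <- col[ord]
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, nrow(s))
  retained <- character(0)
  Gc <- scale(G[, col, drop = FALSE], center = TRUE, scale = FALSE)
  nrm <- sqrt(colSums(Gc^2))
  for (i in seq_len(nrow(s))) {
    if (!alive[i]) next
    retained <- c(retained, s$snp[i])
    alive[i] <- FALSE
    cand <- which(alive & s$chr == s$chr[i] &
                    abs(s$bp - s$bp[i]) <= window_bp)
    if (!length(cand)) next
    if (nrm[i] == 0) next
    r <- drop(crossprod(Gc[, cand, drop = FALSE], Gc[, i])) /
      (nrm[cand] * nrm[i])
    r[!is.finite(r)] <- 0
    alive[cand[r^2 > r2_threshold]] <- FALSE
  }
  retained
}

#' Polygenic score from retained SNPs
#'
#' Per-individual weighted allele sum over the retained SNPs whose
#' p-value does not exceed `p_threshold`:
#' `score_i = sum_j beta_j * dosage_ij`. Missing dosages contribute the
#' SNP's mean dosage (mean imputation).
#'
#' @param genotypes a [GenotypePanel-class].
#' @param sumstats harmonised [GwasSumstats-class].
#' @param retained character vector of retained SNP ids (from
#'   [clumpSnps()]).
#' @param p_threshold p-value inclusion threshold (default 1, all SNPs).
#' @return numeric vector of raw scores with attribute `"provenance"`
#'   (trait, SNP counts, threshold).
#' @export
scorePGS <- function(genotypes, sumstats, retained, p_threshold = 1) {
  s <- sumstatsTable(sumstats)
  if (length(retained) == 0L)
    stop("empty retained SNP set: no score can be computed", call. = FALSE)
  stopifnot(all(retained %in% s$snp))
  use <- s[s$snp %in% retained & s$p <= p_threshold, , drop = FALSE]
  G <- dosages(genotypes)
  info <- snpInfo(genotypes)
  col <- match(use$snp, info$snp)
  stopifnot(!anyNA(col))
  Gm <- G[, col, drop = FALSE]
  if (anyNA(Gm)) {
    mu <- colMeans(Gm, na.rm = TRUE)
    for (j in seq_len(ncol(Gm))) {
      nas <- is.na(Gm[, j])
      if (any(nas)) Gm[nas, j] <- mu[j]
    }
  }
  score <- drop(Gm %*% use$beta)
  if (!length(score)) score <- numeric(nrow(G))
  attr(score, "provenance") <- list(trait = sumstats@trait,
                                    n_snps_used = nrow(use),
                                    n_retained = length(retained),
                                    p_threshold = p_threshold)
  score
}

#' Standardise a polygenic score
#'
#' Centres and scales to sample standard deviation 1 (n - 1
#' denominator).
#'
#' @param score numeric score vector.
#' @return standardised scores (mean 0, variance 1), provenance
#'   attribute preserved.
#' @export
standardiseScores <- function(score) {
  out <- standardise_vector(as.numeric(score), "polygenic score")
  attr(out, "provenance") <- c(attr(score, "provenance"),
                               list(standardised = TRUE))
  out
}

#' Harmonise, clump, score and standardise in one call
#'
#' @param genotypes a [GenotypePanel-class].
#' @param sumstats a [GwasSumstats-class] (raw; harmonised internally).
#' @param r2_threshold,window_kb,p_threshold see [clumpSnps()] and
#'   [scorePGS()].
#' @return list with `score` (standardised), `harmonised` sumstats,
#'   `retained` SNP ids and a `report` list.
#' @export
buildPGS <- function(genotypes, sumstats, r2_threshold = 0.10,
                     window_kb = 250, p_threshold = 1) {
  h <- harmoniseSumstats(sumstats, genotypes)
  retained <- clumpSnps(h, genotypes, r2_threshold, window_kb)
  raw <- scorePGS(genotypes, h, retained, p_threshold)
  score <- standardiseScores(raw)
  list(score = score, harmonised = h, retained = retained,
       report = c(h@report,
                  list(n_retained = length(retained),
                       r2_threshold = r2_threshold, window_kb = window_kb,
                       p_threshold = p_threshold)))
}
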