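# Polygenic scoring: harmonisation, LD r2, greedy clumping against a
# brute-force oracle, weighted scoring, standardisation, end-to-end
# recovery of the true genetic value.

test_that("already-aligned sumstats pass through minus ambiguous SNPs", {
  gp <- simulateGenotypes(100, 30, ambiguous_fraction = 0.3, seed = 1)
  info <- snpInfo(gp)
  ss <- GwasSumstats(data.frame(snp = info$snp, chr = info$chr,
                                bp = info$bp, A1 = info$A1, A2 = info$A2,
                                beta = seq(0.01, 0.30, by = 0.01),
                                p = rep(0.5, 30)))
  h <- harmoniseSumstats(ss, gp)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambig <- info$A1 == comp[info$A2]
  expect_equal(sumstatsTable(h)$snp, info$snp[!ambig])
  expect_equal(sumstatsTable(h)$beta, seq(0.01, 0.30, by = 0.01)[!ambig])
  expect_equal(h@report$n_ambiguous, sum(ambig))
})

test_that("a swapped-allele row is sign-flipped", {
  snp <- data.frame(snp = "rs1", chr = "1", bp = 100L, A1 = "A",
                    A2 = "G", MAF = 0.3)
  gp <- GenotypePanel(matrix(c(0, 1, 2), 3, 1), snp)
  ss <- GwasSumstats(data.frame(snp = "rs1", chr = "1", bp = 100L,
                                A1 = "G", A2 = "A", beta = 0.2, p = 0.1))
  h <- harmoniseSumstats(ss, gp)
  expect_equal(sumstatsTable(h)$beta, -0.2)
  expect_equal(sumstatsTable(h)$A1, "A")
  expect_equal(h@report$n_flipped, 1L)
  expect_error(harmoniseSumstats(
    GwasSumstats(data.frame(snp = "zz", chr = "1", bp = 1L, A1 = "A",
                            A2 = "G", beta = 1, p = 0.5)), gp),
    "no overlapping")
})

test_that("simulated swaps are fully restored against the truth record", {
  gp <- simulateGenotypes(200, 80, ld_block_size = 1,
                          ambiguous_fraction = 0.25, seed = 6)
  w <- rnorm(80, 0, 0.05)
  ss <- simulateSumstats(gp, w, Inf, seed = 7, swap_fraction = 0.4)
  h <- harmoniseSumstats(ss, gp)
  tab <- sumstatsTable(h)
  truth <- w[match(tab$snp, snpInfo(gp)$snp)]
  expect_equal(tab$beta, truth)   # noise-free: exact restoration
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  info <- snpInfo(gp)
  expect_equal(nrow(tab), sum(info$A1 != comp[info$A2]))
})

test_that("ldR2 equals the squared Pearson correlation of dosages", {
  gp <- tiny_panel()
  expect_equal(ldR2(gp, "rs1", "rs1"), 1.0)
  snp <- data.frame(snp = c("a", "b"), chr = "1", bp = c(1L, 2L),
                    A1 = "A", A2 = "G", MAF = 0.5)
  gp2 <- GenotypePanel(cbind(c(0, 1, 2, 0), c(2, 1, 0, 2)), snp)
  expect_equal(ldR2(gp2, "a", "b"), 1.0)  # perfect negative correlation
  gp3 <- simulateGenotypes(50, 2, ld_block_size = 2, ld_rho = 0.5,
                           seed = 9)
  D <- dosages(gp3)
  direct <- (sum((D[, 1] - mean(D[, 1])) * (D[, 2] - mean(D[, 2]))) /
               sqrt(sum((D[, 1] - mean(D[, 1]))^2) *
                      sum((D[, 2] - mean(D[, 2]))^2)))^2
  expect_equal(ldR2(gp3, 1, 2), direct, tolerance = 1e-12)
  gp4 <- GenotypePanel(cbind(c(1, 1, 1), c(0, 1, 2)),
                       data.frame(snp = c("c", "d"), chr = "1",
                                  bp = c(1L, 2L), A1 = "A", A2 = "G",
                                  MAF = 0.5))
  expect_error(ldR2(gp4, "c", "d"), "zero-variance")
})

test_that("clumping retains the most significant SNP per LD clump", {
  # single SNP: trivially retained
  gp1 <- simulateGenotypes(50, 1, seed = 2)
  info <- snpInfo(gp1)
  ss1 <- GwasSumstats(data.frame(snp = info$snp, chr = info$chr,
                                 bp = info$bp, A1 = info$A1,
                                 A2 = info$A2, beta = 0.1, p = 0.5))
  expect_equal(clumpSnps(ss1, gp1), info$snp)
  # two perfectly correlated SNPs 10 kb apart: only the smaller p stays
  D <- cbind(c(0, 1, 2, 0, 1), c(0, 1, 2, 0, 1))
  snp <- data.frame(snp = c("s1", "s2"), chr = "1",
                    bp = c(10000L, 20000L), A1 = "A", A2 = "G",
                    MAF = 0.4)
  gp2 <- GenotypePanel(D, snp)
  ss2 <- GwasSumstats(data.frame(snp = c("s1", "s2"), chr = "1",
                                 bp = c(10000L, 20000L), A1 = "A",
                                 A2 = "G", beta = 0.1,
                                 p = c(1e-4, 1e-8)))
  expect_equal(clumpSnps(ss2, gp2), "s2")
})

test_that("clumping matches the brute-force oracle on random instances", {
  for (rep in 1:10) {
    gp <- simulateGenotypes(150, 15, ld_block_size = 5, ld_rho = 0.85,
                            seed = 100 + rep)
    info <- snpInfo(gp)
    ss <- withr::with_seed(200 + rep, GwasSumstats(
      data.frame(snp = info$snp, chr = info$chr, bp = info$bp,
                 A1 = info$A1, A2 = info$A2, beta = rnorm(15),
                 p = runif(15))))
    G <- dosages(gp)
    colnames(G) <- info$snp
    expect_identical(clumpSnps(ss, gp),
                     brute_clump(sumstatsTable(ss), G))
  }
})

test_that("clumping is invariant to input row order", {
  gp <- simulateGenotypes(120, 12, ld_block_size = 4, ld_rho = 0.9,
                          seed = 33)
  info <- snpInfo(gp)
  ss <- withr::with_seed(34, GwasSumstats(
    data.frame(snp = info$snp, chr = info$chr, bp = info$bp,
               A1 = info$A1, A2 = info$A2, beta = rnorm(12),
               p = runif(12))))
  perm <- withr::with_seed(35, sample(12))
  ss_perm <- GwasSumstats(sumstatsTable(ss)[perm, ])
  expect_identical(sort(clumpSnps(ss, gp)),
                   sort(clumpSnps(ss_perm, gp)))
})

test_that("scores are weighted dosage sums with mean imputation", {
  snp <- data.frame(snp = c("s1", "s2"), chr = "1", bp = c(1e4, 4e5),
                    A1 = "A", A2 = "G", MAF = 0.4)
  gp <- GenotypePanel(matrix(c(0, 1, 2, 1), 2, 2), snp)
  ss <- GwasSumstats(data.frame(snp = c("s1", "s2"), chr = "1",
                                bp = c(1e4, 4e5), A1 = "A", A2 = "G",
                                beta = c(0.1, -0.2), p = c(0.5, 1)))
  h <- harmoniseSumstats(ss, gp)
  sc <- scorePGS(gp, h, c("s1", "s2"))
  expect_equal(as.numeric(sc), c(0 * 0.1 + 2 * -0.2,
                                 1 * 0.1 + 1 * -0.2))
  # zero weights: all-zero scores
  ss0 <- GwasSumstats(data.frame(snp = c("s1", "s2"), chr = "1",
                                 bp = c(1e4, 4e5), A1 = "A", A2 = "G",
                                 beta = 0, p = 0.5))
  expect_equal(as.numeric(scorePGS(gp, harmoniseSumstats(ss0, gp),
                                   c("s1", "s2"))), c(0, 0))
  # p threshold drops exactly the p = 1 SNP's contribution
  sc99 <- scorePGS(gp, h, c("s1", "s2"), p_threshold = 0.999999)
  expect_equal(as.numeric(sc) - as.numeric(sc99), c(2, 1) * -0.2)
  # missing dosage contributes the SNP mean
  Dna <- matrix(c(0, 1, NA, 1), 2, 2)
  gp_na <- GenotypePanel(Dna, snp)
  sc_na <- scorePGS(gp_na, h, c("s1", "s2"))
  expect_equal(as.numeric(sc_na)[1], 0 * 0.1 + 1 * -0.2)
  expect_error(scorePGS(gp, h, character(0)), "empty retained")
})

test_that("standardisation has mean 0, variance 1, and is idempotent", {
  expect_equal(as.numeric(standardiseScores(c(1, 2, 3))), c(-1, 0, 1))
  x <- withr::with_seed(4, rnorm(100, 5, 3))
  z <- standardiseScores(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(var(z) - 1), 1e-10)
  expect_equal(as.numeric(standardiseScores(as.numeric(z))),
               as.numeric(z), tolerance = 1e-12)
  expect_error(standardiseScores(rep(2, 5)), "zero variance")
})

test_that("the standardised PGS recovers the true genetic value", {
  # no LD, no discovery noise: correlation with truth > 0.99
  gp <- simulateGenotypes(2000, 100, ld_block_size = 1, ld_rho = 0,
                          seed = 55)
  w <- withr::with_seed(56, rnorm(100, 0, 0.05))
  ss <- simulateSumstats(gp, w, Inf, seed = 57, swap_fraction = 0.2)
  built <- buildPGS(gp, ss)
  truth <- drop(dosages(gp) %*% w)
  expect_gt(cor(built$score, truth), 0.99)
})

test_that("scores are invariant to joint allele-orientation flips", {
  gp <- simulateGenotypes(300, 40, ld_block_size = 4, seed = 61)
  w <- withr::with_seed(62, rnorm(40, 0, 0.05))
  ss <- simulateSumstats(gp, w, 50000, seed = 63)
  s1 <- buildPGS(gp, ss)$score
  # recode every SNP to the opposite allele in both panel and sumstats
  info <- snpInfo(gp)
  info2 <- info
  info2$A1 <- info$A2; info2$A2 <- info$A1
  gp2 <- GenotypePanel(2 - dosages(gp), info2,
                       sample_ids = rownames(dosages(gp)))
  s2 <- buildPGS(gp2, ss)$score
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-10)
})
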