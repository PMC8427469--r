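# Synthetic-data generator: configuration guards, genotype copula
# structure, summary-statistic noise model, latent phenotype structure,
# missingness mechanisms, determinism.

test_that("invalid configurations are rejected", {
  expect_error(simConfig(n_individuals = 0), "positive")
  expect_error(simConfig(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simConfig(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simConfig(ld_rho = 1), "ld_rho")
  expect_error(simConfig(discovery_n = 1), "discovery_n")
  expect_error(simConfig(residual_sds = rep(-1, 12)), "residual_sds")
  expect_error(simConfig(missing_rate = 1), "missing_rate")
  expect_error(simulateGenotypes(-5, 10), "positive")
})

test_that("genotypes are HWE-consistent dosages with block structure", {
  gp <- simulateGenotypes(10000, 20, maf_range = c(0.5, 0.5),
                          ld_block_size = 5, ld_rho = 0.4, seed = 7)
  D <- dosages(gp)
  expect_true(all(D %in% 0:2))
  # binomial mean 2 * 0.5 at every SNP
  expect_true(all(abs(colMeans(D) - 1) < 0.05))
  info <- snpInfo(gp)
  # one block spans far less than the 250 kb clumping window,
  # consecutive blocks on a chromosome are farther apart than it
  b1 <- info$bp[1:5]
  expect_lt(max(b1) - min(b1), 250000)
  same_chr <- split(info$bp, info$chr)
  for (bp in same_chr) {
    gaps <- diff(sort(bp))
    expect_gt(max(gaps), 250000)
  }
})

test_that("ld_rho = 0 gives independent adjacent SNPs", {
  gp <- simulateGenotypes(5000, 30, maf_range = c(0.2, 0.4),
                          ld_block_size = 10, ld_rho = 0, seed = 11)
  D <- dosages(gp)
  r <- sapply(seq_len(29), function(j) cor(D[, j], D[, j + 1]))
  expect_lt(mean(abs(r)), 0.05)
})

test_that("adjacent-SNP r2 matches a brute-force copula oracle", {
  rho <- 0.9; f <- 0.3
  gp <- simulateGenotypes(20000, 10, maf_range = c(f, f),
                          ld_block_size = 10, ld_rho = rho, seed = 13)
  D <- dosages(gp)
  r2_obs <- mean(sapply(1:9, function(j) cor(D[, j], D[, j + 1])^2))
  # oracle: >= 1e6 haplotype draws from the same Gaussian-threshold
  # copula, doubled into dosages
  withr::with_seed(1, {
    nh <- 2e6
    z1 <- rnorm(nh); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nh)
    a1 <- as.integer(z1 < qnorm(f)); a2 <- as.integer(z2 < qnorm(f))
    half <- nh / 2
    d1 <- a1[1:half] + a1[(half + 1):nh]
    d2 <- a2[1:half] + a2[(half + 1):nh]
    r2_oracle <- cor(d1, d2)^2
  })
  expect_lt(abs(r2_obs - r2_oracle), 0.05)
})

test_that("summary statistics follow the discovery-noise model", {
  gp <- simulateGenotypes(200, 1000, maf_range = c(0.1, 0.5),
                          ld_block_size = 1, ld_rho = 0, seed = 3)
  w <- rep(0, 1000)
  # zero-noise limit: infinite discovery sample reproduces the truth
  ss0 <- simulateSumstats(gp, w + 0.3, Inf, seed = 5)
  expect_equal(sumstatsTable(ss0)$beta, w + 0.3)
  # null weights: uniform p-values
  ss <- simulateSumstats(gp, w, 20000, seed = 5)
  expect_lt(abs(mean(sumstatsTable(ss)$p < 0.05) - 0.05), 0.02)
  expect_error(simulateSumstats(gp, w, 1), "discovery_n")
})

test_that("reported-beta dispersion matches the analytic se oracle", {
  gp1 <- simulateGenotypes(100, 1, maf_range = c(0.25, 0.25),
                           ld_block_size = 1, seed = 2)
  f <- snpInfo(gp1)$MAF
  n_disc <- 15000
  se_oracle <- 1 / sqrt(n_disc * 2 * f * (1 - f))
  betas <- vapply(1:2000, function(s)
    sumstatsTable(simulateSumstats(gp1, 0.1, n_disc, seed = s))$beta,
    numeric(1))
  expect_lt(abs(sd(betas) / se_oracle - 1), 0.05)
  expect_lt(abs(mean(betas) - 0.1), 3 * se_oracle / sqrt(2000))
})

test_that("zero common loadings remove cross-substance correlation", {
  gp <- simulateGenotypes(5000, 20, seed = 8)
  cfg <- simConfig(n_individuals = 5000, n_snps = 20,
                   traits = "risk_taking", lambda_common = rep(0, 12),
                   missing_rate = 0, seed = 8)
  cfg$true_weights <- matrix(0.05, 20, 1,
                             dimnames = list(NULL, "risk_taking"))
  sim <- simulatePhenotypes(gp, cfg, seed = 8)
  y <- as.matrix(sim$phenotypes[, indicatorNames()])
  cc <- cor(y)
  cross <- cc[1:3, 4:12]  # cigarette block against other substances
  # occasion factors still tie same-wave scores; compare different waves
  off_wave <- cross[cbind(c(1, 2, 3), c(2, 3, 1))]
  expect_lt(mean(abs(off_wave)), 0.03 + 0.02)
})

test_that("an injected structural effect is recovered in the truth record", {
  gp <- simulateGenotypes(50000, 20, seed = 12)
  pe <- matrix(0, 5, 1, dimnames = list(c("C", "S_cig", "S_alc",
                                          "S_can", "S_oth"),
                                        "risk_taking"))
  pe["C", 1] <- 0.14
  cfg <- simConfig(n_individuals = 50000, n_snps = 20,
                   traits = "risk_taking", pgs_effects = pe,
                   missing_rate = 0, seed = 12)
  cfg$true_weights <- matrix(rnorm(20, 0, 0.05), 20, 1,
                             dimnames = list(NULL, "risk_taking"))
  sim <- simulatePhenotypes(gp, cfg, seed = 12)
  r <- cor(sim$truth$pgs_true[, 1], sim$truth$factors[, "C"])
  expect_lt(abs(r - 0.14), 0.02)
})

test_that("continuous indicators match the model-implied covariance", {
  st <- cached_fixture("big_continuous", function() {
    cfg <- simConfig(n_individuals = 50000, n_snps = 20,
                     traits = "risk_taking", missing_rate = 0,
                     discretise = FALSE, seed = 31)
    gp <- simulateGenotypes(50000, 20, seed = 31)
    cfg$true_weights <- matrix(0.05, 20, 1,
                               dimnames = list(NULL, "risk_taking"))
    simulatePhenotypes(gp, cfg, seed = 31)
  })
  cfg <- simConfig(n_individuals = 100, n_snps = 10, seed = 1)
  lc <- cfg$lambda_common; ls <- cfg$lambda_specific
  th <- cfg$residual_sds^2
  # covariance algebra oracle for the generating structure
  # (the small injected PGS effect enters C, variance-normalised away)
  imp <- matrix(0, 12, 12)
  sub <- rep(1:4, each = 3); occ <- rep(1:3, 4)
  for (i in 1:12) for (j in 1:12) {
    imp[i, j] <- lc[i] * lc[j] +
      (sub[i] == sub[j]) * ls[i] * ls[j] + (occ[i] == occ[j]) * 1 +
      (i == j) * th[i]
  }
  S <- cov(as.matrix(st$truth$continuous))
  expect_lt(max(abs(S - imp)), 0.05 * max(diag(imp)) / 2)
  # latent factors: unit variances, mutual orthogonality
  fv <- apply(st$truth$factors, 2, var)
  expect_true(all(abs(fv - 1) < 0.05))
  cf <- cor(st$truth$factors)
  expect_lt(max(abs(cf[upper.tri(cf)])), 0.03)
})

test_that("discretised indicators are bounded integers", {
  ph <- studyPhenotypes(small_study())
  cm <- rep(c(10, 40, 24, 15), each = 3)
  y <- as.matrix(ph[, indicatorNames()])
  for (i in 1:12) {
    v <- y[, i][!is.na(y[, i])]
    expect_true(all(v == round(v) & v >= 0 & v <= cm[i]))
  }
})

test_that("missingness mechanisms behave as specified", {
  gp <- simulateGenotypes(10000, 10, seed = 17)
  cfg <- simConfig(n_individuals = 10000, n_snps = 10,
                   traits = "risk_taking", missing_rate = 0, seed = 17)
  cfg$true_weights <- matrix(0.05, 10, 1,
                             dimnames = list(NULL, "risk_taking"))
  sim <- simulatePhenotypes(gp, cfg, seed = 17)
  ph <- sim$phenotypes
  # rate 0: identity
  expect_identical(injectMissingness(ph, 0, "MCAR", seed = 1)[, -1],
                   ph[, -1])
  # MCAR rate on a single indicator: binomial fraction
  rates <- c(0.3, rep(0, 11))
  out <- injectMissingness(ph, rates, "MCAR", seed = 2)
  expect_lt(abs(mean(is.na(out$cig_17)) - 0.3), 0.02)
  expect_false(anyNA(out$sex))
  # MAR on sex: empirical missingness per sex matches the logistic
  # oracle recomputed from the mechanism's formula
  out2 <- injectMissingness(ph, rates, "MAR", seed = 3,
                            mar_covariate = "sex", mar_slope = 1.5)
  p_emp <- tapply(is.na(out2$cig_17), out2$sex, mean)
  z <- ph$sex
  p_orc <- tapply(plogis(qlogis(0.3) + 1.5 * (z - mean(z))), z, mean)
  expect_lt(abs(p_emp[["0"]] - p_orc[["0"]]), 0.02)
  expect_lt(abs(p_emp[["1"]] - p_orc[["1"]]), 0.02)
  expect_gt(p_emp[["1"]], p_emp[["0"]])
  expect_error(injectMissingness(ph, 1, "MCAR"), "missing_rate")
})

test_that("all-missing rows are dropped and counted", {
  gp <- simulateGenotypes(300, 10, seed = 19)
  cfg <- simConfig(n_individuals = 300, n_snps = 10,
                   traits = "risk_taking", missing_rate = 0, seed = 19)
  cfg$true_weights <- matrix(0.05, 10, 1,
                             dimnames = list(NULL, "risk_taking"))
  ph <- simulatePhenotypes(gp, cfg, seed = 19)$phenotypes
  out <- injectMissingness(ph, 0.9, "MCAR", seed = 4)
  expect_gt(attr(out, "n_dropped"), 0)
  expect_equal(nrow(out) + attr(out, "n_dropped"), nrow(ph))
  kept <- as.matrix(out[, indicatorNames()])
  expect_true(all(rowSums(!is.na(kept)) > 0))
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- simConfig(n_individuals = 150, n_snps = 30,
                   traits = c("risk_taking", "bmi"), seed = 77)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(dosages(studyGenotypes(s1)),
                   dosages(studyGenotypes(s2)))
  expect_identical(studyPhenotypes(s1), studyPhenotypes(s2))
  expect_identical(sumstatsTable(studySumstats(s1)[[1]]),
                   sumstatsTable(studySumstats(s2)[[1]]))
})

test_that("over-strong effects on a factor are rejected", {
  gp <- simulateGenotypes(200, 10, seed = 23)
  pe <- matrix(0, 5, 1, dimnames = list(c("C", "S_cig", "S_alc",
                                          "S_can", "S_oth"), "t"))
  pe["C", 1] <- 1.2
  cfg <- simConfig(n_individuals = 200, n_snps = 10, traits = "t",
                   pgs_effects = pe, missing_rate = 0, seed = 23)
  cfg$true_weights <- matrix(0.1, 10, 1, dimnames = list(NULL, "t"))
  expect_error(simulatePhenotypes(gp, cfg), "variance > 1")
})
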