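# Association stages: BH-FDR against the definitional oracle, selection,
# single- versus multi-PGS behaviour.

test_that("bhFdr matches hand-computed and brute-force step-up values", {
  expect_equal(bhFdr(0.2), 0.2)                        # m = 1
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (rep in 1:25) {
    p <- withr::with_seed(rep, runif(sample(1:10, 1)))
    expect_equal(bhFdr(p), brute_bh(p), tolerance = 1e-12)
    expect_equal(bhFdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_identical(bhFdr(numeric(0)), numeric(0))
  expect_error(bhFdr(c(0.5, 0)), "p-values")
})

test_that("adjusted p-values respect families, order and NAs", {
  p <- c(0.01, 0.5, 0.02, 0.6)
  fam <- c("a", "a", "b", "b")
  q <- bhFdr(p, fam)
  expect_equal(q[1:2], brute_bh(p[1:2]))
  expect_equal(q[3:4], brute_bh(p[3:4]))
  # monotone in raw p within a family
  pr <- withr::with_seed(7, runif(30))
  qr <- bhFdr(pr)
  expect_true(all(diff(qr[order(pr)]) > -1e-12))
  expect_true(all(qr >= pr))
  # NA rows are excluded from the family size
  pn <- c(0.02, NA, 0.04)
  qn <- bhFdr(pn)
  expect_true(is.na(qn[2]))
  expect_equal(qn[c(1, 3)], brute_bh(c(0.02, 0.04)))
})

test_that("family-wise discovery rate is controlled under the null", {
  withr::with_seed(11, {
    n_disc <- vapply(1:500, function(i) {
      q <- bhFdr(runif(18))
      any(q < 0.05)
    }, logical(1))
  })
  mc <- 2 * sqrt(0.05 * 0.95 / 500)
  expect_lte(mean(n_disc), 0.05 + 2 * mc)
})

test_that("selection partitions FDR-significant PGSs by category", {
  tab <- data.frame(
    model = "single", pgs = rep(c("cig_frequency", "risk_taking",
                                  "bmi"), 2),
    factor = rep(c("C", "S_cig"), each = 3),
    p_fdr = c(0.01, 0.2, 0.03, 0.5, 0.04, 0.9))
  sel <- selectSignificant(tab, alpha = 0.05)
  expect_equal(sel$C$substance, "cig_frequency")
  expect_equal(sel$C$trait, "bmi")
  expect_equal(sel$S_cig$trait, "risk_taking")
  expect_length(sel$S_cig$substance, 0)
  # all above alpha: empty sets
  tab$p_fdr <- 0.9
  sel2 <- selectSignificant(tab)
  expect_true(all(lengths(unlist(sel2, recursive = FALSE)) == 0))
  expect_error(selectSignificant(
    data.frame(pgs = "mystery", factor = "C", p_fdr = 0.01)),
    "no category")
})

test_that("single-PGS models recover an injected common-factor effect", {
  gp <- simulateGenotypes(2500, 30, seed = 201)
  pe <- matrix(0, 5, 2, dimnames = list(c("C", "S_cig", "S_alc",
                                          "S_can", "S_oth"),
                                        c("risk_taking", "bmi")))
  pe["C", "risk_taking"] <- 0.25
  cfg <- simConfig(n_individuals = 2500, n_snps = 30,
                   traits = c("risk_taking", "bmi"), pgs_effects = pe,
                   missing_rate = 0, discretise = FALSE, seed = 201)
  cfg$true_weights <- tsoPGS:::.generate_true_weights(
    30, c("risk_taking", "bmi"), 0.3, 202)
  sim <- simulatePhenotypes(gp, cfg, seed = 203)
  d <- sim$phenotypes
  d$risk_taking <- standardiseScores(sim$truth$pgs_true[, 1])
  d$bmi <- standardiseScores(sim$truth$pgs_true[, 2])
  tab <- runSinglePGS(d, buildTSOSpec(4, 3),
                      pgs = c("risk_taking", "bmi"),
                      covariates = "sex")
  expect_equal(nrow(tab), 10L)
  hit <- tab[tab$pgs == "risk_taking" & tab$factor == "C", ]
  expect_lt(abs(hit$b_std - 0.25), 3 * hit$se_robust)
  expect_lt(hit$p_fdr, 0.05)
  expect_true(all(tab$p_fdr >= tab$p_raw - 1e-12, na.rm = TRUE))
  expect_true(all(tab$ci_low <= tab$b_std & tab$b_std <= tab$ci_high))
  # null PGS stays null on the common factor
  null_c <- tab[tab$pgs == "bmi" & tab$factor == "C", ]
  expect_lt(abs(null_c$b_std), 3 * null_c$se_robust + 0.02)
})

test_that("covariate adjustment removes confounding by sex", {
  # sex affects both the common factor and (artificially) the PGS
  gp <- simulateGenotypes(4000, 20, seed = 211)
  ce <- matrix(0, 5, 11, dimnames = list(c("C", "S_cig", "S_alc",
                                           "S_can", "S_oth"),
                                         c("sex", paste0("pc", 1:10))))
  ce["C", "sex"] <- 0.5
  cfg <- simConfig(n_individuals = 4000, n_snps = 20,
                   traits = "risk_taking",
                   pgs_effects = matrix(0, 5, 1,
                                        dimnames = list(rownames(ce),
                                                        "risk_taking")),
                   covariate_effects = ce, missing_rate = 0,
                   discretise = FALSE, seed = 211)
  cfg$true_weights <- matrix(0.05, 20, 1,
                             dimnames = list(NULL, "risk_taking"))
  spec <- buildTSOSpec(4, 3)
  b_adj <- b_unadj <- numeric(5)
  for (r in 1:5) {
    sim <- simulatePhenotypes(gp, cfg, seed = 2120 + r)
    d <- sim$phenotypes
    # confounded score: half sex, half genetics
    d$pgs_conf <- standardiseScores(
      standardiseScores(sim$truth$pgs_true[, 1]) + 1.0 * d$sex)
    adj <- runSinglePGS(d, spec, "pgs_conf", covariates = "sex")
    unadj <- runSinglePGS(d, spec, "pgs_conf",
                          covariates = character(0))
    b_adj[r] <- adj[adj$factor == "C", "b_std"]
    b_unadj[r] <- unadj[unadj$factor == "C", "b_std"]
  }
  expect_lt(abs(mean(b_adj)), 0.05)  # unbiased once sex is partialled
  # confounded estimate inflated towards cov(pgs, C) = 0.112
  expect_gt(mean(b_unadj), 0.07)
})

test_that("a lone selected PGS gives a multi model agreeing with single", {
  # the multi model omits the other factors' PGS paths, so the two
  # estimators agree statistically (in expectation), not numerically
  gp <- simulateGenotypes(2000, 30, seed = 231)
  pe <- matrix(0, 5, 1, dimnames = list(c("C", "S_cig", "S_alc",
                                          "S_can", "S_oth"),
                                        "risk_taking"))
  pe["C", 1] <- 0.2
  cfg <- simConfig(n_individuals = 2000, n_snps = 30,
                   traits = "risk_taking", pgs_effects = pe,
                   missing_rate = 0, discretise = FALSE, seed = 231)
  cfg$true_weights <- matrix(0.05, 30, 1,
                             dimnames = list(NULL, "risk_taking"))
  spec <- buildTSOSpec(4, 3)
  sel <- list(C = list(substance = character(0), trait = "pgs"))
  diffs <- kinds <- numeric(6)
  b_s <- b_m <- numeric(6)
  for (r in 1:6) {
    sim <- simulatePhenotypes(gp, cfg, seed = 2310 + r)
    d <- sim$phenotypes
    d$pgs <- standardiseScores(sim$truth$pgs_true[, 1])
    single <- runSinglePGS(d, spec, "pgs", covariates = "sex")
    multi <- runMultiPGS(d, spec, sel, covariates = "sex")
    b_s[r] <- single[single$factor == "C", "b_std"]
    b_m[r] <- multi$b_std
  }
  expect_lt(abs(mean(b_m) - mean(b_s)), 0.03)
  expect_lt(abs(mean(b_m) - 0.2), 0.04)
})

test_that("collinear PGS sets are rejected with the offending pair", {
  st <- continuous_study()
  d <- st$pheno
  d$dup1 <- d$pgs_true
  d$dup2 <- d$pgs_true
  sel <- list(C = list(substance = c("dup1", "dup2"),
                       trait = character(0)))
  expect_error(runMultiPGS(d, buildTSOSpec(4, 3), sel),
               "collinear.*dup")
})

test_that("multi-PGS estimates are invariant to predictor order", {
  st <- continuous_study()
  d <- st$pheno
  withr::with_seed(221, {
    d$pgs_b <- 0.5 * d$pgs_true + sqrt(0.75) * rnorm(nrow(d))
  })
  sel1 <- list(C = list(substance = character(0),
                        trait = c("pgs_true", "pgs_b")))
  sel2 <- list(C = list(substance = character(0),
                        trait = c("pgs_b", "pgs_true")))
  m1 <- runMultiPGS(d, buildTSOSpec(4, 3), sel1)
  m2 <- runMultiPGS(d, buildTSOSpec(4, 3), sel2)
  m2 <- m2[match(m1$pgs, m2$pgs), ]
  expect_equal(m1$b_std, m2$b_std, tolerance = 1e-6)
})
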