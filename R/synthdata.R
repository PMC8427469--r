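## Synthetic-data generator: LD-blocked genotypes, noisy discovery-GWAS
## summary statistics, and longitudinal substance-use phenotypes driven
## by a common + substance-specific + occasion latent structure with
## polygenic-score effects and configurable missingness. Every stage is
## seeded and records its ground truth for parameter-recovery tests.

.SUBSTANCES <- c("cig", "alc", "can", "oth")
.OCCASIONS <- c("17", "20", "22")

.default_traits <- function() {
  c("cig_frequency", "cig_onset", "cig_dependence", "alc_frequency",
    "alc_dependence", "can_use", "oth_use",
    "risk_taking", "schizophrenia", "depression", "adhd", "neuroticism",
    "extraversion", "educational_attainment", "bmi", "wellbeing",
    "anxiety", "cognitive_performance")
}

#' Categories of the default simulated polygenic scores
#'
#' Splits the 18 default trait names into substance-use scores (set A of
#' the multivariable stage) and trait/vulnerability scores (set B).
#'
#' @return named character vector mapping trait name to `"substance"` or
#'   `"trait"`.
#' @export
defaultPgsCategories <- function() {
  tr <- .default_traits()
  setNames(c(rep("substance", 7L), rep("trait", 11L)), tr)
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic study. The
#' defaults emulate the target study design: around 4000 individuals
#' measured on 4 substances (FTND-like cigarette, AUDIT-like alcohol,
#' CAST-like cannabis, and an illicit-substance count) at 3 ages, 18
#' discovery GWAS of at least 20000 participants, and a latent structure
#' whose population variance decomposition is approximately 22% common,
#' 34% substance-specific, 14% occasion and 30% residual.
#'
#' @param n_individuals,n_snps sample and panel sizes.
#' @param maf_range range of effect-allele frequencies, within (0, 0.5].
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho within-block first-order haplotype correlation in `[0,1)`
#'   (Gaussian-threshold copula).
#' @param discovery_n GWAS discovery sample size controlling
#'   summary-statistic noise; may be `Inf` for noise-free statistics.
#' @param traits character vector of simulated GWAS trait names.
#' @param true_weights optional n_snps x traits matrix of true per-SNP
#'   effects; generated sparsely when `NULL`.
#' @param causal_fraction fraction of SNPs with nonzero effect per trait
#'   when `true_weights` is generated.
#' @param pgs_effects factors x traits matrix of standardised structural
#'   coefficients from each true polygenic score to each latent factor
#'   (rows `C, S_cig, S_alc, S_can, S_oth`). The default injects a 0.14
#'   effect of the risk-taking score on the common factor and 0.12
#'   effects of the cigarette- and alcohol-frequency scores on their
#'   substance factors.
#' @param lambda_common,lambda_specific length-12 loadings of the common
#'   and substance-specific factors (occasion loadings are fixed at 1).
#' @param residual_sds length-12 residual standard deviations of the
#'   continuous indicators.
#' @param covariate_effects factors x 11 matrix of effects of (sex,
#'   pc1..pc10) on the latent factors; zero by default.
#' @param missing_rate per-indicator missingness probability in `[0, 1)`,
#'   recycled to length 12.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (logistic dependence on
#'   sex).
#' @param count_max score ceilings for the four instruments
#'   (FTND 10, AUDIT 40, CAST 24, illicit count 15).
#' @param discretise map continuous indicators to bounded counts by
#'   rank-preserving quantile discretisation (right-skewed truncated
#'   negative-binomial target marginal)?
#' @param swap_fraction fraction of summary-statistic rows written in
#'   the opposite allele orientation (beta sign flipped accordingly), to
#'   exercise harmonisation.
#' @param seed integer seed; every stage derives its own stream from it.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(n_individuals = 4000, n_snps = 400,
                      maf_range = c(0.05, 0.5), ld_block_size = 10,
                      ld_rho = 0.8, discovery_n = 20000,
                      traits = .default_traits(), true_weights = NULL,
                      causal_fraction = 0.2, pgs_effects = NULL,
                      lambda_common = c(1.084, 1.276, 1.403, 1.021,
                                        1.340, 1.467, 1.148, 1.340,
                                        1.212, 0.957, 1.403, 1.276),
                      lambda_specific = c(1.768, 1.538, 1.384, 1.845,
                                          1.461, 1.307, 1.615, 1.461,
                                          1.691, 1.384, 1.615, 1.538),
                      residual_sds = c(1.357, 1.466, 1.503, 1.302,
                                       1.488, 1.511, 1.489, 1.488,
                                       1.347, 1.820, 1.251, 1.466),
                      covariate_effects = NULL,
                      missing_rate = 0.25,
                      missing_mechanism = c("MCAR", "MAR"),
                      count_max = c(cig = 10, alc = 40, can = 24, oth = 15),
                      discretise = TRUE, swap_fraction = 0.1, seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  factors <- c("C", paste0("S_", .SUBSTANCES))
  if (is.null(pgs_effects)) {
    pgs_effects <- matrix(0, length(factors), length(traits),
                          dimnames = list(factors, traits))
    if ("risk_taking" %in% traits) pgs_effects["C", "risk_taking"] <- 0.14
    if ("cig_frequency" %in% traits)
      pgs_effects["S_cig", "cig_frequency"] <- 0.12
    if ("alc_frequency" %in% traits)
      pgs_effects["S_alc", "alc_frequency"] <- 0.12
  }
  if (is.null(covariate_effects))
    covariate_effects <- matrix(0, length(factors), 11,
                                dimnames = list(factors,
                                                c("sex", paste0("pc", 1:10))))
  missing_rate <- rep_len(missing_rate, 12L)
  cfg <- list(n_individuals = n_individuals, n_snps = n_snps,
              maf_range = maf_range, ld_block_size = ld_block_size,
              ld_rho = ld_rho, discovery_n = discovery_n, traits = traits,
              true_weights = true_weights,
              causal_fraction = causal_fraction, pgs_effects = pgs_effects,
              lambda_common = lambda_common,
              lambda_specific = lambda_specific,
              residual_sds = residual_sds,
              covariate_effects = covariate_effects,
              missing_rate = missing_rate,
              missing_mechanism = missing_mechanism,
              count_max = count_max, discretise = discretise,
              swap_fraction = swap_fraction, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `"SimConfig"` list.
#' @return `cfg`, invisibly; errors on invalid configuration.
#' @export
validateSimConfig <- function(cfg) {
  fail <- function(...) stop("invalid SimConfig: ", ..., call. = FALSE)
  if (!is_count(cfg$n_individuals) || !is_count(cfg$n_snps))
    fail("n_individuals and n_snps must be positive integers")
  mr <- cfg$maf_range
  if (length(mr) != 2L || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    fail("maf_range must lie within (0, 0.5]")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) fail("ld_rho must be in [0, 1)")
  if (!is_count(cfg$ld_block_size)) fail("ld_block_size must be positive")
  if (!is.infinite(cfg$discovery_n) && cfg$discovery_n < 2)
    fail("discovery_n must be at least 2")
  if (length(cfg$lambda_common) != 12L || length(cfg$lambda_specific) != 12L)
    fail("loadings must have length 12 (4 substances x 3 occasions)")
  if (length(cfg$residual_sds) != 12L || any(cfg$residual_sds <= 0))
    fail("residual_sds must be 12 positive values")
  if (any(cfg$missing_rate < 0 | cfg$missing_rate >= 1))
    fail("missing_rate must be in [0, 1)")
  if (length(cfg$count_max) != 4L || any(cfg$count_max < 1))
    fail("count_max must give 4 positive ceilings")
  if (!is.null(cfg$true_weights) &&
      nrow(cfg$true_weights) != cfg$n_snps)
    fail("true_weights must have n_snps rows")
  if (!identical(rownames(cfg$pgs_effects), c("C", paste0("S_", .SUBSTANCES))))
    fail("pgs_effects rows must be C, S_cig, S_alc, S_can, S_oth")
  if (cfg$swap_fraction < 0 || cfg$swap_fraction > 1)
    fail("swap_fraction must be in [0, 1]")
  invisible(cfg)
}

#' Indicator names of the 4 x 3 substance-use design
#'
#' Substance-major order: `cig_17, cig_20, cig_22, alc_17, ..., oth_22`.
#'
#' @return character vector of length 12.
#' @export
indicatorNames <- function()
  as.vector(t(outer(.SUBSTANCES, .OCCASIONS, paste, sep = "_")))

#' Simulate LD-blocked biallelic genotypes
#'
#' Draws two haplotypes per individual. Within an LD block, haplotype
#' alleles follow a first-order autoregressive Gaussian copula with
#' correlation `ld_rho`, thresholded at each SNP's allele frequency;
#' blocks are mutually independent. Dosages are the per-individual
#' haplotype sums, so each SNP is in Hardy-Weinberg proportions at its
#' drawn frequency. Physical positions place a whole block well inside a
#' 250 kb clumping window while consecutive blocks are 1 Mb apart, and
#' blocks are split over two chromosomes.
#'
#' @param n_individuals,n_snps dimensions.
#' @param maf_range effect-allele frequency range in (0, 0.5].
#' @param ld_block_size SNPs per block (the last block may be short).
#' @param ld_rho copula autocorrelation in `[0, 1)`.
#' @param ambiguous_fraction fraction of SNPs assigned a
#'   strand-ambiguous allele pair (A/T or C/G). The default is 0,
#'   mirroring a quality-controlled panel from which ambiguous SNPs
#'   have been excluded; set it above 0 to exercise the harmonisation
#'   drop rule.
#' @param seed integer seed.
#' @return a [GenotypePanel-class].
#' @export
simulateGenotypes <- function(n_individuals, n_snps,
                              maf_range = c(0.05, 0.5),
                              ld_block_size = 10, ld_rho = 0.8,
                              ambiguous_fraction = 0, seed = 1L) {
  if (!is_count(n_individuals) || !is_count(n_snps))
    stop("invalid SimConfig: n_individuals and n_snps must be positive",
         call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1)
    stop("invalid SimConfig: ld_rho must be in [0, 1)", call. = FALSE)
  with_seed(seed, {
    f <- runif(n_snps, maf_range[1], maf_range[2])
    blocks <- split(seq_len(n_snps),
                    (seq_len(n_snps) - 1L) %/% ld_block_size)
    nh <- 2L * n_individuals
    dos <- matrix(0L, n_individuals, n_snps)
    for (idx in blocks) {
      s <- length(idx)
      Z <- matrix(0, nh, s)
      Z[, 1L] <- rnorm(nh)
      if (s > 1L) {
        innov_sd <- sqrt(1 - ld_rho^2)
        for (j in 2:s)
          Z[, j] <- ld_rho * Z[, j - 1L] + innov_sd * rnorm(nh)
      }
      al <- sweep(Z, 2L, qnorm(f[idx]), "<")
      dos[, idx] <- al[seq_len(n_individuals), , drop = FALSE] +
        al[n_individuals + seq_len(n_individuals), , drop = FALSE]
    }
    ## positions: 1 kb spacing inside a block (span << 250 kb), 1 Mb
    ## between block starts (> 250 kb window), blocks split over 2 chrs
    nb <- length(blocks)
    chr_of_block <- rep(c("1", "2"), length.out = nb)
    bp <- integer(n_snps)
    counter <- c("1" = 0L, "2" = 0L)
    for (b in seq_len(nb)) {
      idx <- blocks[[b]]
      chr <- chr_of_block[b]
      start <- 1e6L * counter[chr] + 10000L
      bp[idx] <- start + 1000L * (seq_along(idx) - 1L)
      counter[chr] <- counter[chr] + 1L
    }
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    pairs <- cbind(sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
                   NA_character_)
    ambig <- runif(n_snps) < ambiguous_fraction
    pairs[, 2] <- vapply(seq_len(n_snps), function(i) {
      a <- pairs[i, 1]
      if (ambig[i]) comp[[a]]
      else sample(setdiff(c("A", "C", "G", "T"), c(a, comp[[a]])), 1L)
    }, character(1))
    info <- data.frame(snp = sprintf("rs%05d", seq_len(n_snps)),
                       chr = rep(chr_of_block, lengths(blocks)),
                       bp = bp, A1 = pairs[, 1], A2 = pairs[, 2], MAF = f)
    GenotypePanel(dos, info)
  })
}

#' Simulate discovery-GWAS summary statistics
#'
#' Reported effects are the true per-SNP effects plus Gaussian
#' estimation noise with standard error `1 / sqrt(discovery_n * 2 f (1 - f))`
#' (the single-SNP regression standard error under unit residual
#' variance and Hardy-Weinberg dosage variance); the p-value is the
#' two-sided Wald p of the reported effect. A `swap_fraction` of rows is
#' written in the opposite allele orientation with the beta sign flipped,
#' to exercise downstream harmonisation.
#'
#' @param genotypes a [GenotypePanel-class] supplying SNP metadata.
#' @param true_weights numeric vector of true effects, one per SNP.
#' @param discovery_n discovery sample size (`Inf` for noise-free).
#' @param seed integer seed.
#' @param swap_fraction fraction of rows with swapped alleles.
#' @param trait trait label for the result.
#' @return a [GwasSumstats-class].
#' @export
simulateSumstats <- function(genotypes, true_weights, discovery_n,
                             seed = 1L, swap_fraction = 0, trait = "trait") {
  info <- snpInfo(genotypes)
  if (length(true_weights) != nrow(info))
    stop("true_weights length must equal the number of panel SNPs",
         call. = FALSE)
  if (!is.infinite(discovery_n) && discovery_n < 2)
    stop("invalid SimConfig: discovery_n must be at least 2", call. = FALSE)
  with_seed(seed, {
    f <- info$MAF
    se <- if (is.infinite(discovery_n)) rep(0, nrow(info)) else
      1 / sqrt(discovery_n * 2 * f * (1 - f))
    beta <- true_weights + rnorm(nrow(info)) * se
    p <- ifelse(se > 0, 2 * pnorm(-abs(beta) / se),
                ifelse(beta == 0, 1, 1e-300))
    p <- pmin(pmax(p, 1e-300), 1)
    out <- data.frame(snp = info$snp, chr = info$chr, bp = info$bp,
                      A1 = info$A1, A2 = info$A2, beta = beta, se = se,
                      p = p)
    if (swap_fraction > 0) {
      k <- which(runif(nrow(out)) < swap_fraction)
      tmp <- out$A1[k]
      out$A1[k] <- out$A2[k]
      out$A2[k] <- tmp
      out$beta[k] <- -out$beta[k]
    }
    GwasSumstats(out, trait = trait)
  })
}

## Right-skewed bounded-count marginal: rank-preserving map of a
## continuous vector onto a truncated negative-binomial quantile scale.
.discretise_counts <- function(y, count_max, size = 0.6, mu_frac = 0.15) {
  mu <- mu_frac * count_max
  u <- (rank(y, ties.method = "average") - 0.5) / length(y)
  fmax <- pnbinom(count_max, size = size, mu = mu)
  pmin(qnbinom(u * fmax, size = size, mu = mu), count_max)
}

#' Simulate longitudinal substance-use phenotypes
#'
#' Builds standardised true polygenic scores from the panel and the true
#' weights, then generates unit-variance latent factors: a common
#' liability `C`, four substance-specific factors `S_k` and three
#' occasion factors `O_t`. `C` and the `S_k` are linear in the true
#' scores and covariates with coefficients `pgs_effects` /
#' `covariate_effects`, plus an independent residual scaled so each
#' factor's variance is 1 (an error is raised if the systematic part
#' already exceeds unit variance). Indicators are
#' `y = lambda_common * C + lambda_specific * S_k + O_t + eps` and are
#' optionally discretised onto bounded right-skewed count scales by
#' rank-preserving quantile mapping. Sex and 10 standard-normal
#' principal-component covariates are generated and recorded.
#'
#' @param genotypes a [GenotypePanel-class].
#' @param config a [simConfig()] list.
#' @param seed integer seed (defaults to the config seed).
#' @return list with `phenotypes` (data.frame: id, sex, pc1..pc10 and
#'   the 12 indicators) and `truth` (latent scores, true polygenic
#'   scores, generating parameters, continuous indicators).
#' @export
simulatePhenotypes <- function(genotypes, config, seed = config$seed) {
  validateSimConfig(config)
  G <- dosages(genotypes)
  n <- nrow(G)
  traits <- config$traits
  W <- config$true_weights
  stopifnot(!is.null(W), ncol(W) == length(traits))
  with_seed(seed, {
    pgs_true <- matrix(0, n, length(traits),
                       dimnames = list(NULL, traits))
    for (j in seq_along(traits)) {
      raw <- drop(G %*% W[, j])
      if (stats::sd(raw) > 0) pgs_true[, j] <- standardise_vector(raw)
    }
    sex <- rbinom(n, 1L, 0.5)
    pcs <- matrix(rnorm(n * 10L), n, 10L,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    covars <- cbind(sex = sex, pcs)
    factors <- rownames(config$pgs_effects)
    eta <- matrix(0, n, length(factors) + 3L,
                  dimnames = list(NULL, c(factors,
                                          paste0("O_", .OCCASIONS))))
    for (f in factors) {
      sys <- drop(pgs_true %*% config$pgs_effects[f, ]) +
        drop(covars %*% config$covariate_effects[f, ])
      v <- if (all(sys == 0)) 0 else stats::var(sys)
      if (v > 1)
        stop("invalid SimConfig: effects on factor ", f,
             " imply variance > 1 (negative residual variance)",
             call. = FALSE)
      eta[, f] <- sys + rnorm(n) * sqrt(1 - v)
    }
    for (t in paste0("O_", .OCCASIONS)) eta[, t] <- rnorm(n)
    ind <- indicatorNames()
    ycont <- matrix(0, n, 12L, dimnames = list(NULL, ind))
    for (i in seq_len(12L)) {
      k <- .SUBSTANCES[(i - 1L) %/% 3L + 1L]
      t <- .OCCASIONS[(i - 1L) %% 3L + 1L]
      ycont[, i] <- config$lambda_common[i] * eta[, "C"] +
        config$lambda_specific[i] * eta[, paste0("S_", k)] +
        eta[, paste0("O_", t)] + rnorm(n) * config$residual_sds[i]
    }
    yobs <- ycont
    if (config$discretise) {
      cm <- rep(config$count_max, each = 3L)
      for (i in seq_len(12L))
        yobs[, i] <- .discretise_counts(ycont[, i], cm[i])
    }
    phenotypes <- data.frame(id = paste0("ind", seq_len(n)), sex = sex,
                             pcs, yobs, check.names = FALSE)
    truth <- list(pgs_true = pgs_true, factors = eta,
                  lambda_common = config$lambda_common,
                  lambda_specific = config$lambda_specific,
                  residual_sds = config$residual_sds,
                  pgs_effects = config$pgs_effects,
                  covariate_effects = config$covariate_effects,
                  continuous = ycont, seed = seed)
    list(phenotypes = phenotypes, truth = truth)
  })
}

#' Inject missingness into phenotype indicators
#'
#' Sets indicator cells missing completely at random (`"MCAR"`) or with
#' logistic dependence on a covariate (`"MAR"`, default dependence on
#' sex: `logit P(missing) = logit(rate) + slope * (z - mean(z))`). Rows
#' with all 12 indicators missing are dropped (count attached as
#' attribute `"n_dropped"`); covariates are never set missing.
#'
#' @param phenotypes phenotype data.frame as from [simulatePhenotypes()].
#' @param missing_rate per-indicator probabilities in `[0, 1)`, recycled
#'   to 12.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param seed integer seed.
#' @param mar_covariate covariate column driving MAR missingness.
#' @param mar_slope logistic slope of the MAR mechanism.
#' @return the phenotype data.frame with `NA` cells.
#' @export
injectMissingness <- function(phenotypes, missing_rate,
                              mechanism = c("MCAR", "MAR"), seed = 1L,
                              mar_covariate = "sex", mar_slope = 1) {
  mechanism <- match.arg(mechanism)
  missing_rate <- rep_len(missing_rate, 12L)
  if (any(missing_rate < 0 | missing_rate >= 1))
    stop("invalid SimConfig: missing_rate must be in [0, 1)", call. = FALSE)
  ind <- indicatorNames()
  stopifnot(all(ind %in% colnames(phenotypes)))
  n <- nrow(phenotypes)
  with_seed(seed, {
    for (i in seq_along(ind)) {
      r <- missing_rate[i]
      if (r == 0) next
      pr <- if (mechanism == "MCAR") rep(r, n) else {
        z <- phenotypes[[mar_covariate]]
        plogis(qlogis(r) + mar_slope * (z - mean(z)))
      }
      miss <- runif(n) < pr
      phenotypes[[ind[i]]][miss] <- NA
    }
    all_missing <- rowSums(!is.na(phenotypes[, ind, drop = FALSE])) == 0L
    out <- phenotypes[!all_missing, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_dropped") <- sum(all_missing)
    out
  })
}

## Sparse true per-SNP effects for each simulated trait.
.generate_true_weights <- function(n_snps, traits, causal_fraction, seed) {
  with_seed(seed, {
    W <- matrix(0, n_snps, length(traits),
                dimnames = list(NULL, traits))
    n_causal <- max(2L, round(causal_fraction * n_snps))
    for (j in seq_along(traits)) {
      idx <- sample.int(n_snps, n_causal)
      W[idx, j] <- rnorm(n_causal, 0, 0.05)
    }
    W
  })
}

#' Simulate a complete study with ground truth
#'
#' Runs the full generator: genotypes, one set of discovery summary
#' statistics per trait, phenotypes with latent structure, and
#' missingness. Each stage uses a seed derived deterministically from
#' `config$seed`, so a config fully determines the study.
#'
#' @param config a [simConfig()] list.
#' @return a [SimulatedStudy-class].
#' @examples
#' cfg <- simConfig(n_individuals = 200, n_snps = 50,
#'                  traits = c("risk_taking", "cig_frequency"),
#'                  pgs_effects = NULL, seed = 7)
#' study <- simulateStudy(cfg)
#' study
#' @export
simulateStudy <- function(config) {
  validateSimConfig(config)
  gp <- simulateGenotypes(config$n_individuals, config$n_snps,
                          config$maf_range, config$ld_block_size,
                          config$ld_rho,
                          seed = derive_seed(config$seed, "genotypes"))
  if (is.null(config$true_weights))
    config$true_weights <- .generate_true_weights(
      config$n_snps, config$traits, config$causal_fraction,
      derive_seed(config$seed, "weights"))
  ss <- lapply(seq_along(config$traits), function(j)
    simulateSumstats(gp, config$true_weights[, j], config$discovery_n,
                     seed = derive_seed(config$seed,
                                        paste0("sumstats_", config$traits[j])),
                     swap_fraction = config$swap_fraction,
                     trait = config$traits[j]))
  names(ss) <- config$traits
  ph <- simulatePhenotypes(gp, config,
                           seed = derive_seed(config$seed, "phenotypes"))
  pheno <- ph$phenotypes
  if (any(config$missing_rate > 0))
    pheno <- injectMissingness(pheno, config$missing_rate,
                               config$missing_mechanism,
                               seed = derive_seed(config$seed, "missing"))
  truth <- ph$truth
  truth$true_weights <- config$true_weights
  truth$config_seed <- config$seed
  new("SimulatedStudy", genotypes = gp, sumstats = ss,
      phenotypes = pheno, truth = truth)
}
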