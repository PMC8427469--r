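# Shared fixtures and independent oracles, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- fn()
  .fixture_env[[name]]
}

# tiny hand-written genotype panel
tiny_panel <- function() {
  snp <- data.frame(snp = c("rs1", "rs2"), chr = c("1", "1"),
                    bp = c(1000L, 2000L), A1 = c("A", "C"),
                    A2 = c("G", "T"), MAF = c(0.3, 0.4))
  GenotypePanel(matrix(c(0, 1, 2, 1, 1, 0, 2, 1), 4, 2), snp)
}

# small full study reused by several tests (default discretised scores,
# MCAR missingness)
small_study <- function() cached_fixture("small_study", function()
  simulateStudy(simConfig(n_individuals = 600, n_snps = 60,
                          traits = c("risk_taking", "cig_frequency"),
                          missing_rate = 0.15, seed = 421)))

# continuous complete phenotypes at moderate n, with the true risk-taking
# polygenic score attached as a standardised predictor column
continuous_study <- function() cached_fixture("continuous_study", function() {
  st <- simulateStudy(simConfig(n_individuals = 1500, n_snps = 60,
                                traits = "risk_taking", missing_rate = 0,
                                discretise = FALSE, seed = 99))
  ph <- studyPhenotypes(st)
  ph$pgs_true <- standardiseScores(studyTruth(st)$pgs_true[, 1])
  list(study = st, pheno = ph)
})

# data matrix whose sample moments (n-denominator) equal mu0/sigma0 exactly
exact_moment_data <- function(n, mu0, sigma0, seed = 1) {
  p <- length(mu0)
  withr::with_seed(seed, Z <- matrix(rnorm(n * p), n, p))
  Z <- sweep(Z, 2, colMeans(Z))
  S <- crossprod(Z) / n
  Zw <- Z %*% solve(chol(S))
  Y <- Zw %*% chol(sigma0) + matrix(mu0, n, p, byrow = TRUE)
  colnames(Y) <- names(mu0)
  Y
}

# independent greedy-clumping oracle: literal restatement of the rule
# with pairwise r2 computed from the definition
brute_clump <- function(stats, G_named) {
  stats <- stats[order(stats$p, stats$bp, stats$snp), ]
  retained <- character(0)
  remaining <- stats
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    retained <- c(retained, idx$snp)
    remaining <- remaining[-1, , drop = FALSE]
    if (!nrow(remaining)) break
    drop <- logical(nrow(remaining))
    for (r in seq_len(nrow(remaining))) {
      cand <- remaining[r, ]
      if (cand$chr != idx$chr) next
      if (abs(cand$bp - idx$bp) > 250 * 1000) next
      r2 <- cor(G_named[, idx$snp], G_named[, cand$snp])^2
      if (is.finite(r2) && r2 > 0.10) drop[r] <- TRUE
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  retained
}

# definitional Benjamini-Hochberg step-up oracle:
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- sapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))))
  q <- numeric(m)
  q[ord] <- qs
  q
}

# multivariate-normal log-density computed from first principles
mvn_logdens <- function(y, mu, sigma) {
  d <- y - mu
  -0.5 * (length(y) * log(2 * pi) +
            as.numeric(determinant(sigma)$modulus) +
            drop(t(d) %*% solve(sigma) %*% d))
}
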