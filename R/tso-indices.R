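## Fit assessment: likelihood-ratio chi-square against the saturated
## model, CFI against the independence baseline, RMSEA, SRMR on the
## saturated moments; fully standardised solution with delta-method
## SEs; variance decomposition of the indicators.

## Saturated and independence-baseline log-likelihoods. Without
## predictors the saturated model comes from fitSaturated() (EM under
## missingness, closed form when complete) and the baseline factorises
## into per-variable ML over observed values. With predictors (complete
## indicators required) both are conditional: multivariate OLS for the
## saturated model, per-variable OLS for the baseline.
.reference_fits <- function(layout, pat) {
  p <- layout$p; n <- pat$n
  if (layout$q == 0) {
    sat <- fitSaturated(pat$Y)
    l_base <- 0
    for (j in seq_len(p)) {
      yj <- pat$Y[, j]; yj <- yj[!is.na(yj)]
      vj <- mean((yj - mean(yj))^2)
      l_base <- l_base - 0.5 * length(yj) * (log(2 * pi) + log(vj) + 1)
    }
    return(list(loglik_sat = sat$loglik, loglik_base = l_base,
                S = sat$sigma, mu_sat = sat$mu))
  }
  if (anyNA(pat$Y))
    stop("fit indices with predictors require complete indicators",
         call. = FALSE)
  Z <- cbind(1, pat$X)
  coefs <- solve(crossprod(Z), crossprod(Z, pat$Y))
  Res <- pat$Y - Z %*% coefs
  Sres <- crossprod(Res) / n
  l_sat <- -0.5 * n * (p * log(2 * pi) +
                         determinant(Sres)$modulus[1] + p)
  l_base <- -0.5 * n * sum(log(2 * pi) + log(diag(Sres)) + 1)
  list(loglik_sat = l_sat, loglik_base = l_base, S = Sres,
       mu_sat = colMeans(pat$Y))
}

#' @describeIn fitIndices Likelihood-ratio test statistic
#'   `T = 2 (loglik_sat - loglik_model)` against the saturated model
#'   (EM-fitted under missingness), baseline chi-square against the
#'   independence model,
#'   `CFI = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)`,
#'   `RMSEA = sqrt(max(T - df, 0) / (df * n))` and SRMR as the root mean
#'   squared correlation-metric residual between the saturated and
#'   implied covariances. With `rmsea_n = "n-1"` the RMSEA denominator
#'   uses `n - 1`.
#' @param rmsea_n `"n"` (default) or `"n-1"`.
#' @export
setMethod("fitIndices", "TSOFit", function(fit, data,
                                           rmsea_n = c("n", "n-1"), ...) {
  rmsea_n <- match.arg(rmsea_n)
  spec <- fit@spec
  layout <- spec_layout(spec)
  Y <- as.matrix(data[, spec@indicators, drop = FALSE])
  X <- if (layout$q > 0)
    as.matrix(data[, spec@predictors, drop = FALSE]) else NULL
  pat <- make_pattern_data(Y, X)
  stopifnot(pat$n == fit@nUsed)
  ref <- .reference_fits(layout, pat)
  p <- layout$p
  df <- spec@df
  df_b <- as.integer(p * (p + 1) / 2 - p)
  T_mod <- max(0, 2 * (ref$loglik_sat - fit@loglik))
  T_base <- max(0, 2 * (ref$loglik_sat - ref$loglik_base))
  num <- max(T_mod - df, 0)
  den <- max(T_base - df_b, T_mod - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  n_rmsea <- if (rmsea_n == "n") pat$n else pat$n - 1L
  rmsea <- if (df == 0) NA_real_ else sqrt(num / (df * n_rmsea))
  sigma_hat <- if (layout$q == 0) fit@impliedSigma else {
    un <- unpack_theta(layout, fit@theta)
    tcrossprod(un$Lambda) + diag(un$theta, nrow = p)
  }
  S <- ref$S
  d <- sqrt(diag(S))
  E <- (S - sigma_hat) / tcrossprod(d)
  srmr <- sqrt(mean(E[upper.tri(E, diag = TRUE)]^2))
  pvalue <- if (df > 0) pchisq(T_mod, df, lower.tail = FALSE)
            else NA_real_
  out <- list(chisq = T_mod, df = df, pvalue = pvalue, cfi = cfi,
              rmsea = rmsea, srmr = srmr, baseline_chisq = T_base,
              baseline_df = df_b, loglik_model = fit@loglik,
              loglik_sat = ref$loglik_sat,
              loglik_baseline = ref$loglik_base, n = pat$n)
  if (df == 0)
    out$note <- "df = 0: RMSEA undefined (saturated covariance structure)"
  out
})

## Standardisation map: theta (natural) -> standardised parameter vector
## of the same length, with the predictor sample moments held fixed.
.std_map <- function(layout, pred_sd) {
  function(theta) {
    un <- unpack_theta(layout, theta)
    Phi <- diag(layout$mF)
    if (layout$q > 0 && !is.null(pred_sd$cov))
      Phi <- Phi + un$Gamma %*% pred_sd$cov %*% t(un$Gamma)
    sdF <- sqrt(diag(Phi))
    Sigma <- un$Lambda %*% Phi %*% t(un$Lambda) +
      diag(un$theta, nrow = layout$p)
    sdY <- sqrt(diag(Sigma))
    out <- numeric(layout$npar)
    if (layout$n_lam) {
      j <- layout$lam_idx[, 1L]; f <- layout$lam_idx[, 2L]
      out[seq_len(layout$n_lam)] <-
        un$Lambda[layout$lam_idx] * sdF[f] / sdY[j]
    }
    out[layout$off_theta + seq_len(layout$p)] <- un$theta / sdY^2
    out[layout$off_nu + seq_len(layout$p)] <- un$nu / sdY
    if (layout$n_gam) {
      f <- layout$gam_idx[, 1L]; k <- layout$gam_idx[, 2L]
      sx <- sqrt(diag(pred_sd$cov))
      out[layout$off_gam + seq_len(layout$n_gam)] <-
        un$Gamma[layout$gam_idx] * sx[k] / sdF[f]
    }
    out
  }
}

#' @describeIn standardisedSolution Rescales every estimate by the
#'   model-implied standard deviations of its source and target
#'   variables (fully standardised solution): loadings by
#'   `sd(factor)/sd(indicator)`, residual variances to variance
#'   proportions, structural coefficients by
#'   `sd(predictor)/sd_implied(factor)`. Standard errors are propagated
#'   through the standardisation map by the delta method with a
#'   numerical Jacobian, using the robust covariance when available.
#' @param type `"robust"` or `"naive"` covariance for the delta method.
#' @export
setMethod("standardisedSolution", "TSOFit",
          function(fit, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  layout <- spec_layout(fit@spec)
  un <- unpack_theta(layout, fit@theta)
  Phi <- diag(layout$mF)
  if (layout$q > 0)
    Phi <- Phi + un$Gamma %*% fit@predictorStats$cov %*% t(un$Gamma)
  if (any(diag(Phi) <= 0) || any(diag(fit@impliedSigma) <= 0))
    stop("degenerate standardisation: zero implied variance",
         call. = FALSE)
  map <- .std_map(layout, fit@predictorStats)
  est_std <- map(fit@theta)
  V <- tryCatch(vcov(fit, type = type), error = function(e) NULL)
  se <- se_std <- rep(NA_real_, layout$npar)
  if (!is.null(V)) {
    se <- sqrt(pmax(diag(V), 0))
    J <- num_jacobian(map, fit@theta)
    se_std <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
  }
  pt <- fit@spec@paramTable
  data.frame(name = pt$name, type = pt$type, lhs = pt$lhs, rhs = pt$rhs,
             est = unname(fit@theta), se = se, est_std = est_std,
             se_std = se_std)
})

#' @describeIn varianceDecomposition Per indicator, the shares of
#'   model-implied variance attributable to the common factor
#'   (`lambda_C^2`), the substance-specific factor (`lambda_S^2`), the
#'   occasion factor (fixed unit loading and variance) and the residual,
#'   each divided by the implied total; shares sum to one. Requires a
#'   model without exogenous predictors.
#' @export
setMethod("varianceDecomposition", "TSOFit", function(fit, ...) {
  spec <- fit@spec
  if (length(spec@predictors) > 0)
    stop("variance decomposition is defined for the baseline model ",
         "(no predictors)", call. = FALSE)
  layout <- spec_layout(spec)
  un <- unpack_theta(layout, fit@theta)
  fac <- spec@factorNames
  common_col <- which(fac == "C")
  spec_cols <- grep("^S_", fac)
  occ_cols <- grep("^O_", fac)
  L2 <- un$Lambda^2
  common <- if (length(common_col)) L2[, common_col] else numeric(layout$p)
  specific <- rowSums(L2[, spec_cols, drop = FALSE])
  occasion <- if (length(occ_cols))
    rowSums(L2[, occ_cols, drop = FALSE]) else numeric(layout$p)
  total <- common + specific + occasion + un$theta
  tab <- data.frame(indicator = spec@indicators,
                    common = common / total, specific = specific / total,
                    occasion = occasion / total,
                    residual = un$theta / total)
  rownames(tab) <- NULL
  list(table = tab,
       average = c(common = mean(tab$common),
                   specific = mean(tab$specific),
                   occasion = mean(tab$occasion),
                   residual = mean(tab$residual)))
})
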