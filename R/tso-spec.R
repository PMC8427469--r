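## TSO model specification: a common liability factor across all
## indicators, one specific factor per substance, one occasion factor
## per wave (loadings fixed to 1), all factor variances fixed to 1 and
## factors mutually orthogonal; free residual variances and intercepts.
## Latent factors may be regressed on observed exogenous predictors.

#' Build a trait-state-occasion model specification
#'
#' Constructs the constraint pattern described in [TSOSpec-class]. With
#' a single substance the common and occasion factors are dropped (they
#' are not identified without cross-substance covariance) and only the
#' substance-specific factor remains. Model degrees of freedom are
#' `p(p+1)/2` unique covariance elements minus the free
#' covariance-structure parameters (free loadings plus residual
#' variances); the saturated mean structure contributes none.
#'
#' @param n_substances number of substances (>= 1).
#' @param n_occasions number of measurement occasions (>= 2).
#' @param structural named list mapping factor names to character
#'   vectors of predictor column names the factor is regressed on
#'   (e.g. `list(C = c("pgs", "sex"))`). Regressed factors keep their
#'   residual variance fixed at 1.
#' @param substances,occasions optional labels; defaults are
#'   `cig, alc, can, oth` and `17, 20, 22` (extended generically beyond
#'   4 x 3).
#' @return a [TSOSpec-class].
#' @examples
#' spec <- buildTSOSpec(4, 3)
#' modelDf(spec)   # 42
#' @export
buildTSOSpec <- function(n_substances = 4, n_occasions = 3,
                         structural = list(), substances = NULL,
                         occasions = NULL) {
  if (n_substances < 1) stop("need at least 1 substance", call. = FALSE)
  if (n_occasions < 2) stop("need at least 2 occasions", call. = FALSE)
  if (is.null(substances))
    substances <- if (n_substances <= 4) .SUBSTANCES[seq_len(n_substances)]
                  else paste0("sub", seq_len(n_substances))
  if (is.null(occasions))
    occasions <- if (n_occasions <= 3) .OCCASIONS[seq_len(n_occasions)]
                 else paste0("t", seq_len(n_occasions))
  indicators <- as.vector(t(outer(substances, occasions, paste, sep = "_")))
  p <- length(indicators)
  has_common <- n_substances >= 2
  factors <- c(if (has_common) "C", paste0("S_", substances),
               if (has_common) paste0("O_", occasions))
  L <- matrix(0, p, length(factors),
              dimnames = list(indicators, factors))
  for (i in seq_len(p)) {
    k <- substances[(i - 1L) %/% n_occasions + 1L]
    t <- occasions[(i - 1L) %% n_occasions + 1L]
    if (has_common) {
      L[i, "C"] <- NA
      L[i, paste0("O_", t)] <- 1
    }
    L[i, paste0("S_", k)] <- NA
  }
  if (length(structural)) {
    if (!all(names(structural) %in% factors))
      stop("structural map references unknown factor: ",
           paste(setdiff(names(structural), factors), collapse = ", "),
           call. = FALSE)
  }
  predictors <- unique(unlist(structural, use.names = FALSE))
  if (is.null(predictors)) predictors <- character(0)
  n_free_lambda <- sum(is.na(L))
  df <- as.integer(p * (p + 1) / 2 - n_free_lambda - p)
  pt <- .param_table(indicators, factors, L, structural, predictors)
  new("TSOSpec", nSubstances = as.integer(n_substances),
      nOccasions = as.integer(n_occasions), substances = substances,
      occasions = occasions, indicators = indicators,
      factorNames = factors, lambdaTemplate = L,
      predictors = predictors, structural = structural,
      paramTable = pt, df = df)
}

.param_table <- function(indicators, factors, L, structural, predictors) {
  free <- which(is.na(L), arr.ind = TRUE)
  free <- free[order(free[, 2], free[, 1]), , drop = FALSE]
  lam <- data.frame(type = "lambda",
                    lhs = factors[free[, 2]], rhs = indicators[free[, 1]],
                    row = free[, 1], col = free[, 2])
  th <- data.frame(type = "theta", lhs = indicators, rhs = indicators,
                   row = seq_along(indicators), col = NA_integer_)
  nu <- data.frame(type = "nu", lhs = indicators, rhs = "1",
                   row = seq_along(indicators), col = NA_integer_)
  gam <- NULL
  if (length(structural)) {
    gam <- do.call(rbind, lapply(names(structural), function(f)
      data.frame(type = "gamma", lhs = f, rhs = structural[[f]],
                 row = match(f, factors),
                 col = match(structural[[f]], predictors))))
  }
  pt <- rbind(lam, th, nu, gam)
  pt$name <- ifelse(pt$type == "lambda", paste0(pt$lhs, "=~", pt$rhs),
             ifelse(pt$type == "theta", paste0("theta[", pt$lhs, "]"),
             ifelse(pt$type == "nu", paste0("nu[", pt$lhs, "]"),
                    paste0(pt$lhs, "~", pt$rhs))))
  rownames(pt) <- NULL
  pt
}

#' Model degrees of freedom
#'
#' @param spec a [TSOSpec-class].
#' @return degrees of freedom of the covariance structure.
#' @export
modelDf <- function(spec) spec@df

#' Number of free parameters
#'
#' @param spec a [TSOSpec-class].
#' @param mean_structure include intercepts and structural coefficients?
#' @return free-parameter count (covariance structure only by default).
#' @export
nFreeParams <- function(spec, mean_structure = FALSE) {
  pt <- spec@paramTable
  if (mean_structure) nrow(pt)
  else sum(pt$type %in% c("lambda", "theta"))
}

setMethod("show", "TSOSpec", function(object) {
  cat("TSOSpec:", object@nSubstances, "substances x", object@nOccasions,
      "occasions (", length(object@indicators), "indicators )\n")
  cat("  factors:", paste(object@factorNames, collapse = ", "), "\n")
  cat("  free parameters:", nrow(object@paramTable),
      "( covariance structure:", nFreeParams(object), ")\n")
  cat("  df:", object@df, "\n")
  if (length(object@structural)) {
    cat("  structural:\n")
    for (f in names(object@structural))
      cat("    ", f, "~", paste(object@structural[[f]], collapse = " + "),
          "\n")
  }
})

## Index layout of the free-parameter vector:
## [lambda free | residual variances | intercepts | gamma free]
spec_layout <- function(spec) {
  pt <- spec@paramTable
  p <- length(spec@indicators)
  mF <- length(spec@factorNames)
  q <- length(spec@predictors)
  lam <- pt[pt$type == "lambda", ]
  gam <- pt[pt$type == "gamma", ]
  n_lam <- nrow(lam)
  list(p = p, mF = mF, q = q, n_lam = n_lam, n_gam = nrow(gam),
       lam_idx = cbind(lam$row, lam$col),
       gam_idx = if (nrow(gam)) cbind(gam$row, gam$col) else
         matrix(0L, 0, 2),
       off_lam = 0L, off_theta = n_lam, off_nu = n_lam + p,
       off_gam = n_lam + 2L * p,
       npar = n_lam + 2L * p + nrow(gam),
       names = pt$name, template = spec@lambdaTemplate)
}

## theta vector (natural scale) -> matrices
unpack_theta <- function(layout, theta) {
  L <- layout$template
  L[is.na(L)] <- 0
  if (layout$n_lam) L[layout$lam_idx] <- theta[seq_len(layout$n_lam)]
  th <- theta[layout$off_theta + seq_len(layout$p)]
  nu <- theta[layout$off_nu + seq_len(layout$p)]
  Gamma <- matrix(0, layout$mF, layout$q)
  if (layout$n_gam)
    Gamma[layout$gam_idx] <- theta[layout$off_gam + seq_len(layout$n_gam)]
  list(Lambda = L, theta = th, nu = nu, Gamma = Gamma)
}

## matrices -> theta vector; round-trips with unpack_theta
pack_theta <- function(layout, Lambda, theta_resid, nu, Gamma = NULL) {
  out <- numeric(layout$npar)
  if (layout$n_lam) out[seq_len(layout$n_lam)] <- Lambda[layout$lam_idx]
  out[layout$off_theta + seq_len(layout$p)] <- theta_resid
  out[layout$off_nu + seq_len(layout$p)] <- nu
  if (layout$n_gam)
    out[layout$off_gam + seq_len(layout$n_gam)] <- Gamma[layout$gam_idx]
  names(out) <- layout$names
  out
}

#' Model-implied moments
#'
#' Computes the model-implied mean vector and covariance matrix of the
#' indicators: `sigma = Lambda Phi Lambda' + Theta` with `Phi = I` for a
#' model without predictors. With exogenous predictors (treated as
#' fixed), the marginal factor covariance is
#' `Phi = Gamma S_x Gamma' + I` and the mean adds
#' `Lambda Gamma xbar`, where `S_x` and `xbar` are the predictors'
#' sample moments.
#'
#' @param spec a [TSOSpec-class].
#' @param theta named free-parameter vector (natural scale), as produced
#'   by [coef()] on a [TSOFit-class].
#' @param predictor_stats list with elements `mean` and `cov` of the
#'   predictors; required when the spec has predictors.
#' @return list with `mu` and `sigma`.
#' @export
impliedMoments <- function(spec, theta, predictor_stats = NULL) {
  layout <- spec_layout(spec)
  stopifnot(length(theta) == layout$npar)
  un <- unpack_theta(layout, theta)
  if (any(un$theta <= 0))
    stop("non-positive residual variance in theta", call. = FALSE)
  Phi <- diag(layout$mF)
  mu <- un$nu
  if (layout$q > 0) {
    if (is.null(predictor_stats))
      stop("predictor_stats required for a spec with predictors",
           call. = FALSE)
    Sx <- predictor_stats$cov
    Phi <- Phi + un$Gamma %*% Sx %*% t(un$Gamma)
    mu <- mu + drop(un$Lambda %*% un$Gamma %*% predictor_stats$mean)
  }
  sigma <- un$Lambda %*% Phi %*% t(un$Lambda) + diag(un$theta,
                                                     nrow = layout$p)
  dimnames(sigma) <- list(spec@indicators, spec@indicators)
  names(mu) <- spec@indicators
  list(mu = mu, sigma = sigma)
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' `F = log|sigma| - log|S| + trace(S sigma^-1) - p`, the normal-theory
#' ML fit function; zero exactly when `sigma = S`.
#'
#' @param S sample covariance matrix (positive definite).
#' @param sigma model-implied covariance matrix (positive definite).
#' @return non-negative scalar.
#' @export
mlDiscrepancy <- function(S, sigma) {
  S <- as.matrix(S); sigma <- as.matrix(sigma)
  p <- nrow(S)
  stopifnot(identical(dim(S), dim(sigma)))
  chS <- tryCatch(chol(S), error = function(e)
    stop("S is not positive definite", call. = FALSE))
  chSig <- tryCatch(chol(sigma), error = function(e)
    stop("sigma is not positive definite", call. = FALSE))
  ld_S <- 2 * sum(log(diag(chS)))
  ld_sig <- 2 * sum(log(diag(chSig)))
  ld_sig - ld_S + sum(diag(S %*% chol2inv(chSig))) - p
}

#' Serialise a model specification to JSON
#'
#' @param spec a [TSOSpec-class].
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return path (invisibly) or JSON string.
#' @export
writeTSOSpec <- function(spec, path = NULL) {
  doc <- list(n_substances = spec@nSubstances,
              n_occasions = spec@nOccasions,
              substances = spec@substances, occasions = spec@occasions,
              structural = spec@structural)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a model specification from JSON
#'
#' @param path JSON file written by [writeTSOSpec()].
#' @return a [TSOSpec-class].
#' @export
readTSOSpec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structural <- lapply(doc$structural, as.character)
  buildTSOSpec(doc$n_substances, doc$n_occasions, structural = structural,
               substances = doc$substances, occasions = doc$occasions)
}
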