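## Estimation of the TSO model: quasi-Newton maximisation of the FIML
## log-likelihood on a transformed space (log residual variances), with
## analytic gradients, deterministic start values, jittered restart
## fallback, observed-information naive SEs and sandwich robust SEs.

.tso_start <- function(layout, pat) {
  p <- layout$p
  sds <- vars <- mus <- numeric(p)
  for (j in seq_len(p)) {
    yj <- pat$Y[, j]
    yj <- yj[!is.na(yj)]
    mus[j] <- mean(yj)
    vars[j] <- stats::var(yj)
    sds[j] <- sqrt(vars[j])
  }
  L <- layout$template
  Lstart <- L
  Lstart[is.na(L)] <- 0
  if (layout$n_lam)
    Lstart[layout$lam_idx] <- 0.5 * sds[layout$lam_idx[, 1L]]
  pack_theta(layout, Lstart, 0.5 * vars, mus,
             matrix(0, layout$mF, layout$q))
}

## natural <-> working (log residual variances)
.to_working <- function(layout, theta) {
  idx <- layout$off_theta + seq_len(layout$p)
  theta[idx] <- log(theta[idx])
  theta
}
.to_natural <- function(layout, tw) {
  idx <- layout$off_theta + seq_len(layout$p)
  tw[idx] <- exp(tw[idx])
  tw
}

## Minimise -loglik over the working space with a value/gradient cache
## (nlminb queries objective and gradient separately).
.tso_optimise <- function(start_nat, layout, pat, control) {
  idx_th <- layout$off_theta + seq_len(layout$p)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(tw) {
    if (identical(cache$key, tw)) return(cache$val)
    theta <- .to_natural(layout, tw)
    res <- tso_loglik_grad(theta, layout, pat, want_grad = TRUE)
    if (is.null(res) || !is.finite(res$ll)) {
      val <- list(obj = 1e10, grad = rep(0, layout$npar))
    } else {
      g <- res$grad
      g[idx_th] <- g[idx_th] * theta[idx_th]   # chain rule for log scale
      val <- list(obj = -res$ll, grad = -g)
    }
    cache$key <- tw; cache$val <- val
    val
  }
  opt <- stats::nlminb(.to_working(layout, start_nat),
                       function(tw) evaluate(tw)$obj,
                       function(tw) evaluate(tw)$grad,
                       control = list(iter.max = control$iter_max,
                                      eval.max = control$eval_max,
                                      rel.tol = control$rel_tol))
  theta <- .to_natural(layout, opt$par)
  res <- tso_loglik_grad(theta, layout, pat, want_grad = TRUE)
  list(theta = theta, loglik = res$ll, grad = res$grad,
       optim_convergence = opt$convergence, message = opt$message,
       iterations = opt$iterations)
}

## Flip the sign of any factor whose free loadings sum negative; the
## likelihood is invariant, the reported solution becomes deterministic.
.canonicalise_signs <- function(layout, theta) {
  un <- unpack_theta(layout, theta)
  for (f in seq_len(layout$mF)) {
    rows <- which(layout$lam_idx[, 2L] == f)
    if (!length(rows)) next
    if (sum(un$Lambda[layout$lam_idx[rows, , drop = FALSE]]) < 0) {
      un$Lambda[, f] <- -un$Lambda[, f]
      if (layout$q > 0) un$Gamma[f, ] <- -un$Gamma[f, ]
    }
  }
  pack_theta(layout, un$Lambda, un$theta, un$nu, un$Gamma)
}

## Observed information by central differences of the analytic gradient.
.tso_hessian <- function(theta, layout, pat, eps = 1e-5) {
  npar <- layout$npar
  H <- matrix(0, npar, npar)
  for (k in seq_len(npar)) {
    h <- eps * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    gp <- tso_loglik_grad(tp, layout, pat)$grad
    gm <- tso_loglik_grad(tm, layout, pat)$grad
    H[, k] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

.solve_information <- function(A, names) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    d <- abs(diag(qr.R(qr(A))))
    bad <- names[d < max(d) * 1e-12]
    stop("information matrix is rank deficient; offending parameters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dimnames(out) <- list(names, names)
  out
}

#' Fit a trait-state-occasion model by FIML
#'
#' Maximises the full-information Gaussian log-likelihood of the
#' indicators (exogenous predictors treated as fixed regressors) with a
#' quasi-Newton method on a log-residual-variance transformed space and
#' analytic gradients. Start values: free loadings at half the
#' indicator's observed SD, residual variances at half the observed
#' variance, intercepts at the observed means, structural coefficients
#' at zero. The fit is declared converged when the optimiser terminates
#' normally and the per-observation-scaled gradient satisfies
#' `max|grad|/n < gradtol`; otherwise up to five deterministically
#' jittered restarts are attempted. Standard errors: naive from the
#' inverse observed information (numerical Hessian of the
#' log-likelihood); robust by the sandwich (see [robustSE()]).
#'
#' @param spec a [TSOSpec-class].
#' @param data data.frame containing the indicator columns (NA =
#'   missing) and, for a structural model, complete predictor columns.
#' @param se `"robust"`, `"naive"` or `"none"`.
#' @param start optional full start vector on the natural scale.
#' @param gradtol scaled-gradient convergence criterion.
#' @param control list: `iter_max`, `eval_max`, `rel_tol`, `restarts`,
#'   `restart_sd`.
#' @return a [TSOFit-class].
#' @examples
#' cfg <- simConfig(n_individuals = 300, n_snps = 20,
#'                  traits = "risk_taking", missing_rate = 0,
#'                  discretise = FALSE, seed = 2)
#' study <- simulateStudy(cfg)
#' fit <- fitTSO(buildTSOSpec(4, 3), studyPhenotypes(study), se = "none")
#' fit
#' @export
fitTSO <- function(spec, data, se = c("robust", "naive", "none"),
                   start = NULL, gradtol = 1e-5, control = list()) {
  se <- match.arg(se)
  control <- modifyList(list(iter_max = 1000L, eval_max = 2000L,
                             rel_tol = 1e-12, restarts = 5L,
                             restart_sd = 0.25), control)
  layout <- spec_layout(spec)
  miss_ind <- setdiff(spec@indicators, colnames(data))
  if (length(miss_ind))
    stop("data lacks indicator columns: ",
         paste(miss_ind, collapse = ", "), call. = FALSE)
  Y <- as.matrix(data[, spec@indicators, drop = FALSE])
  X <- NULL
  if (layout$q > 0) {
    missp <- setdiff(spec@predictors, colnames(data))
    if (length(missp))
      stop("data lacks predictor columns: ",
           paste(missp, collapse = ", "), call. = FALSE)
    X <- as.matrix(data[, spec@predictors, drop = FALSE])
    if (anyNA(X)) stop("predictors must be complete", call. = FALSE)
    if (any(apply(X, 2, stats::sd) == 0))
      stop("degenerate predictor: zero variance", call. = FALSE)
  }
  pat <- make_pattern_data(Y, X)
  start_nat <- if (is.null(start)) .tso_start(layout, pat) else start
  res <- .tso_optimise(start_nat, layout, pat, control)
  is_conv <- function(r)
    !is.null(r$grad) && max(abs(r$grad)) / pat$n < gradtol
  tries <- 0L
  while (!is_conv(res) && tries < control$restarts) {
    tries <- tries + 1L
    jit <- with_seed(1000L + tries, rnorm(layout$npar, 0,
                                          control$restart_sd))
    st <- start_nat * (1 + jit) + 0.01 * jit
    idx_th <- layout$off_theta + seq_len(layout$p)
    st[idx_th] <- pmax(st[idx_th], 1e-3)
    cand <- .tso_optimise(st, layout, pat, control)
    if (is.null(res$loglik) ||
        (!is.null(cand$loglik) && cand$loglik > res$loglik)) res <- cand
  }
  theta <- .canonicalise_signs(layout, res$theta)
  names(theta) <- layout$names
  converged <- is_conv(res)
  if (!converged)
    warning("fitTSO did not reach the scaled-gradient criterion (",
            signif(max(abs(res$grad)) / pat$n, 3), " >= ", gradtol, ")")
  heywood <- any(theta[layout$off_theta + seq_len(layout$p)] < 1e-6)
  if (heywood)
    warning("residual variance at the boundary (possible Heywood case)")
  pred_stats <- if (layout$q > 0)
    list(mean = colMeans(pat$X),
         cov = stats::cov(pat$X) * (pat$n - 1) / pat$n)
  else list()
  imp <- impliedMoments(spec, theta,
                        if (layout$q > 0) pred_stats else NULL)
  vcov_naive <- matrix(0, 0, 0)
  vcov_robust <- matrix(0, 0, 0)
  if (se != "none") {
    A <- -.tso_hessian(theta, layout, pat)
    vcov_naive <- .solve_information(A, layout$names)
    if (se == "robust") {
      S <- tso_scores(theta, layout, pat)
      B <- crossprod(S)
      vcov_robust <- vcov_naive %*% B %*% vcov_naive
      dimnames(vcov_robust) <- dimnames(vcov_naive)
    }
  }
  new("TSOFit", spec = spec, theta = theta, loglik = res$loglik,
      nUsed = as.integer(pat$n), converged = converged,
      heywood = heywood, vcovNaive = vcov_naive,
      vcovRobust = vcov_robust, impliedMu = imp$mu,
      impliedSigma = imp$sigma, predictorStats = pred_stats,
      optim = list(iterations = res$iterations,
                   optim_convergence = res$optim_convergence,
                   message = res$message, restarts = tries,
                   max_scaled_grad = max(abs(res$grad)) / pat$n,
                   n_skipped = pat$n_skipped))
}

#' @describeIn robustSE Sandwich estimator `A^-1 B A^-1` with bread `A`
#'   the observed information (numerical Hessian of the total FIML
#'   log-likelihood) and meat `B` the sum of outer products of casewise
#'   score vectors. Refreshes both covariance slots of the fit.
#' @export
setMethod("robustSE", "TSOFit", function(fit, data, ...) {
  if (!fit@converged)
    stop("robust SEs require a converged fit", call. = FALSE)
  layout <- spec_layout(fit@spec)
  Y <- as.matrix(data[, fit@spec@indicators, drop = FALSE])
  X <- if (layout$q > 0)
    as.matrix(data[, fit@spec@predictors, drop = FALSE]) else NULL
  pat <- make_pattern_data(Y, X)
  A <- -.tso_hessian(fit@theta, layout, pat)
  vcov_naive <- .solve_information(A, layout$names)
  S <- tso_scores(fit@theta, layout, pat)
  B <- crossprod(S)
  vr <- vcov_naive %*% B %*% vcov_naive
  dimnames(vr) <- dimnames(vcov_naive)
  fit@vcovNaive <- vcov_naive
  fit@vcovRobust <- vr
  fit
})

#' @describeIn fitTSO Free-parameter estimates (natural scale).
#' @param object,x a [TSOFit-class].
#' @export
setMethod("coef", "TSOFit", function(object, ...) object@theta)

#' @describeIn fitTSO FIML log-likelihood with `df` and `nobs`
#'   attributes.
#' @export
setMethod("logLik", "TSOFit", function(object, ...)
  structure(object@loglik, df = length(object@theta),
            nobs = object@nUsed, class = "logLik"))

#' @describeIn fitTSO Covariance matrix of the estimates;
#'   `type = "robust"` (default when available) or `"naive"`.
#' @param type which covariance matrix.
#' @export
setMethod("vcov", "TSOFit", function(object,
                                     type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  if (type == "robust" && nrow(object@vcovRobust) > 0)
    return(object@vcovRobust)
  if (type == "robust" && nrow(object@vcovNaive) == 0)
    stop("fit carries no covariance matrix (se = 'none')", call. = FALSE)
  if (type == "robust")
    stop("robust covariance not computed; call robustSE()", call. = FALSE)
  if (nrow(object@vcovNaive) == 0)
    stop("fit carries no covariance matrix (se = 'none')", call. = FALSE)
  object@vcovNaive
})

#' Standard errors of a fitted TSO model
#'
#' @param fit a [TSOFit-class].
#' @param type `"robust"` or `"naive"`.
#' @return named vector of standard errors.
#' @export
seTSO <- function(fit, type = c("robust", "naive")) {
  sqrt(diag(vcov(fit, type = match.arg(type))))
}

setMethod("show", "TSOFit", function(object) {
  cat("TSOFit:", length(object@theta), "free parameters, n =",
      object@nUsed, "\n")
  cat("  log-likelihood:", format(object@loglik, digits = 8), "\n")
  cat("  converged:", object@converged,
      if (object@heywood) " (Heywood warning)" else "", "\n")
  if (length(object@spec@structural)) {
    cat("  structural coefficients (raw):\n")
    pt <- object@spec@paramTable
    g <- which(pt$type == "gamma")
    est <- object@theta[g]
    se <- if (nrow(object@vcovRobust)) sqrt(diag(object@vcovRobust))[g]
          else rep(NA_real_, length(g))
    for (i in seq_along(g))
      cat(sprintf("    %-24s %8.4f (se %.4f)\n", pt$name[g[i]], est[i],
                  se[i]))
  }
})
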