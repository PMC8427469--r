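## Full-information likelihood machinery. Rows are grouped by their
## missingness pattern; within a pattern the likelihood and its analytic
## gradient are evaluated from accumulated cross-product statistics, so
## the cost of one evaluation does not grow with n. Casewise score
## vectors (for the sandwich meat) use the same algebra row-wise.

## Group rows of Y (indicators, NA = missing) and X (complete
## predictors) by missingness pattern and accumulate per-pattern
## cross-products W = sum over rows of w w', w = (y_obs, 1, x).
make_pattern_data <- function(Y, X = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  q <- if (is.null(X)) 0L else ncol(X)
  if (q > 0) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == n, !anyNA(X))
  }
  obs <- !is.na(Y)
  all_missing <- rowSums(obs) == 0L
  n_skipped <- sum(all_missing)
  if (n_skipped > 0) {
    warning(n_skipped, " rows with all indicators missing skipped")
    Y <- Y[!all_missing, , drop = FALSE]
    obs <- obs[!all_missing, , drop = FALSE]
    if (q > 0) X <- X[!all_missing, , drop = FALSE]
    n <- nrow(Y)
  }
  key <- as.vector(obs %*% (2^(seq_len(p) - 1)))
  groups <- split(seq_len(n), key)
  patterns <- lapply(groups, function(rows) {
    o <- which(obs[rows[1L], ])
    block <- cbind(Y[rows, o, drop = FALSE], 1,
                   if (q > 0) X[rows, , drop = FALSE])
    list(o = o, rows = rows, n = length(rows), W = crossprod(block))
  })
  list(patterns = patterns, n = n, p = p, q = q, Y = Y, X = X,
       n_skipped = n_skipped)
}

## FIML log-likelihood and analytic gradient at a natural-scale theta.
## Returns list(ll, grad). `want_grad = FALSE` skips gradient work.
tso_loglik_grad <- function(theta, layout, pat, want_grad = TRUE) {
  un <- unpack_theta(layout, theta)
  p <- layout$p; q <- layout$q; mF <- layout$mF
  Lambda <- un$Lambda
  Sigma <- tcrossprod(Lambda) + diag(un$theta, nrow = p)
  B <- if (q > 0) Lambda %*% un$Gamma else NULL
  ll <- 0
  G <- matrix(0, p, p)
  gnu <- numeric(p)
  GB <- if (q > 0) matrix(0, p, q) else NULL
  log2pi <- log(2 * pi)
  for (g in pat$patterns) {
    o <- g$o; m <- length(o); d <- m + 1L + q
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    C <- chol2inv(ch)
    logdet <- 2 * sum(log(diag(ch)))
    nu_o <- un$nu[o]
    W <- g$W
    AW <- W[seq_len(m), , drop = FALSE] -
      tcrossprod(nu_o, W[m + 1L, ])
    if (q > 0)
      AW <- AW - B[o, , drop = FALSE] %*%
        W[m + 1L + seq_len(q), , drop = FALSE]
    M <- AW[, seq_len(m), drop = FALSE] -
      tcrossprod(AW[, m + 1L], nu_o)
    if (q > 0)
      M <- M - AW[, m + 1L + seq_len(q), drop = FALSE] %*%
        t(B[o, , drop = FALSE])
    M <- (M + t(M)) / 2
    ll <- ll - 0.5 * (g$n * (m * log2pi + logdet) + sum(C * M))
    if (want_grad) {
      CM <- C %*% M
      Gg <- -0.5 * g$n * C + 0.5 * CM %*% C
      G[o, o] <- G[o, o] + Gg
      gnu[o] <- gnu[o] + drop(C %*% AW[, m + 1L])
      if (q > 0)
        GB[o, ] <- GB[o, ] + C %*% AW[, m + 1L + seq_len(q), drop = FALSE]
    }
  }
  if (!want_grad) return(list(ll = ll, grad = NULL))
  dLam <- 2 * G %*% Lambda
  if (q > 0) dLam <- dLam + GB %*% t(un$Gamma)
  grad <- numeric(layout$npar)
  if (layout$n_lam) grad[seq_len(layout$n_lam)] <- dLam[layout$lam_idx]
  grad[layout$off_theta + seq_len(p)] <- diag(G)
  grad[layout$off_nu + seq_len(p)] <- gnu
  if (layout$n_gam) {
    dGam <- crossprod(Lambda, GB)
    grad[layout$off_gam + seq_len(layout$n_gam)] <- dGam[layout$gam_idx]
  }
  list(ll = ll, grad = grad)
}

## Casewise score matrix (n x npar) at a natural-scale theta; column
## sums equal the total analytic gradient.
tso_scores <- function(theta, layout, pat) {
  un <- unpack_theta(layout, theta)
  p <- layout$p; q <- layout$q
  Lambda <- un$Lambda
  Sigma <- tcrossprod(Lambda) + diag(un$theta, nrow = p)
  B <- if (q > 0) Lambda %*% un$Gamma else NULL
  S <- matrix(0, pat$n, layout$npar)
  for (g in pat$patterns) {
    o <- g$o; m <- length(o)
    C <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
    Lo <- Lambda[o, , drop = FALSE]
    R <- pat$Y[g$rows, o, drop = FALSE] -
      matrix(un$nu[o], g$n, m, byrow = TRUE)
    if (q > 0)
      R <- R - pat$X[g$rows, , drop = FALSE] %*% t(B[o, , drop = FALSE])
    U <- R %*% C
    V <- U %*% Lo
    CLam <- C %*% Lo
    W2 <- if (q > 0) pat$X[g$rows, , drop = FALSE] %*% t(un$Gamma) else NULL
    ## intercepts
    S[g$rows, layout$off_nu + o] <- U
    ## residual variances
    S[g$rows, layout$off_theta + o] <-
      matrix(-0.5 * diag(C), g$n, m, byrow = TRUE) + 0.5 * U^2
    ## loadings
    if (layout$n_lam) {
      for (k in seq_len(layout$n_lam)) {
        j <- layout$lam_idx[k, 1L]; f <- layout$lam_idx[k, 2L]
        jl <- match(j, o)
        if (is.na(jl)) next
        val <- -CLam[jl, f] + U[, jl] * V[, f]
        if (q > 0) val <- val + U[, jl] * W2[, f]
        S[g$rows, k] <- val
      }
    }
    ## structural coefficients
    if (layout$n_gam) {
      for (k in seq_len(layout$n_gam)) {
        f <- layout$gam_idx[k, 1L]; x <- layout$gam_idx[k, 2L]
        S[g$rows, layout$off_gam + k] <-
          V[, f] * pat$X[g$rows, x]
      }
    }
  }
  colnames(S) <- layout$names
  S
}

#' Full-information multivariate-normal log-likelihood
#'
#' Evaluates the incomplete-data Gaussian log-likelihood of a data
#' matrix under fixed moments `(mu, sigma)`: rows are grouped by
#' missingness pattern and each contributes the log-density of its
#' observed sub-vector under the corresponding sub-moments. The result
#' is identical to row-wise evaluation; on complete data it equals the
#' sum of full multivariate-normal log-densities. Rows with every
#' variable missing are skipped with a warning.
#'
#' @param data matrix or data.frame of indicators, `NA` = missing.
#' @param mu mean vector.
#' @param sigma positive-definite covariance matrix.
#' @return log-likelihood scalar with attribute `"n_skipped"`.
#' @export
fimlLogLik <- function(data, mu, sigma) {
  Y <- as.matrix(data)
  p <- ncol(Y)
  stopifnot(length(mu) == p, identical(dim(as.matrix(sigma)), c(p, p)))
  sigma <- as.matrix(sigma)
  obs <- !is.na(Y)
  skip <- rowSums(obs) == 0L
  if (any(skip)) {
    warning(sum(skip), " rows with all variables missing skipped")
    Y <- Y[!skip, , drop = FALSE]
    obs <- obs[!skip, , drop = FALSE]
  }
  key <- as.vector(obs %*% (2^(seq_len(p) - 1)))
  ll <- 0
  for (rows in split(seq_len(nrow(Y)), key)) {
    o <- which(obs[rows[1L], ])
    m <- length(o)
    ch <- tryCatch(chol(sigma[o, o, drop = FALSE]), error = function(e)
      stop("sigma sub-matrix not positive definite", call. = FALSE))
    C <- chol2inv(ch)
    R <- Y[rows, o, drop = FALSE] -
      matrix(mu[o], length(rows), m, byrow = TRUE)
    quad <- rowSums((R %*% C) * R)
    ll <- ll - 0.5 * sum(m * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
  }
  structure(ll, n_skipped = sum(skip))
}

#' Saturated multivariate-normal fit under missingness
#'
#' Maximum-likelihood mean and covariance of an incomplete data matrix
#' via the EM algorithm (E-step: conditional moments of the missing
#' block given the observed block; M-step: moment update), iterated to a
#' relative log-likelihood change below `tol`. On complete data this
#' returns the closed-form ML moments (column means and the
#' n-denominator covariance) directly.
#'
#' @param data matrix or data.frame, `NA` = missing. Every variable must
#'   be observed at least once.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `mu`, `sigma`, `loglik`, `iterations`, `converged`,
#'   and the per-iteration `loglik_trace`.
#' @export
fitSaturated <- function(data, tol = 1e-8, max_iter = 500L) {
  Y <- as.matrix(data)
  n <- nrow(Y); p <- ncol(Y)
  obs <- !is.na(Y)
  if (any(colSums(obs) == 0L))
    stop("inestimable: variable never observed: ",
         paste(colnames(Y)[colSums(obs) == 0L], collapse = ", "),
         call. = FALSE)
  keep <- rowSums(obs) > 0L
  Y <- Y[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
  n <- nrow(Y)
  if (!anyNA(Y)) {
    mu <- colMeans(Y)
    sigma <- crossprod(sweep(Y, 2, mu)) / n
    ll <- as.numeric(fimlLogLik(Y, mu, sigma))
    return(list(mu = mu, sigma = sigma, loglik = ll, iterations = 0L,
                converged = TRUE, loglik_trace = ll))
  }
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2, stats::var, na.rm = TRUE)
  sigma <- diag(v, nrow = p)
  key <- as.vector(obs %*% (2^(seq_len(p) - 1)))
  groups <- split(seq_len(n), key)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Ey <- numeric(p)
    Eyy <- matrix(0, p, p)
    ll <- 0
    for (rows in groups) {
      o <- which(obs[rows[1L], ])
      mi <- setdiff(seq_len(p), o)
      Yo <- Y[rows, o, drop = FALSE]
      ch <- chol(sigma[o, o, drop = FALSE])
      C <- chol2inv(ch)
      R <- Yo - matrix(mu[o], length(rows), length(o), byrow = TRUE)
      ll <- ll - 0.5 * sum(length(o) * log(2 * pi) +
                             2 * sum(log(diag(ch))) +
                             rowSums((R %*% C) * R))
      Yfull <- matrix(0, length(rows), p)
      Yfull[, o] <- Yo
      if (length(mi)) {
        beta <- sigma[mi, o, drop = FALSE] %*% C
        cond <- matrix(mu[mi], length(rows), length(mi), byrow = TRUE) +
          R %*% t(beta)
        Yfull[, mi] <- cond
        condvar <- sigma[mi, mi, drop = FALSE] -
          beta %*% sigma[o, mi, drop = FALSE]
        Eyy[mi, mi] <- Eyy[mi, mi] + length(rows) * condvar
      }
      Ey <- Ey + colSums(Yfull)
      Eyy <- Eyy + crossprod(Yfull)
    }
    mu_new <- Ey / n
    sigma_new <- Eyy / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      mu <- mu_new; sigma <- sigma_new
      break
    }
    mu <- mu_new; sigma <- sigma_new
    ll_old <- ll
    if (iter >= max_iter) break
  }
  names(mu) <- colnames(Y)
  dimnames(sigma) <- list(colnames(Y), colnames(Y))
  list(mu = mu, sigma = sigma,
       loglik = as.numeric(fimlLogLik(Y, mu, sigma)),
       iterations = iter, converged = converged, loglik_trace = trace)
}
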