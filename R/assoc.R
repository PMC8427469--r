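## Association stages: single-PGS TSO models (every trait factor
## regressed on one polygenic score plus covariates), BH-FDR correction,
## FDR-based selection, and multivariable (multi-PGS) TSO models per
## factor for the substance-use and trait PGS sets.

trait_factors <- function(spec)
  grep("^C$|^S_", spec@factorNames, value = TRUE)

## Embed a fitted covariates-only solution as a start vector for a model
## with additional predictors (extra structural coefficients start at 0).
.embed_start <- function(fit_base, spec_new) {
  lay_new <- spec_layout(spec_new)
  start <- numeric(lay_new$npar)
  names(start) <- lay_new$names
  common <- intersect(names(fit_base@theta), names(start))
  start[common] <- fit_base@theta[common]
  idx_th <- lay_new$off_theta + seq_len(lay_new$p)
  start[idx_th] <- pmax(start[idx_th], 1e-3)
  start
}

## Pull the structural rows for one focal set of predictors out of a
## fitted model: raw and standardised estimates, robust Wald p.
.structural_rows <- function(fit, focal, model_id) {
  std <- standardisedSolution(fit, type = "robust")
  rows <- std[std$type == "gamma" & std$rhs %in% focal, , drop = FALSE]
  se_rob <- seTSO(fit, "robust")[rows$name]
  z <- rows$est / se_rob
  data.frame(model = model_id, pgs = rows$rhs, factor = rows$lhs,
             b_std = rows$est_std,
             ci_low = rows$est_std - 1.96 * rows$se_std,
             ci_high = rows$est_std + 1.96 * rows$se_std,
             se_robust = unname(se_rob),
             p_raw = 2 * pnorm(-abs(z)),
             converged = fit@converged,
             row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_(j >= i) (p_(j) m / j)` capped
#' at 1, applied separately within each family. `NA` entries are
#' excluded from their family (and returned as `NA`).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param family optional grouping vector defining FDR families; a
#'   single family when `NULL`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bhFdr <- function(p, family = NULL) {
  if (!length(p)) return(numeric(0))
  if (any(!is.na(p) & (p <= 0 | p > 1)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (is.null(family)) family <- rep(1L, length(p))
  out <- rep(NA_real_, length(p))
  for (fam in split(seq_along(p), family)) {
    ok <- fam[!is.na(p[fam])]
    if (length(ok)) out[ok] <- p.adjust(p[ok], method = "BH")
  }
  out
}

#' Single-PGS trait-state-occasion association models
#'
#' For each polygenic score, fits one TSO model in which all trait
#' factors (the common factor and every substance-specific factor) are
#' simultaneously regressed on that score plus the covariates, with
#' sandwich robust standard errors. Per-(PGS, factor) rows report the
#' fully standardised coefficient, its delta-method 95% CI, the robust
#' Wald p-value, and the BH-FDR adjusted p-value.
#'
#' For speed, a covariates-only model is fitted once and used as warm
#' start for every per-PGS fit.
#'
#' @param data data.frame with the indicator columns, the PGS columns
#'   and the covariate columns. PGS columns must be standardised.
#' @param spec baseline [TSOSpec-class] (no predictors).
#' @param pgs character vector of PGS column names in `data`.
#' @param covariates character vector of covariate column names
#'   (canonically sex plus 10 principal components).
#' @param family FDR family: `"per_factor"` (BH across PGSs within each
#'   factor, the default) or `"global"` (one family over all rows).
#' @param se_type reserved; robust SEs are always used.
#' @return data.frame (an association table) with columns `model`,
#'   `pgs`, `factor`, `b_std`, `ci_low`, `ci_high`, `se_robust`,
#'   `p_raw`, `p_fdr`, `converged`. Non-converged fits are flagged and
#'   excluded from the FDR family with a warning.
#' @export
runSinglePGS <- function(data, spec, pgs, covariates = character(0),
                         family = c("per_factor", "global"),
                         se_type = "robust") {
  family <- match.arg(family)
  stopifnot(all(pgs %in% colnames(data)),
            all(covariates %in% colnames(data)))
  tf <- trait_factors(spec)
  base_fit <- NULL
  if (length(covariates)) {
    spec0 <- buildTSOSpec(spec@nSubstances, spec@nOccasions,
                          structural = setNames(
                            rep(list(covariates), length(tf)), tf),
                          substances = spec@substances,
                          occasions = spec@occasions)
    base_fit <- fitTSO(spec0, data, se = "none")
  } else {
    spec0 <- buildTSOSpec(spec@nSubstances, spec@nOccasions,
                          substances = spec@substances,
                          occasions = spec@occasions)
    base_fit <- fitTSO(spec0, data, se = "none")
  }
  out <- vector("list", length(pgs))
  for (i in seq_along(pgs)) {
    g <- pgs[i]
    preds <- c(g, covariates)
    spec_i <- buildTSOSpec(spec@nSubstances, spec@nOccasions,
                           structural = setNames(
                             rep(list(preds), length(tf)), tf),
                           substances = spec@substances,
                           occasions = spec@occasions)
    fit_i <- fitTSO(spec_i, data, se = "robust",
                    start = .embed_start(base_fit, spec_i))
    out[[i]] <- .structural_rows(fit_i, g, paste0("single:", g))
  }
  tab <- do.call(rbind, out)
  tab$model_kind <- "single"
  if (any(!tab$converged))
    warning(sum(!tab$converged),
            " non-converged rows excluded from the FDR family")
  pv <- ifelse(tab$converged, tab$p_raw, NA_real_)
  fam <- if (family == "per_factor") tab$factor else rep(1L, nrow(tab))
  tab$p_fdr <- bhFdr(pv, fam)
  tab
}

#' Select FDR-significant PGSs per factor
#'
#' For each latent factor, returns the PGSs whose FDR-adjusted p-value
#' is below `alpha`, partitioned into substance-use PGSs (set A of the
#' multivariable stage) and trait/vulnerability PGSs (set B) by the
#' category map.
#'
#' @param table association table from [runSinglePGS()].
#' @param alpha selection threshold on `p_fdr` (default 0.05).
#' @param categories named character vector mapping each PGS to
#'   `"substance"` or `"trait"` (see [defaultPgsCategories()]).
#' @return named list per factor, each a list with elements `substance`
#'   and `trait` (possibly empty character vectors).
#' @export
selectSignificant <- function(table, alpha = 0.05,
                              categories = defaultPgsCategories()) {
  unknown <- setdiff(unique(table$pgs), names(categories))
  if (length(unknown))
    stop("no category declared for PGS: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!all(categories %in% c("substance", "trait")))
    stop("categories must be 'substance' or 'trait'", call. = FALSE)
  out <- list()
  for (f in unique(table$factor)) {
    rows <- table[table$factor == f & !is.na(table$p_fdr) &
                    table$p_fdr < alpha, , drop = FALSE]
    out[[f]] <- list(
      substance = rows$pgs[categories[rows$pgs] == "substance"],
      trait = rows$pgs[categories[rows$pgs] == "trait"])
  }
  out
}

#' Multivariable (multi-PGS) trait-state-occasion models
#'
#' For each latent factor and each non-empty selected set (A:
#' substance-use PGSs; B: trait PGSs), fits one TSO model regressing
#' that factor on all selected PGSs plus covariates jointly, with the
#' other trait factors regressed on covariates only. Rows carry the
#' mutually adjusted standardised coefficients.
#'
#' @param data data.frame with indicators, PGS and covariate columns.
#' @param spec baseline [TSOSpec-class].
#' @param selected per-factor selection from [selectSignificant()].
#' @param covariates covariate column names.
#' @param condition_threshold collinearity guard: an error names the
#'   most correlated pair when the PGS correlation matrix's condition
#'   number exceeds it.
#' @return association table as in [runSinglePGS()], with `model_kind`
#'   `"multi-A-substance"` or `"multi-B-trait"` and `p_fdr` adjusted
#'   within each fitted model's rows.
#' @export
runMultiPGS <- function(data, spec, selected, covariates = character(0),
                        condition_threshold = 1e8) {
  tf <- trait_factors(spec)
  out <- list()
  for (f in names(selected)) {
    for (set_name in c("substance", "trait")) {
      set_pgs <- selected[[f]][[set_name]]
      if (!length(set_pgs)) next
      if (length(set_pgs) > 1) {
        Rm <- stats::cor(as.matrix(data[, set_pgs, drop = FALSE]))
        if (kappa(Rm, exact = TRUE) > condition_threshold) {
          off <- abs(Rm); diag(off) <- 0
          worst <- which(off == max(off), arr.ind = TRUE)[1, ]
          stop("collinear PGSs: ", set_pgs[worst[1]], " and ",
               set_pgs[worst[2]], call. = FALSE)
        }
      }
      structural <- setNames(rep(list(covariates), length(tf)), tf)
      structural[[f]] <- c(set_pgs, covariates)
      structural <- structural[lengths(structural) > 0]
      spec_f <- buildTSOSpec(spec@nSubstances, spec@nOccasions,
                             structural = structural,
                             substances = spec@substances,
                             occasions = spec@occasions)
      fit_f <- fitTSO(spec_f, data, se = "robust")
      kind <- if (set_name == "substance") "multi-A-substance"
              else "multi-B-trait"
      rows <- .structural_rows(fit_f, set_pgs,
                               paste0(kind, ":", f))
      rows <- rows[rows$factor == f, , drop = FALSE]
      rows$model_kind <- kind
      rows$p_fdr <- bhFdr(ifelse(rows$converged, rows$p_raw, NA_real_))
      out[[paste(f, set_name)]] <- rows
    }
  }
  if (!length(out))
    return(data.frame(model = character(0), pgs = character(0),
                      factor = character(0), b_std = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      se_robust = numeric(0), p_raw = numeric(0),
                      converged = logical(0),
                      model_kind = character(0), p_fdr = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
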