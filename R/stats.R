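## Group inference and correlation with covariate removal.

## Build the design matrix (intercept + covariates, sex coded 0/1 where
## character/factor) and fail on rank deficiency.
covariateDesign <- function(n, covariates) {
  if (is.null(covariates) || (is.data.frame(covariates) && !ncol(covariates)))
    return(matrix(1, n, 1))
  covariates <- as.data.frame(covariates)
  stopIfNot(nrow(covariates) == n, "covariate rows must match values")
  stopIfNot(!anyNA(covariates), "missing covariate values are not allowed")
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  stopIfNot(qrX$rank == ncol(X),
            "covariate design is rank deficient after adding an intercept")
  X
}

#' Residualize values on covariates
#'
#' Ordinary least-squares residuals of \code{values} on an intercept plus
#' the covariate columns (character/factor covariates such as sex are
#' dummy-coded). Residuals sum to zero.
#'
#' @param values numeric vector, no missing values.
#' @param covariates data.frame of covariates (or NULL: centering only).
#' @return numeric residual vector.
#' @export
residualize <- function(values, covariates = NULL) {
  stopIfNot(!anyNA(values), "missing values are not allowed")
  X <- covariateDesign(length(values), covariates)
  qr.resid(qr(X), values)
}

#' Permutation test of a group difference with covariate removal
#'
#' Freedman-Lane scheme: the pooled values are residualized once on the
#' covariates, the observed statistic is the difference of group means of
#' those residuals (group1 minus group2), and the null is built by
#' permuting the group labels over the residuals. The two-tailed p uses
#' the add-one estimator p = (1 + #{|T_perm| >= |T_obs|}) / (1 + nPerm),
#' so p is never zero.
#'
#' @param g1,g2 numeric vectors, one per group (both non-empty).
#' @param covariates data.frame with \code{length(g1) + length(g2)} rows in
#'   (g1, g2) order, or NULL.
#' @param nPerm number of label permutations (reference analysis: 10000).
#' @param seed integer seed.
#' @return a \linkS4class{PermutationTestResult}.
#' @export
permutationGroupTest <- function(g1, g2, covariates = NULL, nPerm = 10000,
                                 seed = 1) {
  stopIfNot(length(g1) >= 1L && length(g2) >= 1L,
            "both groups must be non-empty")
  stopIfNot(nPerm >= 1, "nPerm must be >= 1")
  n1 <- length(g1); n <- n1 + length(g2)
  e <- residualize(c(g1, g2), covariates)
  obs <- mean(e[seq_len(n1)]) - mean(e[(n1 + 1):n])
  tnull <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    p <- sample.int(n)
    mean(e[p[seq_len(n1)]]) - mean(e[p[(n1 + 1):n]])
  }, 1))
  p <- (1 + sum(abs(tnull) >= abs(obs))) / (1 + nPerm)
  new("PermutationTestResult", observed = obs, nullMean = mean(tnull),
      nullSd = stats::sd(tnull), nPerm = as.integer(nPerm), pRaw = p,
      pAdjusted = NA_real_, method = "none", seed = as.integer(seed))
}

checkP <- function(p) {
  stopIfNot(is.numeric(p) && all(p >= 0 & p <= 1),
            "p-values must lie in [0, 1]")
}

#' Holm-Bonferroni (FWE) step-down adjustment
#'
#' @param p numeric p-values in [0, 1].
#' @param alpha family-wise significance level for the decisions.
#' @return list(adjusted, reject).
#' @export
holmBonferroni <- function(p, alpha = 0.05) {
  checkP(p)
  adj <- stats::p.adjust(p, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Benjamini-Hochberg (FDR) step-up adjustment
#'
#' @param p numeric p-values in [0, 1].
#' @param q false-discovery level for the decisions.
#' @return list(adjusted, reject).
#' @export
benjaminiHochberg <- function(p, q = 0.05) {
  checkP(p)
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' Covariate-adjusted Spearman correlation
#'
#' Residualizes x and y on the covariates (OLS, intercept included), then
#' computes the Spearman rank correlation of the residuals; the two-tailed
#' p comes from the t approximation with n - 2 degrees of freedom. If
#' either variable is constant after residualization the result is NA.
#'
#' @param x,y numeric vectors, length >= 4.
#' @param covariates data.frame of covariates or NULL.
#' @return a \linkS4class{CorrelationResult}.
#' @export
spearmanPartial <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopIfNot(n >= 4L && length(y) == n,
            "need matched x and y with n >= 4")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  covNames <- if (is.null(covariates)) character(0) else
    colnames(as.data.frame(covariates))
  nearConst <- function(r) stats::sd(r) <= 1e-12 * max(1, abs(mean(r)))
  if (nearConst(rx) || nearConst(ry))
    return(new("CorrelationResult", rho = NA_real_, p = NA_real_,
               n = as.integer(n), covariates = covNames))
  rho <- stats::cor(rx, ry, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new("CorrelationResult", rho = rho, p = p, n = as.integer(n),
      covariates = covNames)
}

#' Mann-Whitney U test
#'
#' U from rank sums with midrank ties; the p-value is exact when
#' min(n, m) <= 8 and the pooled sample has no ties, otherwise a normal
#' approximation with tie-corrected variance is used.
#'
#' @param x,y numeric samples (both non-empty).
#' @param correct continuity correction for the normal approximation.
#' @return list(U, p, exact).
#' @export
mannWhitneyU <- function(x, y, correct = TRUE) {
  stopIfNot(length(x) >= 1L && length(y) >= 1L,
            "both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = correct))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Without continuity correction by default (1 degree of freedom);
#' \code{correct = TRUE} applies the Yates correction.
#'
#' @param table 2 x 2 matrix of non-negative counts with no zero margin.
#' @param correct apply the continuity correction.
#' @return list(statistic, p, df).
#' @export
chiSquare2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopIfNot(all(dim(table) == c(2L, 2L)) && all(table >= 0),
            "table must be 2 x 2 with non-negative counts")
  stopIfNot(all(rowSums(table) > 0) && all(colSums(table) > 0),
            "table must have no zero margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter))
}
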