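#' Phylogenetic covariance matrix of a tree
#'
#' The Brownian-motion expected among-species covariance: diagonal entries
#' are root-to-tip path lengths, off-diagonal entries the depth of the most
#' recent common ancestor of each pair.
#'
#' @param tree an [ape::phylo] tree with branch lengths (in Myr).
#' @return an n x n symmetric positive semi-definite matrix with species
#'   order given by the tip labels.
#' @export
tree_covariance <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies all off-diagonal covariances by `lambda`, leaving the
#' diagonal unchanged: lambda = 1 is the Brownian expectation, lambda = 0 a
#' star phylogeny (no phylogenetic signal).
#'
#' @param C phylogenetic covariance matrix.
#' @param lambda value in `[0, upper]`.
#' @param upper admissible upper bound (default 1).
#' @return the transformed covariance matrix.
#' @export
lambda_transform <- function(C, lambda, upper = 1) {
  if (length(lambda) != 1L || !is.finite(lambda) ||
    lambda < 0 || lambda > upper) {
    stop("lambda must lie in [0, ", upper, "]")
  }
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

## Gaussian profile log-likelihood of a common lambda across columns, with
## per-column Brownian rates profiled out analytically
lambda_profile_loglik <- function(lambda, resid, C) {
  n <- nrow(resid)
  Cl <- lambda_transform(C, lambda)
  R <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(R)) {
    return(-Inf)
  }
  logdet <- 2 * sum(log(diag(R)))
  Z <- backsolve(R, resid, transpose = TRUE)
  one <- backsolve(R, rep(1, n), transpose = TRUE)
  mu <- drop(crossprod(one, Z)) / sum(one^2)
  Zc <- Z - outer(one, mu)
  sigma2 <- colSums(Zc^2) / n
  sum(-n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2)
}

#' Estimate Pagel's lambda on multivariate residuals
#'
#' Maximizes, over a common lambda, the sum across residual columns of the
#' Brownian-motion Gaussian log-likelihood with covariance
#' `lambda_transform(C, lambda)`; each column's rate (and mean) is profiled
#' out analytically. Optimized by Brent search on `[0, upper]` to a
#' tolerance of 1e-6. Constant columns are dropped with a warning.
#'
#' @param resid n x p residual matrix, rows matched to `C`.
#' @param C phylogenetic covariance matrix.
#' @param upper search upper bound (default 1).
#' @return the maximizing lambda.
#' @export
estimate_lambda <- function(resid, C, upper = 1) {
  resid <- as.matrix(resid)
  constant <- apply(resid, 2L, function(x) var(x) == 0)
  if (any(constant)) {
    warning(sum(constant), " constant residual column(s) dropped")
    resid <- resid[, !constant, drop = FALSE]
  }
  if (!ncol(resid)) stop("no non-constant residual columns")
  opt <- optimize(
    lambda_profile_loglik,
    interval = c(0, upper), maximum = TRUE, tol = 1e-6,
    resid = resid, C = C
  )
  ## Brent search can stall off the boundary; check the endpoints too
  cand <- c(opt$maximum, 0, upper)
  ll <- c(
    opt$objective,
    lambda_profile_loglik(0, resid, C),
    lambda_profile_loglik(upper, resid, C)
  )
  cand[which.max(ll)]
}
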