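#' Regularization path endpoint
#'
#' The smallest lambda at which the node-wise lasso returns an empty graph:
#' the largest absolute off-diagonal entry of the covariance matrix. At any
#' `lambda >= lambda_max(gamma)` every soft-threshold update shrinks all
#' coefficients to exactly zero.
#'
#' @param gamma Symmetric d x d covariance matrix (`d >= 2`).
#' @return A non-negative scalar.
#' @export
lambda_max <- function(gamma) {
  gamma <- unclass(gamma)
  if (nrow(gamma) < 2L) stopf("lambda_max needs at least 2 proteins")
  off <- abs(gamma)
  diag(off) <- 0
  max(off)
}

#' Build a lambda path
#'
#' A decreasing sequence of K regularization strengths from `lmax` down to
#' `lmax * min_ratio`, log-spaced by default. Thirty values along the path
#' is the conventional resolution for StARS model selection.
#'
#' @param lmax Path endpoint, usually [lambda_max()] of the covariance.
#' @param K Number of values (default 30).
#' @param min_ratio Smallest lambda as a fraction of `lmax` (default 0.01).
#'   With `spacing = "linear"`, `min_ratio = 0` is allowed and puts 0 on the
#'   path.
#' @param spacing `"log"` (default) or `"linear"`.
#' @return Numeric vector of strictly decreasing lambda values.
#' @export
build_lambda_path <- function(lmax, K = 30L, min_ratio = 0.01,
                              spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (!is.finite(lmax) || lmax <= 0) stopf("lmax must be positive")
  if (K < 2L) stopf("K must be >= 2")
  if (min_ratio < 0 || min_ratio >= 1) stopf("min_ratio must be in [0, 1)")
  if (spacing == "log") {
    if (min_ratio <= 0) stopf("log spacing needs min_ratio > 0")
    exp(seq(log(lmax), log(lmax * min_ratio), length.out = K))
  } else {
    seq(lmax, lmax * min_ratio, length.out = K)
  }
}

#' Fit the neighborhood-selection lasso at one lambda
#'
#' Solves, for every protein j, the covariance-parameterized lasso
#' `min_g 0.5 g' Gamma g - Gamma[,j]' g + lambda ||g||_1` with `g[j] = 0`,
#' by cyclic coordinate descent with soft-thresholding. Column j of the
#' returned coefficient matrix holds protein j's estimated neighborhood;
#' nonzero entries are the conditional-dependence partners. Equivalent to an
#' L1-penalized regression of each profile on all others, but parameterized
#' by the Gram matrix only, so subsampled refits never touch the raw data.
#'
#' @param gamma Symmetric d x d covariance matrix ([clr_covariance()]).
#' @param lambda Regularization strength, `>= 0`.
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   sweep (default 1e-4).
#' @param max_iter Maximum coordinate-descent sweeps per column (default 1000).
#' @param init Optional d x d warm-start coefficient matrix (e.g. the
#'   solution at the previous, larger lambda).
#' @return List of class `neighborhood_graph`: `coefficients` (d x d, zero
#'   diagonal), `lambda`, `sweeps`, `converged`.
#' @references Meinshausen & Buhlmann (2006), Ann Statist 34(3):1436-1462.
#' @export
fit_neighborhood <- function(gamma, lambda, tol = 1e-4, max_iter = 1000L,
                             init = NULL) {
  gamma <- unclass(gamma)
  if (anyNA(gamma)) stopf("NaN/NA in covariance matrix")
  if (!isSymmetric(gamma, tol = 1e-8)) stopf("covariance matrix must be symmetric")
  if (lambda < 0) stopf("lambda must be >= 0")
  d <- nrow(gamma)
  if (is.null(init)) init <- matrix(0, d, d)
  res <- .cd_neighborhood(gamma, lambda, init, tol, as.integer(max_iter))
  if (!all(res$converged))
    warnf("coordinate descent did not converge for column(s): %s",
          paste(which(!res$converged), collapse = ", "))
  dimnames(res$coefficients) <- dimnames(gamma)
  structure(list(coefficients = res$coefficients, lambda = lambda,
                 sweeps = res$sweeps, converged = res$converged),
            class = "neighborhood_graph")
}

#' Fit the neighborhood lasso along a lambda path
#'
#' Fits from the most- to the least-regularized end, warm-starting each fit
#' at the previous solution.
#'
#' @inheritParams fit_neighborhood
#' @param lambdas Decreasing vector of lambda values ([build_lambda_path()]).
#' @return List of `neighborhood_graph` objects, one per lambda.
#' @export
fit_neighborhood_path <- function(gamma, lambdas, tol = 1e-4,
                                  max_iter = 1000L) {
  ord <- order(lambdas, decreasing = TRUE)
  fits <- vector("list", length(lambdas))
  init <- NULL
  for (i in ord) {
    fits[[i]] <- fit_neighborhood(gamma, lambdas[i], tol, max_iter, init)
    init <- fits[[i]]$coefficients
  }
  fits
}

#' Symmetrize a neighborhood graph with the OR rule
#'
#' An edge i-j is present when either protein's neighborhood regression
#' selected the other. The OR rule is the standard symmetrization for
#' neighborhood selection; under its asymptotic conditions the resulting
#' support matches the off-diagonal support of the precision matrix.
#'
#' @param g A `neighborhood_graph` (or a d x d coefficient matrix).
#' @param zero_tol Coefficients with absolute value `<= zero_tol` count as
#'   zero (default 0: soft-thresholding produces exact zeros).
#' @return Symmetric logical d x d adjacency matrix with zero diagonal.
#' @export
symmetrize_or <- function(g, zero_tol = 0) {
  cf <- if (inherits(g, "neighborhood_graph")) g$coefficients else unclass(g)
  adj <- (abs(cf) > zero_tol) | (abs(t(cf)) > zero_tol)
  diag(adj) <- FALSE
  adj
}
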