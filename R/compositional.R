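#' Add a pseudocount to raw abundances
#'
#' CF-MS abundances contain exact zeros (proteins not identified in a
#' fraction), which the log-ratio transform cannot handle. A pseudocount is
#' added to every entry of the raw matrix before closure.
#'
#' @param x An [elution_matrix] or numeric matrix of raw abundances.
#' @param pc Pseudocount, a positive real (default 1).
#' @return The matrix with `pc` added to every entry.
#' @export
add_pseudocount <- function(x, pc = 1) {
  if (!is.numeric(pc) || length(pc) != 1L || !is.finite(pc) || pc <= 0)
    stopf("pseudocount must be a single positive number")
  x + pc
}

#' Closure: normalize each fraction to a composition
#'
#' Each fraction (column) is divided by its total so that per-fraction
#' abundances are relative (sum to 1). MS quantitation is inherently
#' relative, so columns carry only compositional information; closure makes
#' that explicit before the CLR transform.
#'
#' @param x Numeric matrix with all entries > 0 (apply [add_pseudocount()]
#'   first).
#' @return Matrix of the same shape whose columns each sum to 1.
#' @export
closure_normalize <- function(x) {
  x <- unclass(x)
  if (any(x <= 0))
    stopf("closure requires strictly positive entries; apply add_pseudocount() first")
  sweep(x, 2L, colSums(x), "/")
}

#' Centered log-ratio (CLR) transform
#'
#' Maps each composition (fraction column) from the simplex to the zero-sum
#' hyperplane: `clr(x) = log(x / g(x))` with `g` the geometric mean of the
#' column. Covariances of CLR coordinates avoid the negative bias that
#' closure induces in naive covariances of compositions.
#'
#' @param comp Numeric matrix of strictly positive compositions
#'   (see [closure_normalize()]).
#' @return Matrix of CLR coordinates; every column sums to 0.
#' @export
clr_transform <- function(comp) {
  comp <- unclass(comp)
  if (any(comp <= 0)) stopf("CLR requires strictly positive entries")
  lx <- log(comp)
  sweep(lx, 2L, colMeans(lx), "-")
}

#' Nonparanormal (Gaussian copula) transform
#'
#' Replaces each protein's profile (row) by the Gaussian scores of its
#' shrunken empirical CDF: ranks are mapped to (0, 1), Winsorized at
#' `delta = 1 / (4 n^(1/4) sqrt(pi log n))`, passed through the standard
#' normal quantile function, and rescaled to unit sample variance. This
#' relaxes distributional assumptions of the subsequent regressions while
#' preserving within-row rank order. Constant rows map to all zeros.
#'
#' @param z Numeric matrix (proteins x fractions), typically CLR output.
#' @return Matrix of the same shape with Gaussianized rows.
#' @references Liu, Lafferty & Wasserman (2009), J Mach Learn Res 10:
#'   2295-2328 (the nonparanormal).
#' @export
nonparanormal_transform <- function(z) {
  z <- unclass(z)
  n <- ncol(z)
  if (n < 3L) stopf("nonparanormal transform needs at least 3 fractions")
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  out <- t(apply(z, 1L, function(row) {
    if (max(row) == min(row)) return(numeric(n))
    u <- rank(row, ties.method = "average") / (n + 1)
    u <- pmin(pmax(u, delta), 1 - delta)
    g <- stats::qnorm(u)
    g / stats::sd(g)
  }))
  dimnames(out) <- dimnames(z)
  out
}

#' Protein-protein covariance of transformed profiles
#'
#' Sample covariance (denominator `n - 1`) across fractions of the
#' CLR/copula-transformed matrix; the d x d result is the Gamma matrix that
#' the neighborhood-selection lasso operates on. In the sparse
#' high-dimensional regime this CLR covariance approximates the covariance
#' of the unobserved absolute abundances.
#'
#' @param z Numeric matrix (proteins x fractions), `n >= 2`.
#' @return Symmetric d x d covariance matrix with protein ids as dimnames.
#' @export
clr_covariance <- function(z) {
  z <- unclass(z)
  if (ncol(z) < 2L) stopf("covariance needs at least 2 fractions")
  g <- stats::cov(t(z))
  (g + t(g)) / 2
}

#' Full compositional transform pipeline
#'
#' Convenience wrapper: pseudocount -> closure -> CLR, optionally followed
#' (default) or preceded by the nonparanormal copula transform.
#'
#' @param x Raw [elution_matrix] (non-negative values).
#' @param pseudocount Pseudocount added before closure (default 1).
#' @param copula Apply the nonparanormal transform (default TRUE).
#' @param copula_order `"clr_then_copula"` (default) Gaussianizes the CLR
#'   rows; `"copula_then_clr"` Gaussianizes raw log-abundance ranks first and
#'   re-centers columns afterwards.
#' @return Transformed d x n matrix ready for [clr_covariance()].
#' @export
transform_profiles <- function(x, pseudocount = 1, copula = TRUE,
                               copula_order = c("clr_then_copula",
                                                "copula_then_clr")) {
  copula_order <- match.arg(copula_order)
  z <- clr_transform(closure_normalize(add_pseudocount(x, pseudocount)))
  if (!copula) return(z)
  if (copula_order == "clr_then_copula") {
    nonparanormal_transform(z)
  } else {
    g <- nonparanormal_transform(unclass(x))
    sweep(g, 2L, colMeans(g), "-")
  }
}
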