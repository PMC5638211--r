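#' End-to-end direct-contact prediction
#'
#' Runs the full workflow on a raw elution matrix: compositional transform
#' parameters are fixed inside [edge_frequencies()] (pseudocount, closure,
#' CLR, copula, covariance, node-wise lasso, OR rule, StARS subsampling),
#' a lambda is selected either by the StARS instability threshold
#' (`mode = "beta"`) or by benchmark AUPR (`mode = "aupr"`), stable edges
#' are ranked by contact probability, and predictions are restricted to
#' co-complex pairs when a catalog is given.
#'
#' @param x Raw [elution_matrix].
#' @param catalog Optional complex catalog ([read_complex_catalog()]); when
#'   supplied, predictions are filtered with [filter_cocomplex()].
#' @param benchmark Structure benchmark, required for `mode = "aupr"`.
#' @param mode Lambda selection: `"beta"` (unsupervised StARS threshold) or
#'   `"aupr"` (semi-supervised, maximizes benchmark AUPR).
#' @param beta Instability threshold for `mode = "beta"` (default 0.005).
#' @param N,K,min_ratio,seed,pseudocount,copula,tol,max_iter Passed to
#'   [edge_frequencies()].
#' @param min_subunits Passed to [filter_cocomplex()] (default 5).
#' @return List of class `contact_run`: `predictions`
#'   (`contact_predictions`), `profile` (`stability_profile`),
#'   `lambda` (selected), `mode`, `instability` (curve data.frame),
#'   `aupr_path` (per-lambda AUPR for `mode = "aupr"`, else NULL).
#' @export
predict_contacts <- function(x, catalog = NULL, benchmark = NULL,
                             mode = c("beta", "aupr"), beta = 0.005,
                             N = 20L, K = 30L, min_ratio = 0.01, seed = 1L,
                             pseudocount = 1, copula = TRUE,
                             tol = 1e-4, max_iter = 1000L,
                             min_subunits = 5L) {
  mode <- match.arg(mode)
  profile <- edge_frequencies(x, N = N, seed = seed, K = K,
                              min_ratio = min_ratio,
                              pseudocount = pseudocount, copula = copula,
                              tol = tol, max_iter = max_iter)
  aupr_path <- NULL
  if (mode == "beta") {
    lambda <- select_lambda_beta(profile, beta = beta)
  } else {
    if (is.null(benchmark)) stopf("mode = 'aupr' needs a benchmark")
    sel <- select_lambda_aupr(profile, benchmark)
    lambda <- sel$lambda
    aupr_path <- sel$aupr
  }
  preds <- rank_edges(profile, lambda)
  if (!is.null(catalog))
    preds <- filter_cocomplex(preds, catalog, min_subunits = min_subunits)
  structure(list(predictions = preds, profile = profile, lambda = lambda,
                 mode = mode, beta = if (mode == "beta") beta else NULL,
                 instability = instability_curve(profile),
                 aupr_path = aupr_path),
            class = "contact_run")
}

#' @export
print.contact_run <- function(x, ...) {
  cat(sprintf("contact_run: %d predictions at lambda = %.4g (%s selection)\n",
              nrow(x$predictions), x$lambda, x$mode))
  if (nrow(x$predictions)) {
    cat("top predictions:\n")
    print(utils::head(as.data.frame(x$predictions), 5L))
  }
  invisible(x)
}

#' Plot the StARS instability curve
#'
#' @param run A `contact_run` (or the data.frame from
#'   [instability_curve()]).
#' @param beta Threshold line to draw (default 0.005).
#' @export
plot_instability <- function(run, beta = 0.005) {
  curve <- if (inherits(run, "contact_run")) run$instability else run
  graphics::plot(curve$lambda, curve$monotone, log = "x", type = "b",
                 xlab = expression(lambda),
                 ylab = "monotonized instability", pch = 16, cex = 0.7)
  graphics::abline(h = beta, lty = 2, col = "grey50")
  if (inherits(run, "contact_run"))
    graphics::abline(v = run$lambda, lty = 3, col = "red3")
  invisible(curve)
}
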