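#' StARS subsample index sets
#'
#' Draws `N` subsamples of `b = floor(10 * sqrt(n))` fractions, without
#' replacement and independently across subsamples.
#'
#' @param n Number of fractions available.
#' @param N Number of subsamples (default 20).
#' @param seed Integer seed; the same seed reproduces the same index sets.
#' @param b Subsample size; defaults to `floor(10 * sqrt(n))`.
#' @return List of `N` integer vectors of length `b`.
#' @references Liu, Roeder & Wasserman (2010), NIPS 23 (StARS).
#' @export
subsample_indices <- function(n, N = 20L, seed = 1L, b = NULL) {
  if (is.null(b)) b <- floor(10 * sqrt(n))
  if (n <= b)
    stopf("n = %d fractions is too few for subsamples of size b = %d; reduce b",
          n, b)
  with_seed(seed, lapply(seq_len(N), function(i) sort(sample.int(n, b))))
}

#' Per-lambda edge frequencies under subsampling
#'
#' The StARS scoring stage: for each of `N` random fraction subsamples the
#' whole compositional pipeline (pseudocount, closure, CLR, copula,
#' covariance) is recomputed on the subsampled columns and the neighborhood
#' lasso is refit along the lambda path. Each edge's presence frequency
#' across subsamples, `P(lambda)_ij`, is recorded per lambda; these
#' frequencies are the contact probabilities of the final predictions.
#' Recomputing the transform inside every subsample (rather than subsetting
#' a precomputed covariance) keeps the subsampling statistics honest.
#'
#' @param x Raw [elution_matrix] (non-negative abundances).
#' @param lambdas Decreasing lambda path; if `NULL`, built from the
#'   full-data covariance via [build_lambda_path()] with `K` values.
#' @param N Number of subsamples (default 20).
#' @param seed Integer seed controlling the subsample draws.
#' @param K,min_ratio Path parameters when `lambdas` is `NULL`.
#' @param pseudocount,copula,copula_order Passed to [transform_profiles()].
#' @param tol,max_iter Passed to [fit_neighborhood()].
#' @param b Subsample size override (default `floor(10 * sqrt(n))`).
#' @return Object of class `stability_profile`: list with `lambdas`,
#'   `frequencies` (list of symmetric d x d matrices, entries in multiples
#'   of 1/N), `N`, `b`, `seed`, `protein_ids`.
#' @export
edge_frequencies <- function(x, lambdas = NULL, N = 20L, seed = 1L,
                             K = 30L, min_ratio = 0.01,
                             pseudocount = 1, copula = TRUE,
                             copula_order = "clr_then_copula",
                             tol = 1e-4, max_iter = 1000L, b = NULL) {
  xm <- unclass(x)
  d <- nrow(xm)
  n <- ncol(xm)
  if (is.null(lambdas)) {
    z_full <- transform_profiles(xm, pseudocount, copula, copula_order)
    lambdas <- build_lambda_path(lambda_max(clr_covariance(z_full)),
                                 K = K, min_ratio = min_ratio)
  }
  idx_sets <- subsample_indices(n, N = N, seed = seed, b = b)
  counts <- lapply(seq_along(lambdas), function(i) matrix(0L, d, d))
  for (s in seq_along(idx_sets)) {
    xs <- xm[, idx_sets[[s]], drop = FALSE]
    gam <- tryCatch(
      clr_covariance(transform_profiles(xs, pseudocount, copula, copula_order)),
      error = function(e) stopf("subsample %d: %s", s, conditionMessage(e)))
    fits <- fit_neighborhood_path(gam, lambdas, tol = tol, max_iter = max_iter)
    for (i in seq_along(lambdas)) {
      counts[[i]] <- counts[[i]] + symmetrize_or(fits[[i]])
    }
  }
  freqs <- lapply(counts, function(m) {
    p <- m / length(idx_sets)
    dimnames(p) <- list(rownames(xm), rownames(xm))
    p
  })
  structure(list(lambdas = lambdas, frequencies = freqs,
                 N = length(idx_sets), b = length(idx_sets[[1L]]),
                 seed = seed, protein_ids = rownames(xm)),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf("stability_profile: %d proteins, %d lambdas, N = %d subsamples of b = %d fractions\n",
              length(x$protein_ids), length(x$lambdas), x$N, x$b))
  invisible(x)
}

#' Graph instability along the lambda path
#'
#' For each lambda, total edge instability is the normalized sum of
#' Bernoulli variances of the edge frequencies,
#' `D(lambda) = sum_{i<j} 2 P_ij (1 - P_ij) / choose(d, 2)`, which lies in
#' `[0, 0.5]`. Because instability is not monotone in lambda, StARS uses the
#' monotonized curve (running maximum from the most-regularized end).
#'
#' @param profile A `stability_profile` from [edge_frequencies()].
#' @return data.frame with columns `lambda`, `instability`, `monotone`,
#'   ordered as the path (decreasing lambda).
#' @export
instability_curve <- function(profile) {
  d <- length(profile$protein_ids)
  npairs <- d * (d - 1) / 2
  inst <- vapply(profile$frequencies, function(p) {
    v <- 2 * p * (1 - p)
    sum(v[upper.tri(v)]) / npairs
  }, numeric(1L))
  ord <- order(profile$lambdas, decreasing = TRUE)
  mono <- numeric(length(inst))
  mono[ord] <- cummax(inst[ord])
  data.frame(lambda = profile$lambdas, instability = inst, monotone = mono)
}

#' Select lambda at a StARS instability threshold
#'
#' Returns the least-regularized (smallest) lambda whose monotonized
#' instability stays at or below `beta`: the densest graph whose edge set is
#' still stable under subsampling. The default `beta = 0.005` is a
#' conservative threshold (standard StARS uses 0.1).
#'
#' @param profile A `stability_profile`.
#' @param beta Instability threshold in (0, 0.5].
#' @return The selected lambda (scalar). If no lambda qualifies, the
#'   most-regularized lambda is returned with a warning.
#' @export
select_lambda_beta <- function(profile, beta = 0.005) {
  if (!is.numeric(beta) || beta <= 0 || beta > 0.5)
    stopf("beta must be in (0, 0.5]")
  curve <- instability_curve(profile)
  ok <- curve$lambda[curve$monotone <= beta]
  if (!length(ok)) {
    warnf("no lambda reaches instability <= %g; returning the most-regularized lambda",
          beta)
    return(max(curve$lambda))
  }
  min(ok)
}

#' Select lambda by benchmark AUPR
#'
#' The semi-supervised alternative to the beta threshold: for every lambda,
#' edges are ranked by their stability frequency and scored against a
#' structure-derived benchmark; the lambda maximizing the area under the
#' precision-recall curve is selected. Ties go to the more-regularized
#' (sparser) lambda.
#'
#' @param profile A `stability_profile`.
#' @param benchmark A structure benchmark (see [build_structure_benchmark()]).
#' @return List with `lambda`, `aupr` (the per-lambda AUPR vector), and
#'   `index` of the selected lambda.
#' @export
select_lambda_aupr <- function(profile, benchmark) {
  auprs <- vapply(seq_along(profile$lambdas), function(i) {
    preds <- rank_edges(profile, profile$lambdas[i])
    if (!nrow(preds)) return(NA_real_)
    scored <- data.frame(protein_a = preds$protein_a,
                         protein_b = preds$protein_b,
                         score = preds$probability)
    in_bench <- pair_key(scored$protein_a, scored$protein_b) %in%
      pair_key(benchmark$protein_a, benchmark$protein_b)
    if (!any(in_bench)) return(NA_real_)
    precision_recall_curve(scored, benchmark)$aupr
  }, numeric(1L))
  if (all(is.na(auprs)))
    stopf("no lambda produced predictions overlapping the benchmark")
  best <- max(auprs, na.rm = TRUE)
  cand <- which(!is.na(auprs) & auprs == best)
  sel <- cand[which.max(profile$lambdas[cand])]
  list(lambda = profile$lambdas[sel], aupr = auprs, index = sel)
}

#' Rank stable edges as contact predictions
#'
#' All pairs with positive frequency at the chosen lambda, sorted by
#' decreasing contact probability; ties are broken lexicographically by pair
#' id so output order is deterministic.
#'
#' @param profile A `stability_profile`.
#' @param lambda One value of `profile$lambdas`.
#' @return data.frame of class `contact_predictions` with columns
#'   `protein_a`, `protein_b`, `probability`.
#' @export
rank_edges <- function(profile, lambda) {
  i <- which(abs(profile$lambdas - lambda) <= 1e-12 * max(1, abs(lambda)))
  if (!length(i)) stopf("lambda %g is not on the path", lambda)
  p <- profile$frequencies[[i[1L]]]
  ut <- which(upper.tri(p) & p > 0, arr.ind = TRUE)
  ids <- profile$protein_ids
  out <- data.frame(protein_a = ids[ut[, 1L]], protein_b = ids[ut[, 2L]],
                    probability = p[ut], stringsAsFactors = FALSE)
  swap <- out$protein_a > out$protein_b
  tmp <- out$protein_a[swap]
  out$protein_a[swap] <- out$protein_b[swap]
  out$protein_b[swap] <- tmp
  out <- out[order(-out$probability, out$protein_a, out$protein_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda") <- profile$lambdas[i[1L]]
  class(out) <- c("contact_predictions", "data.frame")
  out
}

#' Restrict predictions to co-complex pairs
#'
#' Keeps a predicted pair only if both proteins co-occur in at least one
#' catalog complex with at least `min_subunits` unique members. Pairs whose
#' members are only ever in different complexes, or only share small
#' complexes, are dropped: co-complex membership in a large complex is what
#' licenses interpreting a conditional dependence as a physical contact.
#'
#' @param preds A `contact_predictions` data.frame ([rank_edges()]).
#' @param catalog Named list of complexes ([read_complex_catalog()]).
#' @param min_subunits Minimum unique complex size (default 5, i.e. larger
#'   than 4 subunits).
#' @return The filtered `contact_predictions`.
#' @export
filter_cocomplex <- function(preds, catalog, min_subunits = 5L) {
  big <- catalog[lengths(lapply(catalog, unique)) >= min_subunits]
  if (!length(big)) {
    out <- preds[0L, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  keep_keys <- unique(unlist(lapply(big, function(mem) {
    mem <- unique(mem)
    if (length(mem) < 2L) return(character(0L))
    cmb <- utils::combn(sort(mem), 2L)
    pair_key(cmb[1L, ], cmb[2L, ])
  })))
  keep <- pair_key(preds$protein_a, preds$protein_b) %in% keep_keys
  out <- preds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write contact predictions as TSV
#'
#' @param preds A `contact_predictions` data.frame.
#' @param path Output path.
#' @export
write_predictions <- function(preds, path) {
  utils::write.table(preds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
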