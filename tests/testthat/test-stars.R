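test_that("subsample sizes follow b = floor(10 * sqrt(n)) with boundaries", {
  sets <- subsample_indices(2989, N = 20, seed = 1)
  expect_length(sets, 20L)
  expect_true(all(lengths(sets) == 546L))   # floor(10 * sqrt(2989))
  expect_true(all(unlist(sets) >= 1 & unlist(sets) <= 2989))
  # without replacement within a subsample
  expect_true(all(vapply(sets, anyDuplicated, integer(1)) == 0L))
  # boundary: b = 100 needs n > 100
  expect_error(subsample_indices(100, seed = 1), "too few")
  expect_silent(subsample_indices(101, seed = 1))
  expect_true(all(lengths(subsample_indices(101, seed = 1)) == 100L))
  # determinism under a fixed seed
  expect_identical(subsample_indices(500, seed = 7),
                   subsample_indices(500, seed = 7))
})

test_that("edge frequencies are multiples of 1/N on a symmetric zero-diagonal matrix", {
  set.seed(31)
  tr <- synthetic_truth(n_complexes = 2, n_subunits = 4, n_experiments = 8,
                        fractions_per_experiment = 30, seed = 31)
  x <- generate_dataset(tr)$elution
  prof <- edge_frequencies(x, N = 10, seed = 5, K = 6)
  expect_s3_class(prof, "stability_profile")
  for (p in prof$frequencies) {
    expect_true(isSymmetric(p))
    expect_true(all(diag(p) == 0))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(p * 10, round(p * 10), tolerance = 1e-12)
  }
  # most-regularized end of the path is (near-)empty by construction
  expect_lte(sum(prof$frequencies[[1]]), sum(prof$frequencies[[length(prof$frequencies)]]))
  # bit-reproducible under the same seed
  prof2 <- edge_frequencies(x, N = 10, seed = 5, K = 6)
  expect_identical(prof$frequencies, prof2$frequencies)
})

test_that("a lambda above every subsample's lambda_max gives all-zero frequencies", {
  set.seed(32)
  tr <- synthetic_truth(n_complexes = 2, n_subunits = 3, n_experiments = 6,
                        fractions_per_experiment = 30, seed = 32)
  x <- generate_dataset(tr)$elution
  # CLR+copula entries have unit row variance, so covariance entries are
  # bounded by 1; lambda = 50 dominates any subsample's lambda_max
  prof <- edge_frequencies(x, lambdas = c(50, 25), N = 5, seed = 2)
  expect_true(all(prof$frequencies[[1]] == 0))
  expect_true(all(prof$frequencies[[2]] == 0))
})

test_that("instability is the normalized sum of edge-frequency variances", {
  mk_prof <- function(ps, d, lambdas = NULL) {
    # build a stability_profile by hand from upper-triangle frequencies
    freqs <- lapply(ps, function(pv) {
      p <- matrix(0, d, d)
      p[upper.tri(p)] <- pv
      p + t(p)
    })
    if (is.null(lambdas)) lambdas <- rev(seq_along(ps))
    structure(list(lambdas = lambdas, frequencies = freqs, N = 20, b = 10,
                   seed = 1, protein_ids = paste0("P", 1:d)),
              class = "stability_profile")
  }
  # all frequencies in {0, 1}: zero instability
  p0 <- mk_prof(list(c(0, 1, 1)), 3)
  expect_equal(instability_curve(p0)$instability, 0)
  # all frequencies 0.5: maximal instability 0.5
  p5 <- mk_prof(list(rep(0.5, 3)), 3)
  expect_equal(instability_curve(p5)$instability, 0.5)
  # single pair at P = 0.25 in a d = 2 problem: 2 * 0.25 * 0.75 = 0.375
  p25 <- mk_prof(list(0.25), 2)
  expect_equal(instability_curve(p25)$instability, 0.375)
  # monotonized curve is the running max from the most-regularized end
  pm <- mk_prof(list(c(0.05), c(0.5), c(0.1)), 2, lambdas = c(3, 2, 1))
  curve <- instability_curve(pm)
  expect_equal(curve$monotone, c(2 * 0.05 * 0.95, 0.5, 0.5))
  # beta selection: least-regularized lambda under the monotonized bound
  pb <- mk_prof(list(c(0.0005), c(0.001), c(0.3)), 2, lambdas = c(3, 2, 1))
  # instabilities: ~0.001, ~0.002, 0.42 -> lambda = 2 selected at beta = 0.005
  expect_equal(select_lambda_beta(pb, beta = 0.005), 2)
  # identically zero instability selects the smallest lambda on the path
  pz <- mk_prof(list(0, 1, 1), 2, lambdas = c(3, 2, 1))
  expect_equal(select_lambda_beta(pz), 1)
  # nothing qualifies: most-regularized lambda with a warning
  pw <- mk_prof(list(rep(0.5, 1), rep(0.5, 1)), 2, lambdas = c(2, 1))
  expect_warning(sel <- select_lambda_beta(pw, beta = 0.005), "most-regularized")
  expect_equal(sel, 2)
  expect_error(select_lambda_beta(p0, beta = 0), "beta")

  # instability always within [0, 0.5] for random frequency matrices
  set.seed(14)
  for (i in 1:20) {
    pr <- mk_prof(list(round(runif(6) * 20) / 20), 4)
    d <- instability_curve(pr)$instability
    expect_gte(d, 0)
    expect_lte(d, 0.5)
  }
})

test_that("edges rank by decreasing probability with deterministic ties", {
  prof <- structure(list(
    lambdas = c(2, 1),
    frequencies = list(
      {
        p <- matrix(0, 3, 3); p[1, 2] <- p[2, 1] <- 1.0
        p[1, 3] <- p[3, 1] <- 0.3; p
      },
      {
        p <- matrix(0, 3, 3); p[1, 2] <- p[2, 1] <- 0.4
        p[1, 3] <- p[3, 1] <- 0.4; p
      }),
    N = 20, b = 10, seed = 1, protein_ids = c("A", "B", "C")),
    class = "stability_profile")
  r <- rank_edges(prof, 2)
  expect_equal(r$protein_a, c("A", "A"))
  expect_equal(r$protein_b, c("B", "C"))
  expect_equal(r$probability, c(1.0, 0.3))
  # zero-frequency pair (B, C) is absent
  expect_false(any(r$protein_a == "B"))
  # ties break lexicographically by pair id
  r2 <- rank_edges(prof, 1)
  expect_equal(r2$protein_b, c("B", "C"))
  expect_error(rank_edges(prof, 0.123), "not on the path")
  # order is invariant to the input protein ordering
  prof_rev <- prof
  prof_rev$protein_ids <- rev(prof$protein_ids)
  prof_rev$frequencies <- lapply(prof$frequencies, function(p) p[3:1, 3:1])
  expect_equal(rank_edges(prof_rev, 2), rank_edges(prof, 2),
               ignore_attr = TRUE)
})

test_that("co-complex filtering keeps pairs sharing a large complex only", {
  preds <- structure(data.frame(
    protein_a = c("A", "A", "A", "F"),
    protein_b = c("B", "F", "X", "G"),
    probability = c(1, 0.9, 0.8, 0.7), stringsAsFactors = FALSE),
    class = c("contact_predictions", "data.frame"))
  catalog <- list(big = c("A", "B", "C", "D", "E"),
                  small = c("A", "F", "G"),
                  other = c("X", "Y", "Z", "W", "V"))
  kept <- filter_cocomplex(preds, catalog, min_subunits = 5)
  # (A,B) co-resident in a 5-subunit complex: kept
  expect_true(any(kept$protein_a == "A" & kept$protein_b == "B"))
  # (A,F) only share a 3-subunit complex: dropped
  expect_false(any(kept$protein_b == "F"))
  # (A,X) spans two complexes: dropped
  expect_false(any(kept$protein_b == "X"))
  expect_identical(nrow(kept), 1L)
  # lowering the size threshold admits the small complex
  kept3 <- filter_cocomplex(preds, catalog, min_subunits = 3)
  expect_true(any(kept3$protein_b == "F"))
})

test_that("AUPR-based lambda selection returns the argmax with sparse tie-break", {
  bench <- toy_benchmark(c("A", "A", "B"), c("B", "C", "C"),
                         c(TRUE, FALSE, TRUE))
  mk <- function(pab, pac, pbc) {
    p <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    p["A", "B"] <- p["B", "A"] <- pab
    p["A", "C"] <- p["C", "A"] <- pac
    p["B", "C"] <- p["C", "B"] <- pbc
    p
  }
  prof <- structure(list(
    lambdas = c(3, 2, 1),
    # lambda 3: perfect ranking; lambda 2: inverted; lambda 1: perfect again
    frequencies = list(mk(1, 0.2, 0.9), mk(0.2, 1, 0.1), mk(1, 0.2, 0.9)),
    N = 20, b = 10, seed = 1, protein_ids = c("A", "B", "C")),
    class = "stability_profile")
  sel <- select_lambda_aupr(prof, bench)
  expect_equal(sel$lambda, 3)   # tie between 3 and 1 resolved to larger lambda
  expect_equal(which.min(sel$aupr), 2L)
  # single-lambda path returns that lambda
  prof1 <- prof
  prof1$lambdas <- 2
  prof1$frequencies <- prof$frequencies[2]
  expect_equal(select_lambda_aupr(prof1, bench)$lambda, 2)
  # zero overlap with the benchmark errors
  bench_far <- toy_benchmark("Q", "R", TRUE)
  expect_error(select_lambda_aupr(prof, bench_far), "benchmark")
})
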