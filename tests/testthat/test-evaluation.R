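test_that("interface areas label contacts and small complexes are excluded", {
  tab <- data.frame(
    complex_id = c("cx1", "cx1", "cx1", "cx1", "cx1", "cx1",
                   "cx1", "cx1", "cx1", "cx1", "cx2"),
    protein_a = c("A", "A", "A", "A", "B", "B", "B", "C", "C", "D", "Q"),
    protein_b = c("B", "C", "D", "E", "C", "D", "E", "D", "E", "E", "R"),
    interface_area = c(150.2, 0, 0, 0, 88, 0, 0, 12.5, 0, 3.1, 500),
    stringsAsFactors = FALSE)
  bench <- build_structure_benchmark(tab, min_subunits = 5)
  expect_s3_class(bench, "structure_benchmark")
  # cx2 has only 2 subunits: excluded entirely
  expect_false(any(bench$complex_id == "cx2"))
  expect_equal(nrow(bench), 10L)
  expect_true(bench$label[bench$protein_a == "A" & bench$protein_b == "B"])
  expect_false(bench$label[bench$protein_a == "A" & bench$protein_b == "C"])
  expect_error(build_structure_benchmark(transform(tab, interface_area = -1)),
               "non-negative")
})

test_that("ortholog mapping drops unmapped subunits and can shrink complexes out", {
  tab <- data.frame(
    complex_id = "cx1",
    protein_a = c("y1", "y1", "y1", "y1", "y2", "y2", "y2", "y3", "y3", "y4"),
    protein_b = c("y2", "y3", "y4", "y5", "y3", "y4", "y5", "y4", "y5", "y5"),
    interface_area = c(10, 0, 0, 0, 10, 0, 0, 10, 0, 10),
    stringsAsFactors = FALSE)
  map <- data.frame(from_id = c("y1", "y2", "y3", "y4", "y5"),
                    to_id = c("H1", "H2", "H3", "H4", "H5"))
  full <- build_structure_benchmark(tab, ortholog_map = map, min_subunits = 5)
  expect_equal(sort(unique(c(full$protein_a, full$protein_b))),
               paste0("H", 1:5))
  # removing one mapping reduces the complex to 4 subunits: excluded
  map4 <- map[map$from_id != "y5", ]
  none <- build_structure_benchmark(tab, ortholog_map = map4, min_subunits = 5)
  expect_equal(nrow(none), 0L)
  # at min_subunits 4 the reduced complex survives without y5 pairs
  some <- build_structure_benchmark(tab, ortholog_map = map4, min_subunits = 4)
  expect_equal(nrow(some), 6L)
  expect_false(any(c(some$protein_a, some$protein_b) == "H5"))
})

test_that("precision-recall points and AUPR match the rank-enumeration example", {
  bench <- toy_benchmark(c("A", "A", "B"), c("B", "C", "C"),
                         c(TRUE, FALSE, TRUE))
  scores <- data.frame(protein_a = c("A", "A", "B"),
                       protein_b = c("B", "C", "C"),
                       score = c(3, 2, 1))   # ranked labels T, F, T
  pr <- precision_recall_curve(scores, bench)
  expect_equal(pr$curve$precision, c(1, 0.5, 2 / 3), tolerance = 1e-12)
  expect_equal(pr$curve$recall, c(0.5, 0.5, 1), tolerance = 1e-12)
  expect_equal(pr$aupr, (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(pr$baseline, 2 / 3)
  # recall is non-decreasing along the ranking
  expect_true(all(diff(pr$curve$recall) >= 0))
  # perfect ranking attains AUPR 1
  perfect <- data.frame(protein_a = c("A", "B", "A"),
                        protein_b = c("B", "C", "C"),
                        score = c(5, 4, 1))
  expect_equal(precision_recall_curve(perfect, bench)$aupr, 1)
  expect_error(precision_recall_curve(scores,
               toy_benchmark("A", "B", FALSE)), "no positive")
})

test_that("AUPR equals brute-force average precision on exhaustive small rankings", {
  ids <- paste0("P", 1:9)
  for (len in c(1:4, 8)) {
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), len))
    for (r in seq_len(nrow(patterns))) {
      labels <- as.logical(patterns[r, ])
      if (!any(labels)) next
      bench <- toy_benchmark(ids[seq_len(len)], ids[seq_len(len) + 1],
                             labels)
      scores <- data.frame(protein_a = ids[seq_len(len)],
                           protein_b = ids[seq_len(len) + 1],
                           score = len:1)
      pr <- precision_recall_curve(scores, bench)
      expect_equal(pr$aupr, naive_average_precision(labels),
                   tolerance = 1e-12)
    }
  }
})

test_that("tied scores are scored as blocks, independent of input order", {
  ids <- paste0("P", 1:9)
  tie_patterns <- list(
    c(1, 1, 1, 1),            # one big block
    c(2, 2, 1, 1),            # two blocks
    c(3, 2, 2, 1),            # middle tie
    c(2, 1, 1, 1)             # trailing tie
  )
  set.seed(4)
  for (sc in tie_patterns) {
    for (rep in 1:5) {
      labels <- sample(c(TRUE, FALSE), 4, replace = TRUE)
      if (!any(labels)) labels[1] <- TRUE
      bench <- toy_benchmark(ids[1:4], ids[2:5 + 4], labels)
      perm <- sample(4)
      scores <- data.frame(protein_a = ids[1:4][perm],
                           protein_b = ids[2:5 + 4][perm],
                           score = sc[perm])
      pr <- precision_recall_curve(scores, bench)
      expect_equal(pr$aupr, naive_average_precision(labels, scores = sc),
                   tolerance = 1e-12)
    }
  }
  # all pairs tied: AUPR equals positives/total
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  bench <- toy_benchmark(ids[1:4], ids[6:9], labels)
  scores <- data.frame(protein_a = ids[1:4], protein_b = ids[6:9], score = 0)
  expect_equal(precision_recall_curve(scores, bench)$aupr, 0.5)
})

test_that("AUPR is invariant to monotone transforms and penalizes unscored positives", {
  bench <- toy_benchmark(c("A", "A", "B", "C"), c("B", "C", "C", "D"),
                         c(TRUE, FALSE, TRUE, TRUE))
  scores <- data.frame(protein_a = c("A", "A", "B"),
                       protein_b = c("B", "C", "C"),
                       score = c(0.9, 0.5, 0.2))
  pr <- precision_recall_curve(scores, bench)
  mono <- transform(scores, score = exp(10 * score))
  expect_equal(precision_recall_curve(mono, bench)$aupr, pr$aupr)
  # (C, D) is a positive with no score: recall never reaches 1
  expect_lt(max(pr$curve$recall), 1)
  expect_equal(pr$aupr, (1 + 2 / 3) / 3, tolerance = 1e-12)
  # scores outside the benchmark are ignored
  extra <- rbind(scores, data.frame(protein_a = "Z", protein_b = "W",
                                    score = 100))
  expect_equal(precision_recall_curve(extra, bench)$aupr, pr$aupr)
})

test_that("per-complex AUPR partitions the benchmark", {
  b1 <- toy_benchmark(c("A", "A"), c("B", "C"), c(TRUE, FALSE), "cx1")
  b2 <- toy_benchmark(c("X", "X"), c("Y", "Z"), c(TRUE, FALSE), "cx2")
  b3 <- toy_benchmark("M", "N", FALSE, "cx3")   # no positives: skipped
  bench <- rbind(b1, b2, b3)
  scores <- data.frame(protein_a = c("A", "A", "X", "X", "M"),
                       protein_b = c("B", "C", "Y", "Z", "N"),
                       score = c(1, 0.5, 0.2, 0.9, 1))
  pc <- per_complex_aupr(scores, bench)
  expect_equal(pc[["cx1"]], 1)        # its positive ranked first
  expect_equal(pc[["cx2"]], 0.5)      # its positive ranked second
  expect_identical(attr(pc, "skipped"), "cx3")
  # complexes are independent: altering cx2 scores leaves cx1 unchanged
  scores2 <- transform(scores, score = ifelse(protein_a == "X", 0, score))
  expect_equal(per_complex_aupr(scores2, bench)[["cx1"]], pc[["cx1"]])
})

test_that("crosslink overlap z-scores follow the permutation null", {
  # arithmetic of the z statistic
  preds <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "C"))
  xl <- data.frame(protein_a = c("A", "C", "A"), protein_b = c("B", "D", "D"))
  res <- crosslink_overlap_zscore(preds, xl, trials = 200, seed = 3)
  expect_s3_class(res, "enrichment_result")
  expect_equal(res$observed, 1)
  expect_equal(res$trials, 200)
  expect_false(res$degenerate)
  expect_equal(res$z, (res$observed - res$null_mean) / res$null_sd)
  # self-overlap is the maximal achievable observed count
  self <- crosslink_overlap_zscore(xl, xl, trials = 50, seed = 3)
  expect_equal(self$observed, nrow(xl))
  expect_gte(self$z, res$z)
  # determinism under seed
  res2 <- crosslink_overlap_zscore(preds, xl, trials = 200, seed = 3)
  expect_identical(res$z, res2$z)
  expect_error(crosslink_overlap_zscore(preds[0, ], xl), "predictions")
})
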