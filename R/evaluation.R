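#' Build a structure-derived contact benchmark
#'
#' Labels within-complex protein pairs by their buried interface area in a
#' solved structure: pairs with interfacial area > 0 square Angstroms are
#' contacting (positives), pairs with no interface are non-contacting
#' (negatives). Complexes retaining fewer than `min_subunits` mapped members
#' are excluded entirely (small complexes make contacts guessable at
#' random); pairs spanning two complexes are never emitted.
#'
#' @param interface_table data.frame with columns `complex_id`, `protein_a`,
#'   `protein_b`, `interface_area` (in square Angstroms, >= 0), and
#'   optionally `split` (e.g. "tuning" / "holdout").
#' @param ortholog_map Optional two-column data.frame (`from_id`, `to_id`)
#'   applied to both protein columns before pairing; ids absent from the map
#'   are dropped together with their pairs (no ortholog means the subunit is
#'   not considered).
#' @param min_subunits Minimum unique mapped subunits per complex
#'   (default 5).
#' @return data.frame of class `structure_benchmark` with columns
#'   `complex_id`, `protein_a`, `protein_b`, `interface_area`, `label`
#'   (logical, TRUE = contacting), `split`.
#' @export
build_structure_benchmark <- function(interface_table, ortholog_map = NULL,
                                      min_subunits = 5L) {
  req <- c("complex_id", "protein_a", "protein_b", "interface_area")
  missing <- setdiff(req, names(interface_table))
  if (length(missing))
    stopf("interface table lacks column(s): %s", paste(missing, collapse = ", "))
  df <- interface_table
  df$interface_area <- as.numeric(df$interface_area)
  if (anyNA(df$interface_area) || any(df$interface_area < 0))
    stopf("interface areas must be non-negative numbers")
  if (is.null(df$split)) df$split <- NA_character_
  if (!is.null(ortholog_map)) {
    known <- as.character(ortholog_map[[1L]])
    mapped_a <- df$protein_a %in% known
    mapped_b <- df$protein_b %in% known
    df <- df[mapped_a & mapped_b, , drop = FALSE]
    df$protein_a <- apply_id_map(df$protein_a, ortholog_map)
    df$protein_b <- apply_id_map(df$protein_b, ortholog_map)
  }
  df <- df[df$protein_a != df$protein_b, , drop = FALSE]
  pa <- pmin(df$protein_a, df$protein_b)
  pb <- pmax(df$protein_a, df$protein_b)
  df$protein_a <- pa
  df$protein_b <- pb
  df <- df[!duplicated(paste(df$complex_id, pair_key(pa, pb))), , drop = FALSE]
  sizes <- tapply(c(df$protein_a, df$protein_b),
                  c(df$complex_id, df$complex_id),
                  function(v) length(unique(v)))
  keep <- df$complex_id %in% names(sizes)[sizes >= min_subunits]
  df <- df[keep, c("complex_id", "protein_a", "protein_b", "interface_area",
                   "split"), drop = FALSE]
  df$label <- df$interface_area > 0
  rownames(df) <- NULL
  class(df) <- c("structure_benchmark", "data.frame")
  df
}

#' Read / write a structure benchmark TSV
#'
#' Columns: `complex_id`, `protein_a`, `protein_b`, `interface_area`, and
#' optionally `split`; the contact label is recomputed from the interface
#' area (> 0 = contacting).
#'
#' @param path TSV path.
#' @param min_subunits Passed to [build_structure_benchmark()].
#' @export
read_structure_benchmark <- function(path, min_subunits = 5L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  build_structure_benchmark(df, min_subunits = min_subunits)
}

#' @rdname read_structure_benchmark
#' @param bench A `structure_benchmark`.
#' @export
write_structure_benchmark <- function(bench, path) {
  utils::write.table(as.data.frame(bench), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Precision-recall curve and AUPR against a benchmark
#'
#' Scored pairs are restricted to benchmark pairs and swept in order of
#' decreasing score; at each rank precision = TP/(TP+FP) and recall =
#' TP/(TP+FN). Benchmark pairs that never received a score count as false
#' negatives at every cutoff (dropping them would inflate recall). AUPR is
#' average precision: the mean, over all positives, of the precision at the
#' rank where each positive is retrieved; ties form blocks and every member
#' of a block is assigned the block-end precision, making the result
#' independent of within-tie order.
#'
#' @param scores data.frame with columns `protein_a`, `protein_b`, `score`.
#' @param benchmark A `structure_benchmark` (or data.frame with
#'   `protein_a`, `protein_b`, `label`).
#' @return Object of class `pr_result`: list with `curve` (data.frame
#'   `rank`, `score`, `tp`, `fp`, `precision`, `recall`, one row per tie
#'   block), `aupr`, `n_pos`, `n_neg`, `n_scored`, `baseline`
#'   (positives / total benchmark pairs).
#' @export
precision_recall_curve <- function(scores, benchmark) {
  lab <- benchmark_labels(benchmark)
  n_pos <- sum(lab$label)
  if (n_pos == 0L) stopf("benchmark contains no positive pairs")
  key_s <- pair_key(scores$protein_a, scores$protein_b)
  m <- match(lab$key, key_s)
  scored <- !is.na(m)
  sc <- scores$score[m[scored]]
  y <- lab$label[scored]
  ord <- order(-sc)
  sc <- sc[ord]
  y <- y[ord]
  ap <- 0
  curve <- NULL
  if (length(sc)) {
    block_last <- c(sc[-1L] != sc[-length(sc)], TRUE)
    cum_tp <- cumsum(y)
    cum_fp <- cumsum(!y)
    tp <- cum_tp[block_last]
    fp <- cum_fp[block_last]
    prec <- tp / (tp + fp)
    rec <- tp / n_pos
    tp_in_block <- diff(c(0, tp))
    ap <- sum(prec * tp_in_block) / n_pos
    curve <- data.frame(rank = which(block_last), score = sc[block_last],
                        tp = tp, fp = fp, precision = prec, recall = rec)
  }
  structure(list(curve = curve, aupr = ap, n_pos = n_pos,
                 n_neg = sum(!lab$label), n_scored = sum(scored),
                 baseline = n_pos / nrow(lab)),
            class = "pr_result")
}

benchmark_labels <- function(benchmark) {
  lab <- if (is.logical(benchmark$label)) benchmark$label
         else benchmark$label %in% c("contacting", "TRUE", "true", "1")
  key <- pair_key(benchmark$protein_a, benchmark$protein_b)
  dup <- duplicated(key)
  data.frame(key = key[!dup], label = lab[!dup], stringsAsFactors = FALSE)
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("pr_result: AUPR = %.4f (%d positives, %d negatives, %d scored; random baseline %.4f)\n",
              x$aupr, x$n_pos, x$n_neg, x$n_scored, x$baseline))
  invisible(x)
}

#' Plot a precision-recall curve
#'
#' @param x A `pr_result`.
#' @param add Add to an existing plot.
#' @param col Line color.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pr_result <- function(x, add = FALSE, col = "black", ...) {
  r <- c(0, x$curve$recall)
  p <- c(if (nrow(x$curve)) x$curve$precision[1L] else 1, x$curve$precision)
  if (!add) {
    graphics::plot(r, p, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "Recall", ylab = "Precision", col = col, ...)
    graphics::abline(h = x$baseline, lty = 2, col = "grey50")
  } else {
    graphics::lines(r, p, type = "s", col = col, ...)
  }
  invisible(x)
}

#' Per-complex AUPR
#'
#' Evaluates each benchmark complex on its own pairs only; complexes without
#' a positive pair are skipped (reported in the `skipped` attribute).
#'
#' @inheritParams precision_recall_curve
#' @return Named numeric vector, complex id -> AUPR.
#' @export
per_complex_aupr <- function(scores, benchmark) {
  split_bench <- split(as.data.frame(benchmark), benchmark$complex_id)
  lab <- vapply(split_bench, function(b) sum(benchmark_labels(b)$label) > 0,
                logical(1L))
  res <- vapply(split_bench[lab], function(b) {
    precision_recall_curve(scores, b)$aupr
  }, numeric(1L))
  structure(res, skipped = names(split_bench)[!lab])
}

#' Crosslink-overlap enrichment z-score
#'
#' Tests whether contact predictions overlap an independently measured set
#' of inter-protein crosslinks more than chance. The observed overlap is the
#' number of predicted pairs also crosslinked; the null draws, in each of
#' `trials` trials, the same number of distinct random pairs from the
#' proteins of the crosslinking dataset and records their overlap with the
#' predictions. `z = (observed - null mean) / null sd`.
#'
#' @param preds `contact_predictions` (or data.frame with `protein_a`,
#'   `protein_b`).
#' @param crosslinks data.frame of crosslinked pairs
#'   ([read_crosslink_pairs()]).
#' @param trials Number of null trials (default 1000).
#' @param seed Integer seed for the null draws.
#' @return Object of class `enrichment_result`: list with `observed`,
#'   `null_mean`, `null_sd`, `z` (NA with `degenerate = TRUE` when the null
#'   sd is 0), `trials`, `seed`.
#' @export
crosslink_overlap_zscore <- function(preds, crosslinks, trials = 1000L,
                                     seed = 1L) {
  if (!nrow(preds)) stopf("no predictions supplied")
  xl <- canonical_pairs(crosslinks$protein_a, crosslinks$protein_b)
  if (!nrow(xl)) stopf("crosslink set is empty")
  pred_keys <- unique(pair_key(preds$protein_a, preds$protein_b))
  xl_keys <- pair_key(xl$protein_a, xl$protein_b)
  observed <- sum(xl_keys %in% pred_keys)
  universe <- sort(unique(c(xl$protein_a, xl$protein_b)))
  u <- length(universe)
  n_pairs_univ <- choose(u, 2)
  m <- nrow(xl)
  if (m > n_pairs_univ) stopf("more crosslink pairs than pairs in the universe")
  null_overlap <- with_seed(seed, {
    if (n_pairs_univ <= 2e6) {
      cmb <- utils::combn(universe, 2L)
      all_keys <- pair_key(cmb[1L, ], cmb[2L, ])
      in_pred <- all_keys %in% pred_keys
      vapply(seq_len(trials),
             function(t) sum(in_pred[sample.int(n_pairs_univ, m)]),
             numeric(1L))
    } else {
      vapply(seq_len(trials), function(t) {
        keys <- character(0L)
        while (length(keys) < m) {
          a <- universe[sample.int(u, 2L * (m - length(keys)), replace = TRUE)]
          b <- universe[sample.int(u, 2L * (m - length(keys)), replace = TRUE)]
          ok <- a != b
          keys <- unique(c(keys, pair_key(a[ok], b[ok])))
        }
        sum(keys[seq_len(m)] %in% pred_keys)
      }, numeric(1L))
    }
  })
  mu <- mean(null_overlap)
  sd0 <- stats::sd(null_overlap)
  degenerate <- !is.finite(sd0) || sd0 == 0
  structure(list(observed = observed, null_mean = mu, null_sd = sd0,
                 z = if (degenerate) NA_real_ else (observed - mu) / sd0,
                 degenerate = degenerate, trials = trials, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: observed overlap %d, null %.2f +/- %.2f over %d trials -> z = %s\n",
              x$observed, x$null_mean, x$null_sd, x$trials,
              if (x$degenerate) "undefined (null sd = 0)" else sprintf("%.2f", x$z)))
  invisible(x)
}
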