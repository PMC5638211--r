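# Shared fixtures, built in code at test time.

# Small elution matrix with named axes.
toy_elution <- function(vals = NULL, experiment = "e1") {
  if (is.null(vals))
    vals <- matrix(c(0, 2, 4, 1,
                     5, 0, 2, 3,
                     1, 1, 0, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("P1", "P2", "P3"), paste0("f", 1:4)))
  elution_matrix(vals, experiment)
}

write_toy_elution_tsv <- function(path, rows) {
  # rows: named list protein_id -> character vector of cell strings
  header <- paste(c("protein_id", paste0("f", seq_along(rows[[1L]]))),
                  collapse = "\t")
  body <- vapply(names(rows), function(id) {
    paste(c(id, rows[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  path
}

# Sample n draws from N(0, Sigma) via the Cholesky factor: the independent
# route used to create Gaussian data with a known precision matrix.
rmvn_chol <- function(n, sigma) {
  d <- ncol(sigma)
  z <- matrix(rnorm(n * d), n, d)
  z %*% chol(sigma)
}

# Off-diagonal support of a precision matrix via direct inversion of the
# covariance and thresholding of partial correlations -- the oracle route,
# never the neighborhood lasso.
partial_correlation_support <- function(sigma, tol = 1e-8) {
  theta <- solve(sigma)
  pc <- -theta / sqrt(diag(theta) %o% diag(theta))
  diag(pc) <- 0
  abs(pc) > tol
}

# Chain / star / empty precision matrices on d = 4 nodes, diagonally
# dominant hence positive definite.
precision_chain4 <- function(rho = 0.45) {
  th <- diag(4)
  for (i in 1:3) th[i, i + 1] <- th[i + 1, i] <- -rho
  th
}
precision_star4 <- function(rho = 0.4) {
  th <- diag(4)
  th[1, 2:4] <- th[2:4, 1] <- -rho
  th
}
precision_empty4 <- function() diag(4)

# Naive average precision on a ranked label vector with optional tied
# scores: loops over tie blocks, assigns the block-end precision to every
# positive in the block. Independent of the package's vectorized path.
naive_average_precision <- function(labels, scores = NULL, n_pos_total = NULL) {
  if (is.null(scores)) scores <- rev(seq_along(labels))
  ord <- order(-scores)
  labels <- labels[ord]
  scores <- scores[ord]
  if (is.null(n_pos_total)) n_pos_total <- sum(labels)
  if (n_pos_total == 0) stop("no positives")
  ap <- 0
  tp <- 0
  fp <- 0
  i <- 1
  while (i <= length(labels)) {
    j <- i
    while (j < length(labels) && scores[j + 1] == scores[i]) j <- j + 1
    block_tp <- sum(labels[i:j])
    tp <- tp + block_tp
    fp <- fp + (j - i + 1 - block_tp)
    ap <- ap + block_tp * tp / (tp + fp)
    i <- j + 1
  }
  ap / n_pos_total
}

# Tiny benchmark data.frame from parallel vectors.
toy_benchmark <- function(a, b, label, complex_id = "cx1") {
  data.frame(complex_id = complex_id, protein_a = a, protein_b = b,
             interface_area = ifelse(label, 100, 0), label = label,
             stringsAsFactors = FALSE)
}
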