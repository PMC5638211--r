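#' Count theoretical tryptic peptides
#'
#' In-silico trypsin digest of an amino-acid sequence: cleave C-terminal to
#' K or R except when the next residue is P; no missed cleavages. The count
#' of resulting fragments (of length `>= min_len`) normalizes MS abundances
#' for protein detectability.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet (X is
#'   tolerated and never a cleavage site).
#' @param min_len Minimum fragment length to count (default 1).
#' @return Integer fragment count (at least 1 when any fragment passes
#'   `min_len`).
#' @examples
#' theoretical_tryptic_peptides("MKRAPK")  # MK | R | APK -> 3
#' theoretical_tryptic_peptides("KPK")     # KP suppressed -> 1
#' @export
theoretical_tryptic_peptides <- function(sequence, min_len = 1L) {
  sequence <- toupper(gsub("[[:space:]*]", "", sequence))
  if (!nchar(sequence)) stopf("empty sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))
    stopf("sequence contains characters outside the amino-acid alphabet")
  aa <- strsplit(sequence, "")[[1L]]
  len <- length(aa)
  cut_after <- aa %in% c("K", "R") &
    c(aa[-1L], "") != "P" & seq_len(len) < len
  starts <- c(1L, which(cut_after) + 1L)
  ends <- c(which(cut_after), len)
  sum(ends - starts + 1L >= min_len)
}

#' Peptide counts from a FASTA file
#'
#' Reads protein sequences and applies [theoretical_tryptic_peptides()] to
#' each. FASTA headers are truncated at the first whitespace to form ids.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param min_len Passed to [theoretical_tryptic_peptides()].
#' @return Named integer vector of peptide counts.
#' @export
peptide_counts_from_fasta <- function(path, min_len = 1L) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stopf("peptide_counts_from_fasta() requires the Biostrings package")
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("[[:space:]].*$", "", names(seqs))
  stats::setNames(
    vapply(as.character(seqs), theoretical_tryptic_peptides, integer(1L),
           min_len = min_len, USE.NAMES = FALSE),
    ids)
}

#' Normalize profiles by theoretical peptide count
#'
#' Divides each protein's elution profile by its number of theoretical
#' tryptic peptides, correcting for the higher spectral counts of long,
#' peptide-rich proteins.
#'
#' @param x An [elution_matrix] or numeric matrix.
#' @param counts Named numeric vector, protein id -> peptide count (>= 1).
#' @return The row-normalized matrix.
#' @export
peptide_normalize <- function(x, counts) {
  missing <- setdiff(rownames(x), names(counts))
  if (length(missing))
    stopf("no peptide count for protein(s): %s", paste(missing, collapse = ", "))
  cnt <- counts[rownames(x)]
  if (any(cnt < 1)) stopf("peptide counts must be >= 1")
  unclass(x) / cnt
}

#' Fraction-wise z-scores
#'
#' Standardizes each fraction (column) to mean 0 and unit sample standard
#' deviation (denominator `d - 1`), putting fractions with different total
#' MS signal on a common scale. Constant columns become all-zero, with a
#' warning.
#'
#' @param x Numeric matrix (proteins x fractions).
#' @return Column-standardized matrix.
#' @export
fractionwise_zscore <- function(x) {
  x <- unclass(x)
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  degenerate <- !is.finite(sd) | sd == 0
  if (any(degenerate)) {
    warnf("%d constant fraction(s) standardized to zero", sum(degenerate))
    sd[degenerate] <- 1
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
  z[, degenerate] <- 0
  z
}

#' Pairwise Pearson correlations between protein profiles
#'
#' Pearson correlation across fractions for every unordered protein pair.
#' Rows without variance have undefined correlations; these are recorded as
#' 0 so downstream rankings remain total, and flagged via the
#' `zero_variance` attribute.
#'
#' @param z Numeric matrix (proteins x fractions), typically the output of
#'   [fractionwise_zscore()].
#' @return Symmetric d x d correlation matrix with unit diagonal where
#'   defined.
#' @export
pairwise_pearson <- function(z) {
  z <- unclass(z)
  sds <- apply(z, 1L, stats::sd)
  flat <- !is.finite(sds) | sds == 0
  r <- suppressWarnings(stats::cor(t(z)))
  r[flat, ] <- 0
  r[, flat] <- 0
  dg <- rep(1, nrow(r))
  dg[flat] <- 0
  diag(r) <- dg
  attr(r, "zero_variance") <- rownames(z)[flat]
  r
}

#' Pearson co-elution baseline
#'
#' The comparison method: optional tryptic-peptide normalization, then
#' fraction-wise z-scoring, then pairwise Pearson correlation. Returns the
#' full correlation matrix; use [correlation_edges()] for a ranked pair
#' list comparable to [rank_edges()] output.
#'
#' @param x Raw [elution_matrix].
#' @param counts Optional named peptide-count vector
#'   ([peptide_counts_from_fasta()]); skipped when `NULL`.
#' @return Symmetric correlation matrix.
#' @export
correlation_baseline <- function(x, counts = NULL) {
  m <- unclass(x)
  if (!is.null(counts)) m <- peptide_normalize(m, counts)
  pairwise_pearson(fractionwise_zscore(m))
}

#' Ranked pair list from a correlation matrix
#'
#' @param r Symmetric correlation matrix with dimnames.
#' @return data.frame `protein_a`, `protein_b`, `score`, sorted by
#'   decreasing correlation (ties broken lexicographically).
#' @export
correlation_edges <- function(r) {
  ids <- rownames(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(protein_a = pmin(ids[ut[, 1L]], ids[ut[, 2L]]),
                    protein_b = pmax(ids[ut[, 1L]], ids[ut[, 2L]]),
                    score = r[ut], stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
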