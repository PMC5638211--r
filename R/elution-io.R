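#' Construct an elution matrix
#'
#' An elution matrix holds the protein x fraction abundance data of one or
#' more CF-MS experiments: `d` proteins in rows, `n` collected fractions in
#' columns, non-negative quantitation values with absent identifications
#' stored as exact 0. Each fraction carries the label of the fractionation
#' experiment it came from.
#'
#' @param values Numeric matrix (proteins x fractions) with unique rownames
#'   (protein ids) and unique colnames (fraction ids); all values must be
#'   finite and >= 0.
#' @param experiments Character vector of experiment labels, one per column.
#'   A single label is recycled across all fractions.
#' @return An object of class `elution_matrix`: the numeric matrix with an
#'   `experiments` attribute.
#' @examples
#' m <- matrix(c(0, 2, 1, 0, 3, 5), nrow = 2,
#'             dimnames = list(c("P1", "P2"), c("f1", "f2", "f3")))
#' x <- elution_matrix(m, "exp1")
#' experiment_of_fraction(x)
#' @export
elution_matrix <- function(values, experiments) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must have protein ids as rownames and fraction ids as colnames")
  if (length(experiments) == 1L) experiments <- rep(experiments, ncol(values))
  if (length(experiments) != ncol(values))
    stopf("`experiments` must have one label per fraction (got %d for %d fractions)",
          length(experiments), ncol(values))
  x <- structure(values, experiments = as.character(experiments),
                 class = c("elution_matrix", "matrix", "array"))
  validate_elution_matrix(x)
  x
}

validate_elution_matrix <- function(x) {
  if (nrow(x) == 0L || ncol(x) == 0L) stopf("elution matrix is empty")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stopf("duplicate protein id(s): %s", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stopf("duplicate fraction ids")
  if (anyNA(x) || any(!is.finite(x)))
    stopf("elution values must be finite (non-numeric or NA cell found)")
  if (any(x < 0)) stopf("elution values must be non-negative")
  invisible(x)
}

#' @rdname elution_matrix
#' @param x An `elution_matrix`.
#' @export
experiment_of_fraction <- function(x) {
  stats::setNames(attr(x, "experiments"), colnames(x))
}

#' @export
print.elution_matrix <- function(x, ...) {
  cat(sprintf("elution_matrix: %d proteins x %d fractions (%d experiment(s))\n",
              nrow(x), ncol(x), length(unique(attr(x, "experiments")))))
  cat(sprintf("nonzero values: %d (%.1f%%)\n", sum(x > 0),
              100 * mean(x > 0)))
  invisible(x)
}

#' Read a CF-MS elution table
#'
#' Reads a wide tab-separated table: first column `protein_id`, remaining
#' columns fraction abundances. Blank cells are read as 0 (a protein not
#' identified in a fraction). Values must be numeric and non-negative.
#'
#' @param path Path to the TSV file.
#' @param experiment Experiment label attached to every fraction of the file.
#' @param id_map Optional two-column data.frame (`from_id`, `to_id`) applied
#'   to protein ids at read time (e.g. an ortholog mapping); unmapped ids are
#'   kept as-is.
#' @return An [elution_matrix].
#' @seealso [write_elution_table()], [concat_experiments()]
#' @export
read_elution_table <- function(path, experiment, id_map = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stopf("empty elution table: %s", path)
  ids <- df[[1L]]
  if (!is.null(id_map)) ids <- apply_id_map(ids, id_map)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicate protein id(s) in %s: %s", path, paste(dup, collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[raw == "" | is.na(raw)] <- "0"
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(ids, colnames(raw))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stopf("non-numeric cell at protein '%s', fraction '%s'",
          ids[bad[1L]], colnames(vals)[bad[2L]])
  }
  if (any(vals < 0)) stopf("negative abundance value in %s", path)
  elution_matrix(vals, experiment)
}

apply_id_map <- function(ids, id_map) {
  if (ncol(id_map) < 2L) stopf("id map needs two columns (from_id, to_id)")
  m <- match(ids, as.character(id_map[[1L]]))
  hit <- !is.na(m)
  ids[hit] <- as.character(id_map[[2L]])[m[hit]]
  ids
}

#' @rdname read_elution_table
#' @param x An [elution_matrix] to write.
#' @export
write_elution_table <- function(x, path) {
  df <- data.frame(protein_id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenate fractionation experiments column-wise
#'
#' Builds the joint analysis matrix from per-experiment elution matrices:
#' proteins are the union over experiments, fractions are concatenated in
#' input order, and a protein absent from an experiment is zero-filled in
#' that experiment's fractions (not identified = 0). Fraction ids are made
#' unique by prefixing the experiment label.
#'
#' @param matrices A list of [elution_matrix] objects with distinct
#'   experiment labels.
#' @return A single [elution_matrix].
#' @export
concat_experiments <- function(matrices) {
  if (!length(matrices)) stopf("need at least one elution matrix")
  labs <- lapply(matrices, function(m) unique(attr(m, "experiments")))
  flat <- unlist(labs)
  if (anyDuplicated(flat))
    stopf("clashing experiment label(s): %s",
          paste(unique(flat[duplicated(flat)]), collapse = ", "))
  proteins <- unique(unlist(lapply(matrices, rownames)))
  blocks <- lapply(matrices, function(m) {
    out <- matrix(0, length(proteins), ncol(m),
                  dimnames = list(proteins,
                                  paste(attr(m, "experiments"), colnames(m), sep = ".")))
    out[rownames(m), ] <- m
    out
  })
  vals <- do.call(cbind, blocks)
  exps <- unlist(lapply(matrices, attr, "experiments"))
  elution_matrix(vals, exps)
}

#' Read a complex catalog
#'
#' One row per complex: `complex_id<TAB>member ids` with members separated by
#' spaces. Memberships are de-duplicated; complexes with fewer than two
#' members are rejected.
#'
#' @param path Path to the catalog TSV.
#' @return Named list of character vectors (complex id -> member protein ids).
#' @export
read_complex_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty complex catalog: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  members <- lapply(parts, function(p) {
    if (length(p) < 2L) character(0L)
    else unique(strsplit(trimws(p[[2L]]), "[ ]+")[[1L]])
  })
  names(members) <- ids
  small <- ids[lengths(members) < 2L]
  if (length(small))
    stopf("complex(es) with < 2 members: %s", paste(small, collapse = ", "))
  members
}

#' Read a crosslinked protein-pair list
#'
#' Two-column TSV of crosslinked protein pairs; collapsed to one interaction
#' per unordered pair, self-links dropped.
#'
#' @param path Path to the TSV (header expected).
#' @return data.frame with columns `protein_a`, `protein_b`.
#' @export
read_crosslink_pairs <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (ncol(df) < 2L) stopf("crosslink table needs two id columns")
  canonical_pairs(df[[1L]], df[[2L]])
}

#' @rdname read_elution_table
#' @export
read_id_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (ncol(df) < 2L) stopf("id map needs two columns (from_id, to_id)")
  names(df)[1:2] <- c("from_id", "to_id")
  df[, 1:2]
}

#' Sampling depth of proteins, pairs, and complexes
#'
#' Measures how thoroughly each protein (and, by averaging, each
#' within-complex pair and each complex) was observed across the dataset:
#' a protein's count is the number of fractions with a nonzero abundance.
#' Catalog members absent from the matrix count as 0 and are flagged.
#'
#' @param x An [elution_matrix].
#' @param catalog Named list of complexes (see [read_complex_catalog()]).
#' @return List with data.frames `proteins` (`protein_id`, `n_fractions`,
#'   `present`), `pairs` (within-complex pairs with the mean of the two
#'   member counts), and `complexes` (`complex_id`, `depth` = mean member
#'   count, `n_members`, `n_absent`).
#' @export
sampling_stats <- function(x, catalog) {
  counts <- rowSums(unclass(x) > 0)
  count_of <- function(p) ifelse(p %in% names(counts), counts[p], 0)
  proteins <- data.frame(protein_id = rownames(x),
                         n_fractions = unname(counts),
                         present = TRUE, stringsAsFactors = FALSE)
  absent <- setdiff(unique(unlist(catalog)), rownames(x))
  if (length(absent))
    proteins <- rbind(proteins,
                      data.frame(protein_id = absent, n_fractions = 0,
                                 present = FALSE, stringsAsFactors = FALSE))
  pair_rows <- lapply(names(catalog), function(cid) {
    mem <- sort(catalog[[cid]])
    if (length(mem) < 2L) return(NULL)
    idx <- utils::combn(mem, 2L)
    data.frame(complex_id = cid, protein_a = idx[1L, ], protein_b = idx[2L, ],
               depth = (count_of(idx[1L, ]) + count_of(idx[2L, ])) / 2,
               stringsAsFactors = FALSE)
  })
  complexes <- data.frame(
    complex_id = names(catalog),
    depth = vapply(catalog, function(mem) mean(count_of(mem)), numeric(1L)),
    n_members = lengths(catalog),
    n_absent = vapply(catalog, function(mem) sum(!mem %in% rownames(x)),
                      numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(proteins = proteins,
       pairs = do.call(rbind, pair_rows),
       complexes = complexes)
}
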