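# Internal helpers shared across modules.

#' @useDynLib cfcontact, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls never clobber user streams.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Canonical key for an unordered protein pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Canonicalize a two-column pair data.frame: sorted within pair, unique,
# self-pairs dropped.
canonical_pairs <- function(a, b) {
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  pa <- pmin(a, b); pb <- pmax(a, b)
  dup <- duplicated(paste(pa, pb, sep = "\r"))
  data.frame(protein_a = pa[!dup], protein_b = pb[!dup],
             stringsAsFactors = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
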