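#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
TAG_LEN <- 21L
TAG_ANCHOR <- "CATG"
SUFFIX_LEN <- 17L

#' Hamming distance between two equal-length strings
#'
#' @param a,b character scalars of equal length.
#' @return integer count of mismatching positions.
#' @keywords internal
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): strings must have equal length")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Positional wildcard keys for Hamming-1 indexing
#'
#' Two length-L strings are within Hamming distance 1 iff they share at
#' least one of the L keys formed by masking a single position.  This is
#' the index contract used for both reference redundancy removal and tag
#' assignment.
#'
#' @param tags character vector of equal-length tags.
#' @return character matrix, length(tags) rows x L columns of masked keys.
#' @keywords internal
masked_keys <- function(tags) {
  if (length(tags) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = TAG_LEN))
  }
  L <- nchar(tags[1])
  out <- matrix("", nrow = length(tags), ncol = L)
  for (i in seq_len(L)) {
    k <- tags
    substr(k, i, i) <- "."
    out[, i] <- paste0(i, ":", k)
  }
  out
}

#' Validate tag structure
#'
#' @param tags character vector.
#' @return logical vector: 21 nt, ACGT only, starting CATG.
#' @keywords internal
is_valid_tag <- function(tags) {
  nchar(tags) == TAG_LEN &
    grepl("^[ACGT]+$", tags) &
    startsWith(tags, TAG_ANCHOR)
}

#' Random DNA string generator (uniform i.i.d. bases)
#' @keywords internal
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Derive a stage seed from a master seed
#'
#' Keeps derived seeds positive and below 2^31 so they are valid R
#' integer seeds.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483563) + 1L
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards so pipeline stages do not
#' interfere with each other or with user code.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
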