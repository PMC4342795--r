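# Two-library exact-count differential expression.
#
# With one pooled library per time point, counts for a gene in two
# libraries of sizes N1 and N2 are compared with the Audic-Claverie
# statistic: given x tags in library 1, the probability of observing y
# tags in library 2 is
#
#   p(y | x) = (N2/N1)^y * (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) )
#
# i.e. y | x ~ NegBinom(size = x + 1, prob = N1/(N1+N2)).  Everything is
# computed in log space so counts in the millions are safe.  Genes pass
# as differentially expressed when FDR <= 0.001, |log2 ratio| >= 2
# (four-fold) and the raw count is >= 10 in at least one of the two
# libraries.

#' Audic-Claverie probability p(y | x)
#'
#' @param x,y non-negative counts (vectorized over `y`).
#' @param N1,N2 clean-tag totals of the two libraries.
#' @return numeric vector of probabilities.
#' @export
ac_probability <- function(x, y, N1, N2) {
  exp(ac_log_probability(x, y, N1, N2))
}

ac_log_probability <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (N1 <= 0 || N2 <= 0) stop("library totals must be positive")
  r <- N2 / N1
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

#' Two-sided Audic-Claverie p-value
#'
#' Two-sided p = min(1, 2 * min(lower, upper)) where lower sums
#' p(y'|x) over y' <= y and upper = 1 - sum over y' < y (clamped at 0).
#'
#' @param x,y non-negative counts (scalars).
#' @param N1,N2 clean-tag totals of the two libraries.
#' @return p-value in [0, 1].
#' @export
ac_two_sided_p <- function(x, y, N1, N2) {
  if (length(x) != 1L || length(y) != 1L) stop("x and y must be scalars")
  lp <- ac_log_probability(x, 0:y, N1, N2)
  p_all <- exp(lp)
  lower <- sum(p_all)
  upper <- max(0, 1 - (lower - p_all[length(p_all)]))
  min(1, 2 * min(lower, upper))
}

#' Benjamini-Hochberg (or Benjamini-Yekutieli) FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; input order is
#' preserved in the output.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param method "BH" (default) or "BY".
#' @return adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must be in [0, 1] with no NAs")
  }
  n <- length(p_values)
  if (n == 0L) return(numeric(0))
  cm <- if (method == "BY") sum(1 / seq_len(n)) else 1
  ord <- order(p_values)
  ranked <- p_values[ord] * cm * n / seq_len(n)
  adj_sorted <- pmin(1, rev(cummin(rev(ranked))))
  adj <- numeric(n)
  adj[ord] <- adj_sorted
  adj
}

#' Differential-expression thresholds
#'
#' @param fdr maximum FDR (default 0.001).
#' @param log2_ratio minimum |log2 ratio| (default 2, i.e. four-fold).
#' @param min_raw minimum raw count required in at least one of the two
#'   libraries (default 10).
#' @param fdr_method multiple-testing procedure, "BH" or "BY".
#' @return a named list of thresholds.
#' @export
de_thresholds <- function(fdr = 0.001, log2_ratio = 2, min_raw = 10L,
                          fdr_method = "BH") {
  stopifnot(fdr > 0, fdr <= 1, log2_ratio >= 0, min_raw >= 0)
  list(fdr = fdr, log2_ratio = log2_ratio, min_raw = as.integer(min_raw),
       fdr_method = fdr_method)
}

#' Pairwise differential-expression call between two libraries
#'
#' Tests every gene with a nonzero count in at least one of the two
#' libraries (genes at 0/0 are untestable and excluded from the
#' multiple-testing family).  log2 ratio is log2(TPM_j / TPM_i); when one
#' TPM is zero, the TPM equivalent of a single raw tag in that library is
#' substituted so the ratio stays finite — the raw-count filter makes
#' this floor rarely decisive.
#'
#' @param expr an `expression_matrix`.
#' @param i,j library labels (or column indices) to compare; `i` is the
#'   baseline.
#' @param thresholds a [de_thresholds()] list.
#' @return data.frame of class `pairwise_de`: gene_id, x, y, tpm_i,
#'   tpm_j, log2_ratio, p_value, fdr, passes_fdr, passes_fold,
#'   passes_raw, is_DE; comparison labels in attributes `lib_i`/`lib_j`.
#' @export
call_pairwise <- function(expr, i, j, thresholds = de_thresholds()) {
  stopifnot(inherits(expr, "expression_matrix"))
  libs <- colnames(expr$counts)
  if (is.numeric(i)) i <- libs[i]
  if (is.numeric(j)) j <- libs[j]
  if (!all(c(i, j) %in% libs)) stop("unknown library label")
  if (identical(i, j)) stop("cannot compare a library with itself")

  x <- expr$counts[, i]
  y <- expr$counts[, j]
  keep <- x > 0 | y > 0
  x <- x[keep]; y <- y[keep]
  genes <- rownames(expr$counts)[keep]
  N1 <- expr$clean_totals[[i]]
  N2 <- expr$clean_totals[[j]]

  tpm_i <- x * 1e6 / N1
  tpm_j <- y * 1e6 / N2
  floor_i <- 1e6 / N1
  floor_j <- 1e6 / N2
  log2_ratio <- log2(pmax(tpm_j, floor_j) / pmax(tpm_i, floor_i))

  p <- vapply(seq_along(x), function(k) {
    ac_two_sided_p(x[k], y[k], N1, N2)
  }, numeric(1))
  fdr <- bh_fdr(p, method = thresholds$fdr_method)

  passes_fdr <- fdr <= thresholds$fdr
  passes_fold <- abs(log2_ratio) >= thresholds$log2_ratio
  passes_raw <- pmax(x, y) >= thresholds$min_raw
  out <- data.frame(gene_id = genes, x = x, y = y,
                    tpm_i = tpm_i, tpm_j = tpm_j,
                    log2_ratio = log2_ratio,
                    p_value = p, fdr = fdr,
                    passes_fdr = passes_fdr,
                    passes_fold = passes_fold,
                    passes_raw = passes_raw,
                    is_DE = passes_fdr & passes_fold & passes_raw,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "lib_i") <- i
  attr(out, "lib_j") <- j
  attr(out, "thresholds") <- thresholds
  class(out) <- c("pairwise_de", "data.frame")
  out
}

#' Run all pairwise comparisons of an expression matrix
#'
#' @param expr an `expression_matrix`.
#' @param thresholds a [de_thresholds()] list.
#' @param baseline if non-NULL, only compare this library against every
#'   other (baseline design); default tests all unordered pairs.
#' @return named list of `pairwise_de` data.frames ("i_vs_j").
#' @export
call_all_pairwise <- function(expr, thresholds = de_thresholds(),
                              baseline = NULL) {
  libs <- colnames(expr$counts)
  pairs <- if (is.null(baseline)) {
    utils::combn(libs, 2, simplify = FALSE)
  } else {
    stopifnot(baseline %in% libs)
    lapply(setdiff(libs, baseline), function(l) c(baseline, l))
  }
  out <- lapply(pairs, function(pr) {
    call_pairwise(expr, pr[1], pr[2], thresholds)
  })
  names(out) <- vapply(pairs, function(pr) {
    paste0(pr[1], "_vs_", pr[2])
  }, character(1))
  out
}

#' Union DEG set across pairwise comparisons
#'
#' A gene is a DEG if it passes all three filters in at least one
#' pairwise comparison.  The per-gene record retains which comparisons
#' fired, in which direction, and an overall direction summary ("up" if
#' every firing comparison had log2 ratio > 0 with time ordered i < j,
#' "down" if all < 0, otherwise "complex").
#'
#' @param all_pairwise list of `pairwise_de` from [call_all_pairwise()].
#' @return object of class `deg_set`: data.frame (gene_id, n_comparisons,
#'   direction, comparisons).
#' @export
union_degs <- function(all_pairwise) {
  recs <- lapply(names(all_pairwise), function(nm) {
    df <- all_pairwise[[nm]]
    de <- df[df$is_DE, , drop = FALSE]
    if (!nrow(de)) return(NULL)
    data.frame(gene_id = de$gene_id, comparison = nm,
               log2_ratio = de$log2_ratio, stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs) || !nrow(recs)) {
    out <- data.frame(gene_id = character(0), n_comparisons = integer(0),
                      direction = character(0), comparisons = character(0),
                      stringsAsFactors = FALSE)
  } else {
    sp <- split(recs, recs$gene_id)
    out <- do.call(rbind, lapply(sp, function(d) {
      dir <- if (all(d$log2_ratio > 0)) "up"
             else if (all(d$log2_ratio < 0)) "down"
             else "complex"
      data.frame(gene_id = d$gene_id[1], n_comparisons = nrow(d),
                 direction = dir,
                 comparisons = paste(d$comparison, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    out <- out[order(out$gene_id), ]
    rownames(out) <- NULL
  }
  class(out) <- c("deg_set", "data.frame")
  out
}

#' Write a pairwise DE table with thresholds echoed in the header
#'
#' @param de a `pairwise_de` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairwise_de <- function(de, path) {
  th <- attr(de, "thresholds")
  hdr <- tsv_provenance(extra = c(
    paste0("comparison: ", attr(de, "lib_i"), " vs ", attr(de, "lib_j")),
    paste0("thresholds: fdr<=", th$fdr, " |log2|>=", th$log2_ratio,
           " raw>=", th$min_raw, " method=", th$fdr_method)))
  write_tsv(as.data.frame(de), path, hdr)
}
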