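# Annotation-set over-representation analysis.
#
# Any term -> gene table (KEGG pathway, GO, TF family, hormone category)
# is consumed as a plain GMT-style file.  Significance is the one-sided
# Fisher exact (hypergeometric upper-tail) test of the study set against
# a background universe — by default all detected genes, matching the
# expression universe rather than the annotation file.  BH correction is
# applied within each namespace.

#' Read a GMT-style annotation table
#'
#' Each line: term id, term name, then tab-separated gene ids.
#'
#' @param path GMT file path.
#' @param namespace label for the annotation namespace (e.g. "pathway").
#' @return data.frame (term, name, gene_id) of class `annotation_table`.
#' @export
read_gmt <- function(path, namespace = "pathway") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line needs term, name and >=1 gene: ", l)
    data.frame(term = f[1], name = f[2], gene_id = f[-(1:2)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "namespace") <- namespace
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Write an annotation table in GMT format
#'
#' @param table an `annotation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(table, path) {
  sp <- split(table$gene_id, table$term)
  nm <- vapply(split(table$name, table$term), `[`, character(1), 1L)
  lines <- vapply(names(sp), function(tm) {
    paste(c(tm, nm[[tm]], sp[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation test of a study set against annotation terms
#'
#' For each term with at least one background gene, the one-sided
#' hypergeometric upper-tail p-value of drawing `k` or more term genes in
#' a study set of size `n` from a background of `N` genes of which `K`
#' carry the term.  BH correction across terms within the namespace;
#' significance at corrected p < alpha.
#'
#' @param study character vector of study genes (e.g. the DEG set).
#' @param background character vector, the gene universe; `study` must be
#'   a subset.
#' @param table an `annotation_table`.
#' @param alpha significance level on the corrected p (default 0.05).
#' @return data.frame of class `enrichment_result`: term, name, k, n, K,
#'   N, p_value, corrected_p, significant — ordered by p-value.
#' @export
fisher_enrich <- function(study, background, table, alpha = 0.05) {
  study <- unique(study)
  background <- unique(background)
  offenders <- setdiff(study, background)
  if (length(offenders)) {
    stop("study genes missing from background: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  }
  N <- length(background)
  n <- length(study)
  sp <- split(table$gene_id, table$term)
  nm <- vapply(split(table$name, table$term), `[`, character(1), 1L)

  rows <- lapply(names(sp), function(tm) {
    term_genes <- intersect(unique(sp[[tm]]), background)
    K <- length(term_genes)
    if (K == 0L) return(NULL)
    k <- length(intersect(term_genes, study))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, name = nm[[tm]], k = k, n = n, K = K, N = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      corrected_p = numeric(0), significant = logical(0))
  } else {
    out$corrected_p <- bh_fdr(out$p_value)
    out$significant <- out$corrected_p < alpha
    out <- out[order(out$p_value, out$term), ]
    rownames(out) <- NULL
  }
  attr(out, "namespace") <- attr(table, "namespace")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Per-term direction summary of differentially expressed genes
#'
#' Counts, for each annotation term, how many of its DEG members are
#' labelled up, down, or complex — the layout used to tabulate
#' hormone-related genes by response direction.
#'
#' @param degs a `deg_set` (its `direction` column supplies labels) or a
#'   named character vector gene -> direction.
#' @param table an `annotation_table`.
#' @return data.frame (term, name, up, down, complex, total).
#' @export
summarize_directions <- function(degs, table) {
  if (is.data.frame(degs)) {
    dirs <- stats::setNames(degs$direction, degs$gene_id)
  } else {
    dirs <- degs
  }
  sp <- split(table$gene_id, table$term)
  nm <- vapply(split(table$name, table$term), `[`, character(1), 1L)
  rows <- lapply(names(sp), function(tm) {
    hit <- intersect(unique(sp[[tm]]), names(dirs))
    d <- dirs[hit]
    data.frame(term = tm, name = nm[[tm]],
               up = sum(d == "up"), down = sum(d == "down"),
               complex = sum(d == "complex"), total = length(hit),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
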