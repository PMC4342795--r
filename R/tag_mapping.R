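# Mapping observed clean tags to the reference library.
#
# Assignment semantics: exact matches are searched first; an exact hit
# resolving to a single gene is unambiguous even if 1-mismatch neighbours
# exist elsewhere.  Failing an exact hit, all Hamming-distance-1
# neighbours are collected; one gene -> unambiguous, two or more genes ->
# ambiguous (filtered out of counting), none -> unmapped.  Ambiguity is
# evaluated at the gene level: multiple sites of one gene do not make a
# tag ambiguous.

#' Build a Hamming-1 lookup index over a reference library
#'
#' The index stores, for every reference tag, its exact key and its 21
#' single-position wildcard keys, guaranteeing exact Hamming-1 semantics.
#'
#' @param lib a `reference_tag_library`.
#' @return object of class `tag_index` used by [assign_tags()].
#' @export
build_tag_index <- function(lib) {
  stopifnot(is.data.frame(lib))
  tags <- lib$tag
  genes <- lib$gene_id
  exact <- new.env(hash = TRUE, parent = emptyenv())
  if (length(tags)) {
    sp <- split(genes, tags)
    sp <- lapply(sp, unique)
    list2env(sp, envir = exact)
  }
  fuzzy <- new.env(hash = TRUE, parent = emptyenv())
  if (length(tags)) {
    mk <- masked_keys(tags)
    sp <- split(rep(genes, times = ncol(mk)), as.vector(mk))
    sp <- lapply(sp, unique)
    list2env(sp, envir = fuzzy)
  }
  structure(list(exact = exact, fuzzy = fuzzy, n_tags = length(tags)),
            class = "tag_index")
}

#' Assign observed tags to genes with at most one mismatch
#'
#' @param tags character vector of distinct observed 21-nt tags.
#' @param index a `tag_index` from [build_tag_index()], or a
#'   `reference_tag_library` (indexed on the fly).
#' @return data.frame (tag, status, gene_id): `status` is one of
#'   "unambiguous", "ambiguous", "unmapped", "rejected"; `gene_id` is set
#'   only for unambiguous tags.
#' @export
assign_tags <- function(tags, index) {
  if (inherits(index, "reference_tag_library")) {
    index <- build_tag_index(index)
  }
  stopifnot(inherits(index, "tag_index"))
  n <- length(tags)
  status <- rep("unmapped", n)
  gene <- rep(NA_character_, n)

  ok <- is_valid_tag(tags)
  status[!ok] <- "rejected"
  idx <- which(ok)
  if (length(idx)) {
    hits <- mget(tags[idx], envir = index$exact, ifnotfound = list(NULL))
    n_genes <- lengths(hits)
    status[idx[n_genes == 1L]] <- "unambiguous"
    gene[idx[n_genes == 1L]] <- unlist(hits[n_genes == 1L], use.names = FALSE)
    status[idx[n_genes >= 2L]] <- "ambiguous"

    # 1-mismatch pass for tags without an exact hit
    rem <- idx[n_genes == 0L]
    if (length(rem)) {
      mk <- masked_keys(tags[rem])
      flat <- mget(as.vector(mk), envir = index$fuzzy,
                   ifnotfound = list(NULL))
      qidx <- rep(seq_along(rem), times = ncol(mk))
      by_query <- split(flat, qidx)
      ng <- vapply(by_query, function(lst) {
        g <- unique(unlist(lst, use.names = FALSE))
        length(g)
      }, integer(1))
      g1 <- vapply(by_query, function(lst) {
        g <- unique(unlist(lst, use.names = FALSE))
        if (length(g) == 1L) g else NA_character_
      }, character(1))
      status[rem[ng == 1L]] <- "unambiguous"
      gene[rem[ng == 1L]] <- g1[ng == 1L]
      status[rem[ng >= 2L]] <- "ambiguous"
    }
  }
  data.frame(tag = tags, status = status, gene_id = gene,
             stringsAsFactors = FALSE)
}

#' Assign one tag (scalar convenience wrapper)
#'
#' @param tag a single 21-nt tag.
#' @param index as in [assign_tags()].
#' @return one-row data.frame (tag, status, gene_id).
#' @export
assign_tag <- function(tag, index) {
  stopifnot(length(tag) == 1L)
  assign_tags(tag, index)
}

#' Count unambiguous tags per gene for one library
#'
#' @param tags a `tag_count_set` (see [simulate_tag_library()] /
#'   [read_tag_counts()]).
#' @param index a `tag_index` or `reference_tag_library`.
#' @return object of class `mapping_result`: list with `library_id`,
#'   `gene_counts` (named integer vector), `assignments` (per-distinct-tag
#'   data.frame with copy numbers), `clean_total`, and `summary` — copy
#'   and distinct-tag totals per status plus the two distinct-tag
#'   fractions reported for DGE studies (fraction of distinct tags
#'   unambiguously assigned to a gene; fraction mapped to the reference
#'   at all, i.e. unambiguous + ambiguous).
#' @export
count_library <- function(tags, index) {
  stopifnot(inherits(tags, "tag_count_set"))
  asg <- assign_tags(names(tags$counts), index)
  asg$count <- as.integer(tags$counts)

  un <- asg[asg$status == "unambiguous", , drop = FALSE]
  gene_counts <- integer(0)
  if (nrow(un)) {
    gc <- tapply(un$count, un$gene_id, sum)
    gene_counts <- stats::setNames(as.integer(gc), names(gc))
  }
  n_distinct <- nrow(asg)
  by_status_copies <- tapply(asg$count, asg$status, sum)
  by_status_distinct <- table(asg$status)
  g <- function(x, s) if (s %in% names(x)) as.integer(x[[s]]) else 0L
  summary <- list(
    clean_total = tags$clean_total,
    distinct_tags = n_distinct,
    copies = list(unambiguous = g(by_status_copies, "unambiguous"),
                  ambiguous = g(by_status_copies, "ambiguous"),
                  unmapped = g(by_status_copies, "unmapped"),
                  rejected = g(by_status_copies, "rejected")),
    distinct = list(unambiguous = g(by_status_distinct, "unambiguous"),
                    ambiguous = g(by_status_distinct, "ambiguous"),
                    unmapped = g(by_status_distinct, "unmapped"),
                    rejected = g(by_status_distinct, "rejected")))
  summary$frac_distinct_gene <- if (n_distinct) {
    summary$distinct$unambiguous / n_distinct
  } else 0
  summary$frac_distinct_reference <- if (n_distinct) {
    (summary$distinct$unambiguous + summary$distinct$ambiguous) / n_distinct
  } else 0

  structure(list(library_id = tags$library_id,
                 gene_counts = gene_counts,
                 assignments = asg,
                 clean_total = tags$clean_total,
                 summary = summary),
            class = "mapping_result")
}

#' Assemble an expression matrix from per-library mapping results
#'
#' @param results list of `mapping_result`, one per library, in the
#'   desired column order.
#' @param genes optional character vector fixing the gene universe
#'   (defaults to the union of genes observed in any library).
#' @return object of class `expression_matrix`: list with integer matrix
#'   `counts` (genes x libraries), numeric matrix `tpm`, and
#'   `clean_totals` (named numeric vector).
#' @export
expression_matrix <- function(results, genes = NULL) {
  stopifnot(length(results) >= 1L)
  libs <- vapply(results, `[[`, character(1), "library_id")
  if (anyDuplicated(libs)) stop("duplicate library ids")
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(results, function(r) {
      names(r$gene_counts)
    }))))
  }
  counts <- matrix(0L, nrow = length(genes), ncol = length(libs),
                   dimnames = list(genes, libs))
  for (j in seq_along(results)) {
    gc <- results[[j]]$gene_counts
    gc <- gc[names(gc) %in% genes]
    counts[names(gc), j] <- gc
  }
  clean_totals <- stats::setNames(
    vapply(results, `[[`, numeric(1), "clean_total"), libs)
  out <- list(counts = counts, tpm = NULL, clean_totals = clean_totals)
  class(out) <- "expression_matrix"
  normalize_tpm(out)
}

#' Normalize raw tag counts to TPM (tags per million clean tags)
#'
#' TPM here is the tag-count sense used in DGE studies: raw per-gene tag
#' count x 1e6 / total clean tags in the library — not the
#' length-normalized RNA-seq TPM.
#'
#' @param expr an `expression_matrix` (the `tpm` slot is (re)computed).
#' @return the matrix with `tpm` filled in; raw counts preserved.
#' @export
normalize_tpm <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (any(expr$clean_totals <= 0)) {
    bad <- names(expr$clean_totals)[expr$clean_totals <= 0]
    stop("clean_total is zero for library: ", paste(bad, collapse = ", "))
  }
  expr$tpm <- sweep(expr$counts, 2, expr$clean_totals, "/") * 1e6
  expr
}

#' Read a tag-count TSV (tag, count) into a `tag_count_set`
#'
#' @param path TSV path.
#' @param library_id label for the library (defaults to the file name).
#' @return a `tag_count_set`.
#' @export
read_tag_counts <- function(path, library_id = NULL) {
  df <- read_tsv(path, colClasses = c(tag = "character", count = "integer"))
  if (is.null(library_id)) {
    library_id <- sub("^tags_", "", sub("\\.tsv$", "", basename(path)))
  }
  counts <- stats::setNames(df$count, df$tag)
  structure(list(library_id = library_id, counts = counts,
                 clean_total = sum(df$count)),
            class = "tag_count_set")
}

#' Write a `tag_count_set` to TSV
#'
#' @param tags a `tag_count_set`.
#' @param path output path.
#' @param comments header comment lines.
#' @return `path`, invisibly.
#' @export
write_tag_counts <- function(tags, path, comments = character(0)) {
  df <- data.frame(tag = names(tags$counts),
                   count = as.integer(tags$counts),
                   stringsAsFactors = FALSE)
  df <- df[order(df$tag), ]
  write_tsv(df, path, comments)
}

#' Write an expression matrix (raw + TPM columns per library) to TSV
#'
#' @param expr an `expression_matrix`.
#' @param path output path.
#' @param comments header comment lines.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, comments = character(0)) {
  libs <- colnames(expr$counts)
  df <- data.frame(gene_id = rownames(expr$counts),
                   stringsAsFactors = FALSE)
  for (l in libs) {
    df[[paste0("raw_", l)]] <- expr$counts[, l]
    df[[paste0("tpm_", l)]] <- expr$tpm[, l]
  }
  hdr <- c(comments,
           paste0("clean_totals: ",
                  paste(libs, expr$clean_totals, sep = "=",
                        collapse = " ")))
  write_tsv(df, path, hdr)
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param path TSV path.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path) {
  first <- readLines(path, n = 50L)
  ct_line <- grep("^# clean_totals:", first, value = TRUE)
  if (!length(ct_line)) stop("missing clean_totals header in ", path)
  kv <- strsplit(strsplit(sub("^# clean_totals: ", "", ct_line[1]),
                          " ")[[1]], "=")
  clean_totals <- stats::setNames(
    vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
    vapply(kv, `[`, character(1), 1L))
  df <- read_tsv(path)
  libs <- names(clean_totals)
  counts <- as.matrix(df[paste0("raw_", libs)])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(df$gene_id, libs)
  out <- list(counts = counts, tpm = NULL, clean_totals = clean_totals)
  class(out) <- "expression_matrix"
  normalize_tpm(out)
}
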