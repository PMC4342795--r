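# Virtual reference tag library.
#
# NlaIII DGE represents each transcript by the 21-nt tag (CATG + 17 nt)
# at the restriction site closest to the poly(A) tail.  The reference
# library holds every CATG+17 tag of every coding sequence from the two
# progenitor genomes, after cross-genome redundancy removal: a D-genome
# gene whose canonical (3'-most) tag is identical to, or within Hamming
# distance 1 of, any A-genome canonical tag is dropped entirely, the
# A-genome copy being kept with higher priority.  Within-genome tag
# collisions are retained and resolved as ambiguous at mapping time.

#' Extract CATG+17 reference tags from one coding sequence
#'
#' One tag is produced per CATG occurrence with at least 17 nt downstream.
#' `site_rank` 1 is the 3'-most qualifying site (the canonical tag — the
#' site retained on the mRNA fragment nearest the poly(A) tail), with
#' ranks increasing toward the 5' end.
#'
#' @param cds coding sequence (sense strand) over A/C/G/T.
#' @param gene_id gene identifier.
#' @param genome genome of origin, "A" or "D".
#' @return data.frame (tag, gene_id, genome, site_rank); zero rows if the
#'   sequence has no qualifying CATG site.
#' @export
extract_tags <- function(cds, gene_id, genome) {
  if (!grepl("^[ACGT]*$", cds)) {
    stop("invalid_sequence: CDS for gene '", gene_id,
         "' contains non-ACGT characters")
  }
  starts <- gregexpr(TAG_ANCHOR, cds, fixed = TRUE)[[1]]
  if (starts[1] == -1L) {
    return(data.frame(tag = character(0), gene_id = character(0),
                      genome = character(0), site_rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  ok <- starts + TAG_LEN - 1L <= nchar(cds)
  starts <- starts[ok]
  if (!length(starts)) {
    return(data.frame(tag = character(0), gene_id = character(0),
                      genome = character(0), site_rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  starts <- rev(starts)  # 3'-most first
  data.frame(tag = substring(cds, starts, starts + TAG_LEN - 1L),
             gene_id = gene_id, genome = genome,
             site_rank = seq_along(starts),
             stringsAsFactors = FALSE)
}

#' Extract tags from a whole genome table
#'
#' @param genes data.frame with columns `gene_id`, `cds`.
#' @param genome "A" or "D".
#' @return row-bound data.frame of [extract_tags()] results.
#' @export
extract_genome_tags <- function(genes, genome) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    extract_tags(genes$cds[i], genes$gene_id[i], genome)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(tag = character(0), gene_id = character(0),
                      genome = character(0), site_rank = integer(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Merge two genomes' tag sets into one reference library
#'
#' Canonical (site_rank 1) tags are compared across genomes.  A D-genome
#' gene whose canonical tag is within Hamming distance <= 1 of any
#' A-genome canonical tag is redundant: all of its tag entries are
#' removed and the A-genome entries kept (A-genome priority).  The result
#' is independent of input row order.
#'
#' @param tags_A,tags_D data.frames as produced by [extract_genome_tags()].
#' @return object of class `reference_tag_library`: data.frame
#'   (tag, gene_id, genome, site_rank) with attribute `provenance`, a list
#'   with counts `kept_A`, `kept_D`, `dropped_D_genes`,
#'   `dropped_D_tags`.
#' @export
merge_genomes <- function(tags_A, tags_D) {
  for (df in list(tags_A, tags_D)) {
    stopifnot(all(c("tag", "gene_id", "genome", "site_rank") %in% names(df)))
    bad <- !is_valid_tag(df$tag)
    if (any(bad)) {
      stop("malformed reference tags: ",
           paste(utils::head(df$tag[bad], 3), collapse = ", "))
    }
  }
  canon_A <- tags_A[tags_A$site_rank == 1L, , drop = FALSE]
  canon_D <- tags_D[tags_D$site_rank == 1L, , drop = FALSE]

  dropped_genes <- character(0)
  if (nrow(canon_A) > 0 && nrow(canon_D) > 0) {
    a_keys <- unique(as.vector(masked_keys(canon_A$tag)))
    a_env <- new.env(hash = TRUE, parent = emptyenv(), size = length(a_keys))
    for (k in a_keys) assign(k, TRUE, envir = a_env)
    d_keys <- masked_keys(canon_D$tag)
    hit <- vapply(seq_len(nrow(canon_D)), function(i) {
      any(vapply(d_keys[i, ], exists, logical(1),
                 envir = a_env, inherits = FALSE))
    }, logical(1))
    dropped_genes <- unique(canon_D$gene_id[hit])
  }

  keep_D <- tags_D[!(tags_D$gene_id %in% dropped_genes), , drop = FALSE]
  lib <- rbind(tags_A, keep_D)
  # canonical row order: independent of input ordering
  lib <- lib[order(lib$genome, lib$gene_id, lib$site_rank), , drop = FALSE]
  rownames(lib) <- NULL
  attr(lib, "provenance") <- list(
    kept_A = nrow(tags_A),
    kept_D = nrow(keep_D),
    dropped_D_genes = length(dropped_genes),
    dropped_D_tags = nrow(tags_D) - nrow(keep_D))
  class(lib) <- c("reference_tag_library", "data.frame")
  lib
}

#' Build the reference library straight from two genome tables
#'
#' @param genes_A,genes_D data.frames with columns `gene_id`, `cds`.
#' @param canonical_only if TRUE the mapping database is restricted to
#'   canonical (3'-most) tags; by default all CATG+17 sites are indexed
#'   while redundancy removal always uses canonical tags only.
#' @return a `reference_tag_library`.
#' @export
build_reference_library <- function(genes_A, genes_D,
                                    canonical_only = FALSE) {
  tags_A <- extract_genome_tags(genes_A, "A")
  tags_D <- extract_genome_tags(genes_D, "D")
  lib <- merge_genomes(tags_A, tags_D)
  if (canonical_only) {
    prov <- attr(lib, "provenance")
    lib2 <- lib[lib$site_rank == 1L, , drop = FALSE]
    rownames(lib2) <- NULL
    attr(lib2, "provenance") <- prov
    class(lib2) <- class(lib)
    lib <- lib2
  }
  lib
}

#' Write a reference library (and its provenance) to TSV
#'
#' @param lib a `reference_tag_library`.
#' @param path library TSV path; provenance is written alongside with a
#'   `.provenance.tsv` suffix.
#' @return `path`, invisibly.
#' @export
write_reference_library <- function(lib, path) {
  prov <- attr(lib, "provenance")
  write_tsv(as.data.frame(lib), path,
            tsv_provenance(extra = "columns: tag gene_id genome site_rank"))
  write_tsv(as.data.frame(prov), paste0(path, ".provenance.tsv"),
            tsv_provenance(extra = "reference library provenance counts"))
  invisible(path)
}

#' Read a reference library written by [write_reference_library()]
#'
#' @param path library TSV path.
#' @return a `reference_tag_library` (provenance restored when the
#'   side-car file is present).
#' @export
read_reference_library <- function(path) {
  lib <- read_tsv(path, colClasses = c(tag = "character",
                                       gene_id = "character",
                                       genome = "character",
                                       site_rank = "integer"))
  prov_path <- paste0(path, ".provenance.tsv")
  if (file.exists(prov_path)) {
    attr(lib, "provenance") <- as.list(read_tsv(prov_path))
  }
  class(lib) <- c("reference_tag_library", "data.frame")
  lib
}
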