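# Plain-text I/O helpers shared by all stages.
#
# Every TSV written by the pipeline carries a '#'-prefixed header-comment
# block (version, config hash, column schema) followed by a standard
# tab-separated table with a header row.  Readers skip the comment block,
# so files round-trip losslessly.

#' Write a data frame as a commented TSV
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param comments character vector of comment lines (without leading "#").
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) {
    writeLines(paste0("# ", comments), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input file.
#' @param colClasses optional column classes passed to `read.delim`.
#' @return data.frame.
#' @export
read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    check.names = FALSE)
}

#' Standard header-comment block for pipeline outputs
#' @keywords internal
tsv_provenance <- function(config_hash = NA_character_, extra = character(0)) {
  c(paste0("cottonDGE v",
           as.character(utils::packageVersion("cottonDGE"))),
    paste0("config-hash: ", config_hash),
    extra)
}

#' Deterministic hash of a configuration object
#'
#' Serializes to canonical JSON and hashes with md5 so that identical
#' configs always produce identical provenance headers.
#' @keywords internal
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# recursively drop S3 classes so nested config objects serialize as
# plain lists
strip_classes <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, strip_classes)
  x
}

#' Write CDS sequences to FASTA with genome-tagged headers
#'
#' Headers follow `>geneID genome=A` so the origin genome survives a
#' round trip through the file interface.
#'
#' @param genes data.frame with columns `gene_id`, `cds`.
#' @param genome single character, "A" or "D".
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, genome, path) {
  x <- Biostrings::DNAStringSet(genes$cds)
  names(x) <- paste0(genes$gene_id, " genome=", genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a CDS FASTA written by [write_cds_fasta()]
#'
#' @param path FASTA path.
#' @return data.frame with columns `gene_id`, `genome`, `cds`.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- strsplit(names(x), " ", fixed = TRUE)
  gene_id <- vapply(hdr, `[`, character(1), 1L)
  genome <- vapply(hdr, function(h) {
    g <- grep("^genome=", h, value = TRUE)
    if (length(g)) sub("^genome=", "", g[1]) else NA_character_
  }, character(1))
  data.frame(gene_id = gene_id, genome = genome,
             cds = as.character(x), stringsAsFactors = FALSE)
}
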