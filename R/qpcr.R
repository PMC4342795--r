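# qPCR cross-validation of the DGE profiles.
#
# Relative expression by the comparative 2^-ddCt method: technical
# replicate Ct values are averaged (arithmetic mean), dCt = Ct_target -
# Ct_reference per sample, ddCt = dCt_sample - dCt_calibrator, and
# rel_expr = 2^-ddCt (so rel_expr is exactly 1 at the calibrator sample).
# Per-gene Pearson correlation against the TPM profile quantifies
# platform agreement.

#' Read a Ct table (gene, sample, replicate, ct)
#'
#' Reference-gene measurements are ordinary rows whose `gene` equals the
#' reference gene's name.
#'
#' @param path TSV path.
#' @return data.frame (gene, sample, replicate, ct).
#' @export
read_ct_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene", "sample", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Relative expression by the comparative 2^-ddCt method
#'
#' @param records data.frame (gene, sample, replicate, ct) including
#'   reference-gene rows.
#' @param calibrator calibrator sample label (default "15d", the first
#'   time point).
#' @param reference_gene name of the reference gene rows (default
#'   "actin").
#' @return data.frame of class `relative_expression`: gene, sample,
#'   mean_ct, dct, ddct, rel_expr.
#' @export
ddct <- function(records, calibrator = "15d", reference_gene = "actin") {
  stopifnot(all(c("gene", "sample", "ct") %in% names(records)))
  if (any(records$ct <= 0)) stop("non-positive Ct value in input")

  mean_ct <- stats::aggregate(ct ~ gene + sample, data = records,
                              FUN = mean)
  ref <- mean_ct[mean_ct$gene == reference_gene, c("sample", "ct")]
  if (!nrow(ref)) stop("reference gene '", reference_gene, "' not found")
  tgt <- mean_ct[mean_ct$gene != reference_gene, , drop = FALSE]

  missing_ref <- setdiff(unique(tgt$sample), ref$sample)
  if (length(missing_ref)) {
    stop("reference gene missing for sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  tgt$dct <- tgt$ct - ref$ct[match(tgt$sample, ref$sample)]

  out <- do.call(rbind, lapply(split(tgt, tgt$gene), function(d) {
    if (!(calibrator %in% d$sample)) {
      stop("calibrator sample '", calibrator,
           "' missing for gene ", d$gene[1])
    }
    d$ddct <- d$dct - d$dct[d$sample == calibrator]
    d$rel_expr <- 2^(-d$ddct)
    d
  }))
  out <- data.frame(gene = out$gene, sample = out$sample,
                    mean_ct = out$ct, dct = out$dct, ddct = out$ddct,
                    rel_expr = out$rel_expr,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' Correlate qPCR and DGE expression profiles
#'
#' Per-gene Pearson correlation between the 2^-ddCt profile and the TPM
#' profile over shared time points, plus the mean correlation across
#' genes.  Genes with fewer than 3 shared points, or zero variance on
#' either platform, are reported with `r = NA` and excluded from the
#' mean (with a warning).
#'
#' @param qpcr a `relative_expression` data.frame from [ddct()].
#' @param expr an `expression_matrix`; column names are sample labels.
#' @param genes genes to correlate (default: all genes in `qpcr`).
#' @param log_scale correlate on log2 scale instead of raw values.
#' @param exclude genes to drop (e.g. failed amplifications).
#' @return list with data.frame `per_gene` (gene, n_points, r) and
#'   scalar `mean_r`.
#' @export
correlate_platforms <- function(qpcr, expr, genes = NULL,
                                log_scale = FALSE, exclude = character(0)) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(genes)) genes <- unique(qpcr$gene)
  genes <- setdiff(genes, exclude)
  samples <- colnames(expr$tpm)

  per_gene <- do.call(rbind, lapply(genes, function(g) {
    q <- qpcr[qpcr$gene == g, , drop = FALSE]
    shared <- intersect(samples, q$sample)
    if (length(shared) < 3L || !(g %in% rownames(expr$tpm))) {
      warning("gene ", g, " skipped: fewer than 3 shared time points")
      return(data.frame(gene = g, n_points = length(shared), r = NA_real_,
                        stringsAsFactors = FALSE))
    }
    a <- q$rel_expr[match(shared, q$sample)]
    b <- expr$tpm[g, shared]
    if (log_scale) {
      a <- log2(a)
      b <- log2(b + min(b[b > 0], 1) / 2)
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("gene ", g, " has zero variance on one platform; ",
              "correlation undefined")
      return(data.frame(gene = g, n_points = length(shared), r = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(gene = g, n_points = length(shared),
               r = stats::cor(a, b), stringsAsFactors = FALSE)
  }))
  list(per_gene = per_gene, mean_r = mean(per_gene$r, na.rm = TRUE))
}
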